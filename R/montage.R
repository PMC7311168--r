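#' Construct a quasi-uniform sensor montage on the unit sphere
#'
#' Places `n_channels` sensors on the unit sphere with a Fibonacci lattice
#' (quasi-uniform coverage; a deliberate idealization of a dense EEG net) and
#' designates as the occipital cluster the `cluster_size` sensors closest to
#' the occipital pole direction. The first sensor is relocated to the occipital
#' pole itself so the cluster always contains a sensor at its center,
#' emulating Oz plus its neighbours.
#'
#' @param n_channels Number of sensors (default 129).
#' @param cluster_size Size of the occipital pooling cluster (default 8).
#' @param occipital_dir Unit vector of the occipital pole direction.
#' @param seed Unused; accepted for interface symmetry with the other
#'   generators (the lattice is deterministic).
#' @return Object of class `sensor_montage`: list with `positions`
#'   (n x 3 matrix of unit vectors, rownames E1..En), `labels`,
#'   `occipital_cluster` (character labels), `reference` (label).
#' @export
make_montage <- function(n_channels = 129, cluster_size = 8,
                         occipital_dir = c(0, -1, -0.2), seed = NULL) {
  stopifnot(n_channels >= 4, cluster_size >= 1, cluster_size < n_channels)
  occ <- occipital_dir / sqrt(sum(occipital_dir^2))
  i <- seq_len(n_channels) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_channels
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n_channels) - 1)
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  # pin one sensor exactly at the occipital pole ("Oz")
  d <- drop(pos %*% occ)
  pos[which.max(d), ] <- occ
  labels <- paste0("E", seq_len(n_channels))
  rownames(pos) <- labels
  d <- drop(pos %*% occ)
  cluster <- labels[order(d, decreasing = TRUE)[seq_len(cluster_size)]]
  structure(list(positions = pos, labels = labels,
                 occipital_cluster = cluster, reference = labels[1L]),
            class = "sensor_montage")
}

#' @export
print.sensor_montage <- function(x, ...) {
  cat("Sensor montage:", length(x$labels), "channels; occipital cluster:",
      paste(x$occipital_cluster, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write electrode positions in BESA-style sfp format
#'
#' The sfp format is plain text with one row per electrode:
#' `label x y z` (whitespace separated). Positions are renormalized to unit
#' radius on read if they are within 1% of it; otherwise an error is raised.
#'
#' @param path File path.
#' @param cluster_size Occipital cluster size to designate after reading.
#' @param occipital_dir Occipital pole direction used to pick the cluster.
#' @return `read_sfp()`: a `sensor_montage`. `write_sfp()`: the path,
#'   invisibly.
#' @export
read_sfp <- function(path, cluster_size = 8, occipital_dir = c(0, -1, -0.2)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad))
    stop("malformed sfp file at line ", bad[1], ": expected 'label x y z'")
  labels <- vapply(parts, `[[`, "", 1L)
  pos <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                  numeric(3)))
  if (anyNA(pos)) stop("malformed sfp file: non-numeric coordinates")
  rad <- sqrt(rowSums(pos^2))
  if (any(rad == 0)) stop("malformed sfp file: zero-radius position")
  pos <- pos / rad
  colnames(pos) <- c("x", "y", "z")
  rownames(pos) <- labels
  occ <- occipital_dir / sqrt(sum(occipital_dir^2))
  d <- drop(pos %*% occ)
  cluster <- labels[order(d, decreasing = TRUE)[seq_len(min(cluster_size, nrow(pos)))]]
  structure(list(positions = pos, labels = labels,
                 occipital_cluster = cluster, reference = labels[1L]),
            class = "sensor_montage")
}

#' @rdname read_sfp
#' @param montage A `sensor_montage`.
#' @export
write_sfp <- function(montage, path) {
  p <- montage$positions
  lines <- sprintf("%s\t%.6f\t%.6f\t%.6f", rownames(p), p[, 1], p[, 2], p[, 3])
  writeLines(lines, path)
  invisible(path)
}
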