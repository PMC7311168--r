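# Spherical-spline machinery (Perrin-style): shared by channel interpolation
# and the current source density transform.

# P_l(x) for l = 1..lmax, x in [-1, 1]; matrix length(x) x lmax
legendre_matrix <- function(x, lmax) {
  out <- matrix(0, length(x), lmax)
  p0 <- rep(1, length(x))
  p1 <- x
  out[, 1] <- p1
  if (lmax >= 2) {
    for (l in 1:(lmax - 1)) {
      p2 <- ((2 * l + 1) * x * p1 - l * p0) / (l + 1)
      out[, l + 1] <- p2
      p0 <- p1
      p1 <- p2
    }
  }
  out
}

# spline kernels g (potential) and h (negative surface Laplacian) evaluated
# at cosines of inter-sensor angles
spline_kernels <- function(cosang, m, lmax) {
  x <- pmin(1, pmax(-1, as.numeric(cosang)))
  P <- legendre_matrix(x, lmax)
  l <- seq_len(lmax)
  cg <- (2 * l + 1) / (l * (l + 1))^m
  ch <- (2 * l + 1) / (l * (l + 1))^(m - 1)
  g <- (P %*% cg) / (4 * pi)
  h <- (P %*% ch) / (4 * pi)
  dim(g) <- dim(cosang)
  dim(h) <- dim(cosang)
  list(g = g, h = h)
}

#' CSD transform configuration
#'
#' @param lambda Regularization weight added to the diagonal of the
#'   trace-normalized spline Gram matrix (default 0.2). Normalizing the Gram
#'   trace to the channel count before adding lambda makes the value
#'   comparable across montages; this convention is documented because
#'   published implementations differ in their internal scaling.
#' @param m Spline order (>= 2; default 4).
#' @param legendre_terms Truncation of the Legendre expansion (>= 10).
#' @param head_radius Sphere radius; output scales as 1/radius^2.
#' @return List of class `csd_config`.
#' @export
csd_config <- function(lambda = 0.2, m = 4, legendre_terms = 50,
                       head_radius = 1) {
  stopifnot(lambda >= 0, m >= 2, legendre_terms >= 10, head_radius > 0)
  structure(list(lambda = lambda, m = m, legendre_terms = legendre_terms,
                 head_radius = head_radius), class = "csd_config")
}

# n_ch x n_ch linear operator: potentials -> CSD (negative surface Laplacian)
csd_operator <- function(positions, config = csd_config()) {
  n <- nrow(positions)
  if (n < 4) stop("CSD needs at least 4 channels")
  cosang <- tcrossprod(positions)
  off <- cosang[upper.tri(cosang)]
  if (any(off > 1 - 1e-10))
    stop("duplicate sensor positions: spline system is rank-deficient")
  K <- spline_kernels(cosang, config$m, config$legendre_terms)
  s <- n / sum(diag(K$g))            # trace normalization
  Gs <- s * K$g + diag(config$lambda, n)
  Hs <- s * K$h
  # KKT system enforcing sum(c) = 0 with a free constant d
  A <- rbind(cbind(Gs, 1), c(rep(1, n), 0))
  Ainv <- solve(A)
  T <- (Hs %*% Ainv[seq_len(n), seq_len(n), drop = FALSE]) / config$head_radius^2
  T
}

#' Current source density (surface Laplacian) transform
#'
#' Fits a regularized spherical spline to the scalp potentials at every time
#' sample and returns the (negative) surface Laplacian at each sensor, i.e.
#' radial current source density up to a conductivity constant. The operation
#' is linear in the input and reference-free: adding a constant to all
#' channels leaves the output unchanged.
#'
#' @param avg An `averaged_epochs` object ([average_conditions()]) or a plain
#'   channel x sample matrix.
#' @param montage A `sensor_montage` (ignored if `avg` carries one).
#' @param config A [csd_config()].
#' @return Same shape as the input, in CSD units.
#' @export
csd_transform <- function(avg, montage = NULL, config = csd_config()) {
  if (is.matrix(avg)) {
    T <- csd_operator(montage$positions, config)
    return(T %*% avg)
  }
  stopifnot(inherits(avg, "averaged_epochs"))
  montage <- montage %||% avg$montage
  T <- csd_operator(montage$positions, config)
  out <- avg
  for (i in seq_len(dim(avg$data)[1]))
    out$data[i, , ] <- T %*% avg$data[i, , ]
  out$units <- "CSD"
  out
}

# Spherical-spline interpolation of bad channels from good ones.
# Returns interpolated values at `bad_pos` given potentials v at `good_pos`.
spline_interpolate <- function(good_pos, v, bad_pos, m = 4, legendre_terms = 50,
                               lambda = 1e-5) {
  n <- nrow(good_pos)
  if (n < 4) stop("spline interpolation needs at least 4 good channels")
  cosang <- tcrossprod(good_pos)
  K <- spline_kernels(cosang, m, legendre_terms)
  s <- n / sum(diag(K$g))
  Gs <- s * K$g + diag(lambda, n)
  A <- rbind(cbind(Gs, 1), c(rep(1, n), 0))
  sol <- solve(A, rbind(v, 0))
  cc <- sol[seq_len(n), , drop = FALSE]
  d <- sol[n + 1, ]
  cross <- tcrossprod(bad_pos, good_pos)
  Kg <- spline_kernels(cross, m, legendre_terms)$g * s
  sweep(Kg %*% cc, 2, d, "+")
}
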