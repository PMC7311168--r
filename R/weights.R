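#' Hypothesis contrast weights over the six stimulus conditions
#'
#' Returns the centered weight vector encoding one of the three candidate
#' response shapes across the conditions CS+, GS1, GS2, GS3, GS4, CS-:
#'
#' * `lateral_inhibition`: a difference-of-Gaussians profile with enhancement
#'   at the threat cue (CS+) and suppression of the most similar morph,
#'   weights (+2, -2, +0.5, +1, +0.5, -2);
#' * `quadratic`: the quadratic trend component of a generalization gradient,
#'   weights (+2.5334, +1.0934, -0.0267, -0.8267, -1.3067, -1.4667);
#' * `linear`: the linear trend, weights (+2.5, +1.5, +0.5, -0.5, -1.5, -2.5).
#'
#' All vectors are centered to sum zero; downstream Bayesian model comparison
#' is invariant to affine transformations of the weights, so centering only
#' fixes a convention.
#'
#' @param name One of `"lateral_inhibition"`, `"quadratic"`, `"linear"`.
#' @return Object of class `contrast_weights`: a named numeric vector of
#'   length 6 in canonical condition order, with attribute `shape`.
#' @export
#' @examples
#' contrast_weights("lateral_inhibition")
contrast_weights <- function(name = c("lateral_inhibition", "quadratic", "linear")) {
  name <- match.arg(name)
  w <- switch(name,
    lateral_inhibition = c(2, -2, 0.5, 1, 0.5, -2),
    quadratic = c(2.5334, 1.0934, -0.0267, -0.8267, -1.3067, -1.4667),
    linear = c(2.5, 1.5, 0.5, -0.5, -1.5, -2.5)
  )
  w <- w - mean(w)
  names(w) <- CONDITIONS
  structure(w, shape = name, class = c("contrast_weights", "numeric"))
}

#' @export
print.contrast_weights <- function(x, ...) {
  cat("Contrast weights (", attr(x, "shape"), "):\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

as_weights <- function(w) {
  if (inherits(w, "contrast_weights")) return(w)
  if (is.character(w) && length(w) == 1L) return(contrast_weights(w))
  if (length(w) != 6L) stop("contrast weights must have exactly 6 elements")
  w <- as.numeric(w) - mean(as.numeric(w))
  names(w) <- CONDITIONS
  structure(w, shape = "custom", class = c("contrast_weights", "numeric"))
}

#' Per-subject visuocortical tuning index
#'
#' The scalar product of a hypothesis weight vector with a subject's six
#' condition-wise pooled SNR values (canonical order CS+, GS1..GS4, CS-).
#' Larger values indicate stronger accentuation of the hypothesized pattern.
#'
#' @param snr Numeric vector of 6 pooled SNR values in canonical condition
#'   order, or a matrix with 6 columns (one row per subject).
#' @param weights A `contrast_weights` object, a shape name, or a length-6
#'   numeric vector.
#' @return Scalar index (or one per row of `snr`).
#' @export
tuning_index <- function(snr, weights = "lateral_inhibition") {
  w <- as_weights(weights)
  if (is.matrix(snr)) {
    if (ncol(snr) != 6L) stop("snr matrix must have 6 columns")
    return(drop(snr %*% as.numeric(w)))
  }
  if (length(snr) != 6L) stop("snr vector must have length 6, got ", length(snr))
  sum(as.numeric(snr) * as.numeric(w))
}

#' Tuning indices for every subject in an SNR table
#'
#' @param snr_table Long-format SNR table (see [compute_snr_table()]).
#' @param weights Weight specification as in [tuning_index()].
#' @param phase Phase to use; default `"generalization"`.
#' @return Data frame with columns `subject_id`, `shape`, `index`, `spai`.
#' @export
tuning_index_table <- function(snr_table, weights = "lateral_inhibition",
                               phase = "generalization") {
  w <- as_weights(weights)
  tab <- snr_table[snr_table$phase == phase, , drop = FALSE]
  wide <- reshape_snr_wide(tab)
  idx <- drop(as.matrix(wide[, CONDITIONS]) %*% as.numeric(w))
  data.frame(subject_id = wide$subject_id, shape = attr(w, "shape"),
             index = idx, spai = wide$spai, stringsAsFactors = FALSE)
}

# subject x condition wide table from long SNR format
reshape_snr_wide <- function(tab) {
  subs <- unique(tab$subject_id)
  out <- data.frame(subject_id = subs, stringsAsFactors = FALSE)
  for (cc in CONDITIONS) {
    m <- tab[tab$condition == cc, ]
    out[[cc]] <- m$snr[match(subs, m$subject_id)]
  }
  out$spai <- tab$spai[match(subs, tab$subject_id)]
  if (anyNA(out[, CONDITIONS]))
    stop("incomplete subject x condition table; missing cells are not allowed")
  out
}
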