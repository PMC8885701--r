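#' Clip probabilities away from 0 and 1
#'
#' Cross-entropy losses and the log-transform used by the calibration-error
#' estimator are undefined at 0 and 1; all score vectors are clipped to
#' `[eps, 1 - eps]` before any log is taken.
#'
#' @param p Numeric vector of probabilities.
#' @param eps Clipping constant; default `1e-7`.
#' @return Numeric vector with values in `[eps, 1 - eps]`.
#' @export
clip_prob <- function(p, eps = 1e-7) {
  stopifnot(is.numeric(p), eps > 0, eps < 0.5)
  pmin(pmax(p, eps), 1 - eps)
}

# elementwise binary cross-entropy; scores assumed already clipped
bce <- function(y, s) -(y * log(s) + (1 - y) * log1p(-s))

#' Derive a reproducible sub-seed from a master seed
#'
#' Every source of randomness in the package (group-wise feature draws,
#' minibatch shuffles, parameter initialization, dropout, bootstrap
#' resampling) is seeded from a named substream of a single master seed, so
#' that adding one component never perturbs the draws of another.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels naming the substream.
#' @return An integer in `[1, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483562
  as.integer(h) + 1L   # in [1, 2147483562], always a valid 32-bit seed
}

# stable per-group integer codes in vocabulary order; errors on stray labels
group_codes <- function(groups, levels) {
  codes <- match(as.character(groups), levels)
  if (anyNA(codes)) {
    bad <- unique(setdiff(as.character(groups), levels))
    abort(paste0("group label(s) not in declared vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  codes
}
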