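#' Dynamic population count from a trajectory matrix
#'
#' Counts, for each spatial label and each time bin, the users whose
#' preferential location falls there: `count(z, t)` is the number of rows of
#' the trajectory matrix equal to `z` at bin `t`. Missing cells count
#' nowhere, so for an interpolated source every column sums to N (the
#' trajectory regularization conserves the population), while a
#' non-interpolated source gives column sums at most N.
#'
#' @param m An [itmatrix()].
#' @return A `popcount`: integer matrix labels x bins (rownames = region or
#'   zone ids), with attributes `resolution`, `level`, `interpolated`, `n_users`.
#' @export
population_count <- function(m) {
  stopifnot(inherits(m, "itmatrix"))
  labs <- attr(m, "labels")
  nl <- length(labs)
  counts <- vapply(seq_len(ncol(m)),
                   function(j) tabulate(unclass(m)[, j], nbins = nl),
                   integer(nl))
  if (nl == 1L) counts <- matrix(counts, nrow = 1L)
  rownames(counts) <- labs
  structure(counts, resolution = attr(m, "resolution"),
            level = attr(m, "level"), interpolated = attr(m, "interpolated"),
            n_users = nrow(m), class = c("popcount", "matrix", "array"))
}

#' @export
print.popcount <- function(x, ...) {
  cat(sprintf("popcount: %d %s(s) x %d %s bins (N = %d users%s)\n",
              nrow(x), attr(x, "level"), ncol(x), attr(x, "resolution"),
              attr(x, "n_users"),
              if (attr(x, "interpolated")) ", interpolated" else ""))
  invisible(x)
}

#' Z-scored seasonal signatures
#'
#' Normalizes each zone's count series to mean 0 and unit variance using the
#' population standard deviation (divide by the series length), so that a
#' series of length n satisfies sum(z) = 0 and sum(z^2) = n exactly. A
#' constant series maps to all zeros. These normalized curves are the
#' seasonal signatures compared across zones and against external series.
#'
#' @param x A `popcount` matrix, a plain matrix (series in rows), or a single
#'   numeric series.
#' @return Same shape as `x`, z-scored row-wise (or the z-scored vector).
#' @examples
#' zscore_signature(c(1, 2, 3))  # -1.2247 0 1.2247
#' @export
zscore_signature <- function(x) {
  zs <- function(v) {
    if (length(v) < 2L) stop("series length must be >= 2")
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (s == 0) rep(0, length(v)) else (v - mu) / s
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, zs))
    dimnames(out) <- dimnames(x)
    out
  } else zs(as.numeric(x))
}

#' Interpolation bias of the population count
#'
#' Quantifies how many users per bin the missing-day interpolation adds to
#' each zone: `bias(z) = 100 * mean_t (interp - raw) / interp`, skipping bins
#' where the interpolated count is zero. The per-bin added-user series is
#' returned too, so early-year concentration of the bias (head backfill) can
#' be inspected.
#'
#' @param raw `popcount` from the non-interpolated matrix.
#' @param interp `popcount` from the interpolated matrix (same shape;
#'   elementwise `>= raw`).
#' @param denominator `"interp"` (default) divides by the completed count;
#'   `"raw"` divides by the observed count instead.
#' @return List with `bias_pct` (named per-zone percentages) and `added`
#'   (zones x bins matrix of added users).
#' @export
interpolation_bias <- function(raw, interp, denominator = c("interp", "raw")) {
  denominator <- match.arg(denominator)
  if (!all(dim(raw) == dim(interp))) stop("count shapes differ")
  if (any(unclass(interp) < unclass(raw)))
    stop("interpolation only adds presence: interp must be >= raw")
  added <- unclass(interp) - unclass(raw)
  den <- if (denominator == "interp") unclass(interp) else unclass(raw)
  bias <- vapply(seq_len(nrow(added)), function(i) {
    ok <- den[i, ] > 0
    if (!any(ok)) return(NA_real_)
    100 * mean(added[i, ok] / den[i, ok])
  }, numeric(1))
  names(bias) <- rownames(raw)
  list(bias_pct = bias, added = added)
}

#' Fraction of spectral power at low frequencies
#'
#' Z-scores the series, takes its discrete Fourier transform, and reports the
#' share of total power (zero-frequency term excluded) carried by the lowest
#' `cutoff_fraction` of the positive frequencies. Values near 1 indicate the
#' slow seasonal variation dominates, justifying coarse time quantization;
#' white noise gives approximately `cutoff_fraction`.
#'
#' @param x Numeric series (length >= 4) or matrix of series in rows.
#' @param cutoff_fraction Fraction of the positive-frequency band counted as
#'   "low" (default 0.1).
#' @return Fraction in \[0, 1\] (vector for matrix input). A constant series
#'   returns NA.
#' @export
low_frequency_fraction <- function(x, cutoff_fraction = 0.1) {
  lf <- function(v) {
    if (length(v) < 4L) stop("series length must be >= 4")
    z <- zscore_signature(v)
    if (all(z == 0)) return(NA_real_)
    p <- Mod(stats::fft(z))^2
    half <- floor(length(v) / 2)
    pw <- p[2:(half + 1L)]  # positive frequencies, DC excluded
    nlow <- max(1L, floor(cutoff_fraction * half))
    sum(pw[seq_len(nlow)]) / sum(pw)
  }
  if (is.matrix(x)) apply(x, 1L, lf) else lf(as.numeric(x))
}
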