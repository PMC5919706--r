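#' Rescale one zone's external series to signature scale
#'
#' Z-scores (population standard deviation) the zone's row of an external
#' series so it can be overlaid on the z-scored population-count signatures.
#' A constant series maps to zeros; rescaling preserves the location of the
#' peak.
#'
#' @param series An [external_series()].
#' @param zone Zone id (a rowname of the series).
#' @return Numeric z-scored series.
#' @export
rescale_to_signature <- function(series, zone) {
  stopifnot(inherits(series, "external_series"))
  zone <- as.character(zone)
  if (!zone %in% rownames(series$values))
    stop("zone ", zone, " not in series '", series$name, "'")
  v <- series$values[zone, ]
  if (anyNA(v)) stop("zone ", zone, " has missing cells in '", series$name, "'")
  zscore_signature(v)
}

#' Lagged correlation between a profile signature and an external signature
#'
#' Pearson (or Spearman) correlation at each integer lag in
#' `-lag_range..lag_range`, computed over the overlapping window after
#' shifting (no wrap-around): at lag L the pairing is `a[t]` with `b[t+L]`,
#' so a positive lag at the maximum means `b` trails `a`. The correlation is
#' flagged undefined (NA) when the overlap is shorter than 3 bins or either
#' windowed series is constant.
#'
#' @param a,b Numeric series of equal length (same resolution).
#' @param lag_range Maximum absolute lag in bins (default 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `lag, correlation, n` (n = overlap length).
#' @export
correlate_series <- function(a, b, lag_range = 3L,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("series must have equal length")
  n <- length(a)
  lags <- seq.int(-lag_range, lag_range)
  rows <- lapply(lags, function(L) {
    ia <- seq.int(max(1L, 1L - L), min(n, n - L))
    ib <- ia + L
    if (length(ia) < 3L)
      return(data.frame(lag = L, correlation = NA_real_, n = length(ia)))
    wa <- a[ia]; wb <- b[ib]
    if (stats::sd(wa) == 0 || stats::sd(wb) == 0)
      return(data.frame(lag = L, correlation = NA_real_, n = length(ia)))
    data.frame(lag = L, correlation = stats::cor(wa, wb, method = method),
               n = length(ia))
  })
  do.call(rbind, rows)
}

#' Align external-series onsets with profile-curve changes
#'
#' For each zone: the onset month of the external series (first bin reaching
#' `onset_frac` of the zone's peak value), the month of the largest absolute
#' month-over-month change of each mobility-profile curve (with its sign),
#' and the lag between them in months. A modal lag of 0 across rural zones
#' indicates the profile switch coincides with e.g. the rainfall onset.
#'
#' @param profiles Named list of `mobility_profiles`, one per zone (names =
#'   zone ids), or a single `mobility_profiles` with a `target_zone`.
#' @param series An [external_series()] at monthly resolution.
#' @param onset_frac Fraction of the peak defining onset (default 0.5).
#' @return data.frame `zone, profile, onset_month, change_month, change_sign,
#'   lag`.
#' @export
event_alignment_report <- function(profiles, series, onset_frac = 0.5) {
  stopifnot(inherits(series, "external_series"))
  if (series$resolution != "monthly")
    stop("alignment report is defined at monthly resolution")
  if (inherits(profiles, "mobility_profiles")) {
    zn <- profiles$target_zone
    if (is.null(zn)) stop("profile set lacks a target zone")
    profiles <- stats::setNames(list(profiles), zn)
  }
  rows <- list()
  for (zone in names(profiles)) {
    v <- series$values[as.character(zone), ]
    onset <- which(v >= onset_frac * max(v))[1L]
    ps <- profiles[[zone]]
    for (c in seq_len(ps$k)) {
      dcurve <- diff(ps$curves[c, ])
      cm <- which.max(abs(dcurve)) + 1L  # change lands on the later month
      rows[[length(rows) + 1L]] <- data.frame(
        zone = as.character(zone), profile = c,
        onset_month = onset, change_month = cm,
        change_sign = sign(dcurve[cm - 1L]),
        lag = cm - onset)
    }
  }
  do.call(rbind, rows)
}
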