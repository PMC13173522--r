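# Extracted-ion chromatograms and the cumulative-intensity retention
# metric (%CI): the percentage of a formula's summed DOM XIC intensity
# that has eluted by a probe compound's retention time.

#' Extract an ion chromatogram from MS1 scans
#'
#' One point per MS1 scan: the summed intensity of all peaks within
#' `+/- tol_ppm` of `target_mz`. Scans with no matching peak contribute
#' zeros, so the XIC shares the run's time grid.
#'
#' @param scans List of `ms1_scan` objects (strictly increasing rt).
#' @param target_mz Target m/z (Da).
#' @param tol_ppm Window half-width in ppm (> 0, default 5).
#' @return An `xic` object with fields `target_mz`, `tol_ppm`, `rt`,
#'   `intensity`.
#' @export
extract_xic <- function(scans, target_mz, tol_ppm = 5) {
  if (!length(scans)) stop("no MS1 scans to extract from")
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  .check_run(scans)
  half <- target_mz * tol_ppm * 1e-6
  rt <- vapply(scans, function(s) s$rt, numeric(1))
  intensity <- vapply(scans, function(s) {
    pl <- s$peaks
    if (!n_peaks(pl)) return(0)
    sum(pl$intensity[abs(pl$mz - target_mz) <= half])
  }, numeric(1))
  structure(list(target_mz = target_mz, tol_ppm = tol_ppm,
                 rt = rt, intensity = intensity),
            class = "xic")
}

#' Construct an XIC directly from retention-time/intensity series
#'
#' @param rt Strictly increasing retention times (minutes).
#' @param intensity Non-negative intensities, same length.
#' @param target_mz,tol_ppm Optional provenance fields.
#' @return An `xic` object.
#' @export
xic <- function(rt, intensity, target_mz = NA_real_, tol_ppm = NA_real_) {
  if (length(rt) != length(intensity)) stop("rt and intensity lengths differ")
  if (length(rt) > 1 && any(diff(rt) <= 0)) stop("rt must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(target_mz = target_mz, tol_ppm = tol_ppm,
                 rt = as.numeric(rt), intensity = as.numeric(intensity)),
            class = "xic")
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> target m/z %s  %d scans  rt %.2f-%.2f min  total %.4g\n",
              if (is.na(x$target_mz)) "?" else sprintf("%.4f", x$target_mz),
              length(x$rt), min(x$rt), max(x$rt), sum(x$intensity)))
  invisible(x)
}

#' @export
plot.xic <- function(x, ...) {
  plot(x$rt, x$intensity, type = "l", xlab = "retention time (min)",
       ylab = "intensity",
       main = if (is.na(x$target_mz)) "XIC" else sprintf("XIC m/z %.4f", x$target_mz),
       ...)
  invisible(x)
}

# Cumulative trapezoid-integrated intensity at every scan point; first
# point 0. The cumulative curve is then taken piecewise linear between
# scan points (both forward evaluation and inversion use this same curve,
# so percent_ci and ci_profile are exact inverses of each other).
.cum_trapz <- function(rt, intensity) {
  n <- length(rt)
  if (n == 1L) return(0)
  c(0, cumsum(diff(rt) * (intensity[-n] + intensity[-1]) / 2))
}

#' Percentage of cumulative XIC intensity eluted by a probe time
#'
#' `percent_ci(x, t)` is 100 times the fraction of the XIC's
#' trapezoid-integrated intensity that has eluted by retention time `t`,
#' with linear interpolation between scan points. Values are clamped to
#' [0, 100]; a probe before the first scan gives 0 and a probe after the
#' last scan gives 100.
#'
#' @param xic An `xic` with positive total intensity.
#' @param probe_rt Probe retention time in minutes.
#' @return %CI in [0, 100]. Vectorized over `probe_rt`.
#' @export
percent_ci <- function(xic, probe_rt) {
  if (!inherits(xic, "xic")) stop("xic must be an 'xic' object")
  cum <- .cum_trapz(xic$rt, xic$intensity)
  total <- cum[length(cum)]
  if (total <= 0) stop("formula absent from DOM sample (zero-total XIC)")
  vapply(probe_rt, function(t) {
    if (t <= xic$rt[1]) return(0)
    if (t >= xic$rt[length(xic$rt)]) return(100)
    val <- stats::approx(xic$rt, cum, xout = t)$y
    min(100, max(0, 100 * val / total))
  }, numeric(1))
}

#' Percentile elution profile of an XIC
#'
#' For each requested percentile p, the earliest retention time at which
#' the cumulative intensity fraction reaches p/100 (linear interpolation
#' between scan points; plateaus resolve to the earliest qualifying time).
#'
#' @param xic An `xic` with positive total intensity.
#' @param percentiles Percentiles to report (default the 5-95% set).
#' @return A `ci_profile`: list with `percentiles` (named rt vector) and
#'   `total_intensity`.
#' @export
ci_profile <- function(xic, percentiles = c(5, 10, 25, 50, 75, 90, 95)) {
  if (!inherits(xic, "xic")) stop("xic must be an 'xic' object")
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100")
  }
  cum <- .cum_trapz(xic$rt, xic$intensity)
  total <- cum[length(cum)]
  if (total <= 0) stop("formula absent from DOM sample (zero-total XIC)")
  frac <- cum / total
  rts <- vapply(percentiles, function(p) {
    target <- p / 100
    i <- which(frac >= target - 1e-12)[1]  # earliest point at/above target
    if (i == 1L) return(xic$rt[1])
    if (frac[i] <= frac[i - 1]) return(xic$rt[i])  # flat segment ends here
    xic$rt[i - 1] + (target - frac[i - 1]) / (frac[i] - frac[i - 1]) *
      (xic$rt[i] - xic$rt[i - 1])
  }, numeric(1))
  structure(list(percentiles = stats::setNames(rts, percentiles),
                 total_intensity = total),
            class = "ci_profile")
}

#' @export
print.ci_profile <- function(x, ...) {
  cat("<ci_profile>  total integrated intensity", format(x$total_intensity), "\n")
  print(round(x$percentiles, 4))
  invisible(x)
}

#' %CI for a table of probe compounds against a reference run
#'
#' For each compound the target m/z is derived from its neutral CHO
#' formula as the deprotonated anion; the XIC is extracted from the
#' reference run and %CI evaluated at each isomer's retention time.
#' Compounds whose formula is absent from the reference sample are
#' flagged (`status = "absent"`) rather than aborting the batch.
#'
#' @param compounds A data.frame with columns `compound_id`, `formula`
#'   (Hill string) and `rt` (isomer retention time, minutes); one row per
#'   isomer.
#' @param scans Reference-run MS1 scans (e.g. the DOM standard).
#' @param tol_ppm XIC extraction tolerance in ppm.
#' @param averaging `"per_isomer"` returns only individual rows;
#'   `"mean"` (default) appends one arithmetic-mean row per compound.
#' @return A data.frame with columns `compound_id`, `isomer`, `formula`,
#'   `target_mz`, `rt`, `pct_ci`, `status`; mean rows carry
#'   `isomer = "mean"` and `rt = NA`.
#' @export
compound_ci <- function(compounds, scans, tol_ppm = 5,
                        averaging = c("mean", "per_isomer")) {
  averaging <- match.arg(averaging)
  need <- c("compound_id", "formula", "rt")
  if (!all(need %in% names(compounds))) {
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (id in unique(compounds$compound_id)) {
    sub <- compounds[compounds$compound_id == id, ]
    if (!nrow(sub)) next
    target <- mz_deprotonated(sub$formula[1])
    x <- extract_xic(scans, target, tol_ppm)
    absent <- sum(x$intensity) <= 0
    vals <- if (absent) rep(NA_real_, nrow(sub)) else percent_ci(x, sub$rt)
    out[[length(out) + 1L]] <- data.frame(
      compound_id = id, isomer = as.character(seq_len(nrow(sub))),
      formula = sub$formula[1], target_mz = target, rt = sub$rt,
      pct_ci = vals, status = if (absent) "absent" else "ok"
    )
    if (averaging == "mean") {
      out[[length(out) + 1L]] <- data.frame(
        compound_id = id, isomer = "mean", formula = sub$formula[1],
        target_mz = target, rt = NA_real_,
        pct_ci = if (absent) NA_real_ else mean(vals),
        status = if (absent) "absent" else "ok"
      )
    }
  }
  do.call(rbind, out)
}
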