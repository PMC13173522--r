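# Data model for centroided LC-MS runs: peak lists, MS1 scans, MS2 spectra,
# plus readers/writers for the plain-text fixture dialect and mzML (via mzR).

#' Construct a centroided peak list
#'
#' Peaks are stored sorted ascending by m/z; intensities travel with their
#' m/z values. NaN/NA values are rejected.
#'
#' @param mz Numeric vector of m/z values (Da).
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @return A `peak_list` (data.frame with columns `mz`, `intensity`).
#' @export
peak_list <- function(mz = numeric(0), intensity = numeric(0)) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (anyNA(mz) || anyNA(intensity) || any(is.nan(mz)) || any(is.nan(intensity))) {
    stop("peak list may not contain NA/NaN")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  ord <- order(mz)
  structure(
    data.frame(mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord])),
    class = c("peak_list", "data.frame")
  )
}

#' Number of peaks in a peak list
#' @param pl A `peak_list`.
#' @return Integer count.
#' @export
n_peaks <- function(pl) nrow(pl)

#' Summed intensity of a peak list
#' @param pl A `peak_list`.
#' @return Total intensity.
#' @export
total_intensity <- function(pl) sum(pl$intensity)

#' Construct an MS1 scan
#'
#' @param rt Retention time in minutes (>= 0).
#' @param peaks A `peak_list`.
#' @return An `ms1_scan` object.
#' @export
ms1_scan <- function(rt, peaks = peak_list()) {
  if (!is.numeric(rt) || length(rt) != 1L || is.na(rt) || rt < 0) {
    stop("rt must be a single non-negative number (minutes)")
  }
  structure(list(rt = as.numeric(rt), peaks = peaks), class = "ms1_scan")
}

#' Construct an MS2 spectrum
#'
#' @param precursor_target_mz Target m/z of the isolation window.
#' @param peaks A `peak_list` of fragment peaks.
#' @param nce Normalized collision energy; must belong to `allowed_nce`.
#' @param isolation_halfwidth Isolation half-width in Da (> 0, default 0.7).
#' @param sample_id Sample identifier.
#' @param rt Acquisition retention time in minutes.
#' @param allowed_nce Permitted collision energies (default low/high HCD
#'   settings 35 and 75).
#' @return An `ms2_spectrum` object.
#' @export
ms2_spectrum <- function(precursor_target_mz, peaks = peak_list(), nce = 35,
                         isolation_halfwidth = 0.7, sample_id = "sample",
                         rt = 0, allowed_nce = c(35, 75)) {
  if (precursor_target_mz <= 0) stop("precursor_target_mz must be positive")
  if (isolation_halfwidth <= 0) stop("isolation_halfwidth must be positive")
  if (!is.null(allowed_nce) && !nce %in% allowed_nce) {
    stop("nce ", nce, " not in the configured set {",
         paste(allowed_nce, collapse = ", "), "}")
  }
  structure(
    list(precursor_target_mz = as.numeric(precursor_target_mz),
         isolation_halfwidth = as.numeric(isolation_halfwidth),
         nce = as.numeric(nce), peaks = peaks,
         sample_id = as.character(sample_id), rt = as.numeric(rt)),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2> %s  precursor %.4f +/- %.2f Da  NCE %g  rt %.2f min  %d peaks\n",
              x$sample_id, x$precursor_target_mz, x$isolation_halfwidth,
              x$nce, x$rt, n_peaks(x$peaks)))
  invisible(x)
}

#' @export
print.ms1_scan <- function(x, ...) {
  cat(sprintf("<ms1> rt %.3f min  %d peaks  TIC %.3g\n",
              x$rt, n_peaks(x$peaks), total_intensity(x$peaks)))
  invisible(x)
}

.check_run <- function(ms1) {
  rts <- vapply(ms1, function(s) s$rt, numeric(1))
  if (length(rts) > 1 && any(diff(rts) <= 0)) {
    stop("MS1 scans must be strictly increasing in retention time")
  }
  invisible(TRUE)
}

.flag_range <- function(pl, mz_range = c(150, 1000)) {
  out <- pl$mz < mz_range[1] | pl$mz > mz_range[2]
  attr(pl, "out_of_range") <- out
  pl
}

#' Read an LC-MS run
#'
#' Supported formats: the package's plain-text fixture CSV dialect
#' (columns `scan_type, rt, precursor_mz, nce, mz, intensity`; one row per
#' peak, MS2 spectra grouped by `(rt, precursor_mz, nce)`), and mzML via
#' the `mzR` package. Peaks are returned sorted by m/z, scans ordered by
#' retention time; peaks outside the nominal instrument range (150-1000 Da
#' by default) are retained but flagged via the `out_of_range` attribute
#' on the peak list.
#'
#' @param path File path.
#' @param format `"fixture_csv"` or `"mzml"`.
#' @param sample_id Sample label attached to MS2 spectra; defaults to the
#'   file name without extension.
#' @param mz_range Instrument m/z range used for flagging.
#' @param centroided For mzML: assert that spectra are centroided. Profile
#'   spectra are rejected unless `centroided = TRUE` overrides the file's
#'   own metadata.
#' @return A list with elements `ms1` (list of `ms1_scan`) and `ms2`
#'   (list of `ms2_spectrum`).
#' @export
read_run <- function(path, format = c("fixture_csv", "mzml"),
                     sample_id = NULL, mz_range = c(150, 1000),
                     centroided = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
    fixture_csv = .read_fixture_csv(path, sample_id, mz_range),
    mzml = .read_mzml(path, sample_id, mz_range, centroided)
  )
}

.read_fixture_csv <- function(path, sample_id, mz_range) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_type", "rt", "precursor_mz", "nce", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("fixture CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$scan_type %in% c("ms1", "ms2"))) {
    bad <- which(!df$scan_type %in% c("ms1", "ms2"))[1]
    stop("malformed fixture row ", bad, ": scan_type must be ms1 or ms2")
  }
  ms1_df <- df[df$scan_type == "ms1", ]
  ms2_df <- df[df$scan_type == "ms2", ]

  ms1 <- list()
  if (nrow(ms1_df)) {
    for (rt in sort(unique(ms1_df$rt))) {
      sub <- ms1_df[ms1_df$rt == rt, ]
      empty <- nrow(sub) == 1L && is.na(sub$mz[1])
      pl <- if (empty) peak_list() else peak_list(sub$mz, sub$intensity)
      ms1[[length(ms1) + 1L]] <- ms1_scan(rt, .flag_range(pl, mz_range))
    }
  }
  .check_run(ms1)

  ms2 <- list()
  if (nrow(ms2_df)) {
    key <- paste(ms2_df$rt, ms2_df$precursor_mz, ms2_df$nce)
    for (k in unique(key[order(ms2_df$rt)])) {
      sub <- ms2_df[key == k, ]
      empty <- nrow(sub) == 1L && is.na(sub$mz[1])
      pl <- if (empty) peak_list() else peak_list(sub$mz, sub$intensity)
      ms2[[length(ms2) + 1L]] <- ms2_spectrum(
        precursor_target_mz = sub$precursor_mz[1],
        peaks = .flag_range(pl, mz_range),
        nce = sub$nce[1], sample_id = sample_id, rt = sub$rt[1],
        allowed_nce = NULL
      )
    }
  }
  list(ms1 = ms1, ms2 = ms2)
}

.read_mzml <- function(path, sample_id, mz_range, centroided) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms1 <- list(); ms2 <- list()
  for (i in seq_len(nrow(hdr))) {
    if (!centroided && isFALSE(hdr$centroided[i])) {
      stop("scan ", i, " is profile mode; set centroided = TRUE to override")
    }
    pk <- mzR::peaks(handle, i)
    pl <- .flag_range(peak_list(pk[, 1], pk[, 2]), mz_range)
    rt_min <- hdr$retentionTime[i] / 60  # mzML stores seconds
    if (hdr$msLevel[i] == 1L) {
      ms1[[length(ms1) + 1L]] <- ms1_scan(rt_min, pl)
    } else if (hdr$msLevel[i] == 2L) {
      hw <- hdr$isolationWindowUpperOffset[i]
      if (is.na(hw) || hw <= 0) hw <- 0.7
      nce <- hdr$collisionEnergy[i]
      ms2[[length(ms2) + 1L]] <- ms2_spectrum(
        precursor_target_mz = hdr$precursorMZ[i], peaks = pl,
        nce = if (is.na(nce)) 35 else nce, isolation_halfwidth = hw,
        sample_id = sample_id, rt = rt_min, allowed_nce = NULL
      )
    }
  }
  .check_run(ms1)
  list(ms1 = ms1, ms2 = ms2)
}

#' Write a run in the fixture CSV dialect
#'
#' Inverse of [read_run()] for `format = "fixture_csv"`; the round trip is
#' lossless for the fields of the dialect.
#'
#' @param run List with `ms1` and `ms2` components as returned by
#'   [read_run()] or [simulate_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(run, path) {
  rows <- list()
  for (s in run$ms1) {
    rows[[length(rows) + 1L]] <- if (n_peaks(s$peaks) == 0) {
      data.frame(scan_type = "ms1", rt = s$rt, precursor_mz = NA_real_,
                 nce = NA_real_, mz = NA_real_, intensity = NA_real_)
    } else {
      data.frame(scan_type = "ms1", rt = s$rt, precursor_mz = NA_real_,
                 nce = NA_real_, mz = s$peaks$mz, intensity = s$peaks$intensity)
    }
  }
  for (s in run$ms2) {
    rows[[length(rows) + 1L]] <- if (n_peaks(s$peaks) == 0) {
      data.frame(scan_type = "ms2", rt = s$rt, precursor_mz = s$precursor_target_mz,
                 nce = s$nce, mz = NA_real_, intensity = NA_real_)
    } else {
      data.frame(scan_type = "ms2", rt = s$rt, precursor_mz = s$precursor_target_mz,
                 nce = s$nce, mz = s$peaks$mz, intensity = s$peaks$intensity)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan_type = character(0), rt = numeric(0), precursor_mz = numeric(0),
               nce = numeric(0), mz = numeric(0), intensity = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fragmentation-metrics table
#'
#' One row per (sample, target, collision energy) with the four metrics
#' and a reference to the per-peak assignment ledger. Rows are sorted
#' (sample, target, nce) so repeated writes are byte-identical.
#'
#' @param records A data.frame with columns `sample`, `target`, `nce`,
#'   `pct_parent`, `pct_fg`, `avg_frag`, `pct_radical` and optionally
#'   `ledger_ref`, or a list of such one-row records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  cols <- c("sample", "target", "nce", "pct_parent", "pct_fg",
            "avg_frag", "pct_radical", "ledger_ref")
  if (is.data.frame(records)) df <- records
  else if (is.list(records)) df <- do.call(rbind, lapply(records, as.data.frame))
  else stop("records must be a data.frame or a list of rows")
  if (is.null(df) || nrow(df) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    if (!"ledger_ref" %in% names(df)) df$ledger_ref <- ""
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
    df <- df[order(df$sample, df$target, df$nce), cols]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample = "character", ledger_ref = "character"))
}
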