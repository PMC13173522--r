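# The four per-spectrum HCD fragmentation metrics:
#   %Parent  - intensity remaining as the parent ion
#   %FG      - intensity in CO2/H2O/CH4O (sequential) neutral-loss peaks
#   Avg Frag - intensity-weighted mean fragment m/z
#   %Radical - intensity assignable to odd-electron radical anions
# plus neutral-loss enumeration and the mass-defect contaminant filter.

.LOSS_SPECIES <- c(CO2 = "CO2", H2O = "H2O", CH4O = "CH4O")

#' Total neutral mass of a CO2/H2O/CH4O loss combination
#'
#' @param n_co2,n_h2o,n_ch4o Non-negative loss counts.
#' @return Neutral mass in Da.
#' @export
loss_mass <- function(n_co2, n_h2o, n_ch4o) {
  n_co2 * monoisotopic_mass("CO2") +
    n_h2o * monoisotopic_mass("H2O") +
    n_ch4o * monoisotopic_mass("CH4O")
}

#' Enumerate feasible sequential CO2/H2O/CH4O neutral-loss combinations
#'
#' All combinations of `a` CO2 + `b` H2O + `c` CH4O losses with
#' `1 <= a+b+c <= max_total` whose residual fragment formula is chemically
#' feasible: non-negative element counts, at least one hydrogen (the
#' fragment must be observable as a closed-shell `[frag-H]-` anion) and
#' RDBE of the neutral fragment >= 0. Combinations relate to carboxylic
#' acid (CO2), alcohol (H2O) and aliphatic methyl ether (CH4O)
#' fragmentation channels.
#'
#' @param parent Neutral parent formula (string or `mol_formula`).
#' @param max_total Maximum total number of losses (default 8, giving
#'   headroom over the deepest ladders seen in natural DOM spectra, e.g.
#'   5x CO2 with associated water losses).
#' @return A `loss_table` data.frame, sorted by `neutral_mass`, with
#'   columns `n_co2`, `n_h2o`, `n_ch4o`, `neutral_mass`, `fragment`
#'   (Hill string of the residual neutral) and `fragment_mz`
#'   (the `[frag-H]-` m/z).
#' @examples
#' enumerate_losses("C2H4O2", max_total = 3)  # acetic acid: CO2 or H2O only
#' @export
enumerate_losses <- function(parent, max_total = 8) {
  if (max_total < 1) stop("max_total must be >= 1")
  p <- parse_formula(parent)
  if (p[["H"]] < 1L) stop("parent must be deprotonatable (H >= 1)")
  grid <- expand.grid(n_co2 = 0:max_total, n_h2o = 0:max_total,
                      n_ch4o = 0:max_total)
  tot <- grid$n_co2 + grid$n_h2o + grid$n_ch4o
  grid <- grid[tot >= 1 & tot <= max_total, ]
  fC <- p[["C"]] - grid$n_co2 - grid$n_ch4o
  fH <- p[["H"]] - 2 * grid$n_h2o - 4 * grid$n_ch4o
  fO <- p[["O"]] - 2 * grid$n_co2 - grid$n_h2o - grid$n_ch4o
  dbe <- fC - fH / 2 + 1
  keep <- fC >= 0 & fH >= 1 & fO >= 0 & dbe >= 0
  grid <- grid[keep, ]
  fC <- fC[keep]; fH <- fH[keep]; fO <- fO[keep]
  grid$neutral_mass <- loss_mass(grid$n_co2, grid$n_h2o, grid$n_ch4o)
  grid$fragment <- vapply(seq_len(nrow(grid)), function(i) {
    format(mol_formula(c(C = fC[i], H = fH[i], O = fO[i])))
  }, character(1))
  grid$fragment_mz <- mz_deprotonated(p) - grid$neutral_mass
  grid <- grid[order(grid$neutral_mass), ]
  rownames(grid) <- NULL
  class(grid) <- c("loss_table", "data.frame")
  grid
}

#' Mass-defect filter for likely halogenated contaminants
#'
#' Negative-mode CHO ions in the DOM mass range have fractional m/z
#' (mass defects) below 0.5, while chlorinated/brominated anthropogenic
#' pollutants fall between x.5 and x.0. Peaks with fractional part in
#' [0.0, 0.5) are kept; the rest are excluded (half-open convention, so a
#' fractional part of exactly 0.5 is excluded).
#'
#' @param peaks A `peak_list`.
#' @return List with `kept` and `excluded` peak lists.
#' @export
halogen_mass_defect_filter <- function(peaks) {
  frac <- peaks$mz - floor(peaks$mz)
  keep <- frac < 0.5
  list(kept = peak_list(peaks$mz[keep], peaks$intensity[keep]),
       excluded = peak_list(peaks$mz[!keep], peaks$intensity[!keep]))
}

.match_ppm <- function(mz, targets, tol_ppm) {
  # index of closest target within tolerance, NA otherwise
  vapply(mz, function(m) {
    if (!length(targets)) return(NA_integer_)
    d <- abs(targets - m) / m * 1e6
    i <- which.min(d)
    if (d[i] <= tol_ppm) i else NA_integer_
  }, integer(1))
}

.frag_metrics <- function(ledger, raw_total, filtered_total, sample_id = NA,
                          target = NA, nce = NA) {
  pct <- function(cat) {
    if (filtered_total <= 0) return(0)
    100 * sum(ledger$intensity[ledger$category == cat]) / filtered_total
  }
  nonparent <- ledger$category %in% c("fg", "radical", "unassigned")
  avg_frag <- if (any(nonparent) && sum(ledger$intensity[nonparent]) > 0) {
    sum(ledger$mz[nonparent] * ledger$intensity[nonparent]) /
      sum(ledger$intensity[nonparent])
  } else NA_real_
  structure(
    list(pct_parent = pct("parent"), pct_fg = pct("fg"),
         pct_radical = pct("radical"), avg_frag = avg_frag,
         ledger = ledger, raw_total = raw_total,
         filtered_total = filtered_total,
         sample_id = sample_id, target = target, nce = nce),
    class = "frag_metrics"
  )
}

#' @export
print.frag_metrics <- function(x, ...) {
  cat(sprintf("<frag_metrics>%s  %%Parent %.1f  %%FG %.1f  %%Radical %.1f  AvgFrag %s\n",
              if (is.na(x$target)) "" else paste0(" ", x$target),
              x$pct_parent, x$pct_fg, x$pct_radical,
              if (is.na(x$avg_frag)) "undefined" else sprintf("%.1f", x$avg_frag)))
  cat(sprintf("  %d peaks; raw total %.4g, after mass-defect filter %.4g\n",
              nrow(x$ledger), x$raw_total, x$filtered_total))
  invisible(x)
}

#' @export
as.data.frame.frag_metrics <- function(x, ...) {
  data.frame(sample = as.character(x$sample_id), target = as.character(x$target),
             nce = as.numeric(x$nce), pct_parent = x$pct_parent,
             pct_fg = x$pct_fg, avg_frag = x$avg_frag,
             pct_radical = x$pct_radical)
}

# Core per-peak assignment shared by single-compound and DOM modes.
# parent_mzs: m/z values counted as surviving parent ion.
# fg_targets: data.frame(mz, label) of neutral-loss fragment targets.
.assign_peaks <- function(peaks, parent_mzs, fg_targets, tol_ppm,
                          radical_bounds, mass_defect_filter = TRUE) {
  filt <- if (mass_defect_filter) halogen_mass_defect_filter(peaks) else
    list(kept = peaks, excluded = peak_list())
  ledger <- rbind(
    if (n_peaks(filt$kept)) data.frame(mz = filt$kept$mz,
                                       intensity = filt$kept$intensity,
                                       category = "pending", detail = ""),
    if (n_peaks(filt$excluded)) data.frame(mz = filt$excluded$mz,
                                           intensity = filt$excluded$intensity,
                                           category = "excluded_halogen",
                                           detail = "")
  )
  pending <- ledger$category == "pending"
  # parent first: precedence parent > fg > radical keeps categories disjoint
  pm <- .match_ppm(ledger$mz[pending], parent_mzs, tol_ppm)
  idx <- which(pending)[!is.na(pm)]
  ledger$category[idx] <- "parent"
  ledger$detail[idx] <- sprintf("parent m/z %.6f", parent_mzs[pm[!is.na(pm)]])

  pending <- ledger$category == "pending"
  fm <- .match_ppm(ledger$mz[pending], fg_targets$mz, tol_ppm)
  idx <- which(pending)[!is.na(fm)]
  ledger$category[idx] <- "fg"
  ledger$detail[idx] <- fg_targets$label[fm[!is.na(fm)]]

  for (i in which(ledger$category == "pending")) {
    ion <- assign_formula(ledger$mz[i], bounds = radical_bounds,
                          tol_ppm = tol_ppm)
    if (!is.null(ion) && ion$electron_config == "odd_electron_radical") {
      ledger$category[i] <- "radical"
      ledger$detail[i] <- paste0(format(ion$formula), ".-")
    } else {
      ledger$category[i] <- "unassigned"
      if (!is.null(ion)) ledger$detail[i] <- paste0("[", format(ion$formula), "-H]-")
    }
  }
  list(ledger = ledger,
       raw_total = total_intensity(peaks),
       filtered_total = total_intensity(filt$kept))
}

#' Fragmentation metrics for a spectrum of a known compound
#'
#' Single-compound mode: the parent formula is known, the parent ion is
#' its `[M-H]-` peak, and the functional-group (FG) targets are the
#' feasible CO2/H2O/CH4O loss combinations from [enumerate_losses()].
#' All percentages are relative to the total intensity of the
#' mass-defect-filtered spectrum (both the raw and filtered totals are
#' recorded); Avg Frag is the intensity-weighted mean m/z over non-parent
#' (kept) peaks. Assignment precedence is parent > fg > radical, so the
#' intensity categories are disjoint and, together with `unassigned` and
#' `excluded_halogen`, sum exactly to the raw spectrum total.
#'
#' @param spectrum An `ms2_spectrum` with at least one peak.
#' @param parent Neutral parent formula (string or `mol_formula`, H >= 1).
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @param max_total Maximum loss depth passed to [enumerate_losses()].
#' @param radical_bounds Element bounds for the per-peak radical search.
#' @param mass_defect_filter Apply the halogen mass-defect filter before
#'   assignment (default TRUE); FALSE reproduces the "all mass defects"
#'   variant of the metrics.
#' @return A `frag_metrics` object.
#' @export
compute_metrics_single <- function(spectrum, parent, tol_ppm = 5,
                                   max_total = 8,
                                   radical_bounds = c(C = 40, H = 60, O = 25),
                                   mass_defect_filter = TRUE) {
  if (!inherits(spectrum, "ms2_spectrum")) stop("spectrum must be an 'ms2_spectrum'")
  if (n_peaks(spectrum$peaks) == 0) stop("empty spectrum")
  if (total_intensity(spectrum$peaks) <= 0) stop("spectrum has zero total intensity")
  p <- parse_formula(parent)
  losses <- enumerate_losses(p, max_total)
  fg_targets <- data.frame(
    mz = losses$fragment_mz,
    label = sprintf("-%dxCO2 -%dxH2O -%dxCH4O -> %s",
                    losses$n_co2, losses$n_h2o, losses$n_ch4o, losses$fragment)
  )
  res <- .assign_peaks(spectrum$peaks, mz_deprotonated(p), fg_targets,
                       tol_ppm, radical_bounds, mass_defect_filter)
  .frag_metrics(res$ledger, res$raw_total, res$filtered_total,
                sample_id = spectrum$sample_id, target = format(p),
                nce = spectrum$nce)
}

#' Fragmentation metrics for a DOM spectrum at a nominal mass
#'
#' DOM mode: the precursor population is taken from the MS1 scan nearest
#' in retention time — every MS1 peak inside the isolation window around
#' the nominal mass, above a relative intensity floor, that admits a CHO
#' formula assignment. The parent intensity is MS2 intensity matching any
#' precursor m/z (so parents completely labile to fragmentation still
#' anchor the loss ladders), and the FG target set is the union of loss
#' enumerations over all assigned precursor formulas, deduplicated so a
#' target shared by two precursors is counted once.
#'
#' @param ms1 An `ms1_scan`, or a list of scans (nearest in rt is used).
#' @param spectrum The `ms2_spectrum` acquired at the nominal mass.
#' @param nominal_mass Integer nominal mass of the precursor group.
#' @param tol_ppm Matching tolerance in ppm.
#' @param isolation_halfwidth Isolation half-width in Da; defaults to the
#'   spectrum's own value.
#' @param min_rel_intensity Precursors below this fraction of the base
#'   peak in the window are ignored as noise (default 0.001).
#' @param max_total,radical_bounds,mass_defect_filter As in
#'   [compute_metrics_single()].
#' @param assign_bounds Element bounds for precursor formula assignment.
#' @return A `frag_metrics` object; its `precursors` attribute records the
#'   assigned precursor set.
#' @export
compute_metrics_dom <- function(ms1, spectrum, nominal_mass, tol_ppm = 5,
                                isolation_halfwidth = NULL,
                                min_rel_intensity = 0.001, max_total = 8,
                                assign_bounds = c(C = 40, H = 60, O = 25),
                                radical_bounds = c(C = 40, H = 60, O = 25),
                                mass_defect_filter = TRUE) {
  if (!inherits(spectrum, "ms2_spectrum")) stop("spectrum must be an 'ms2_spectrum'")
  if (n_peaks(spectrum$peaks) == 0) stop("empty spectrum")
  if (nominal_mass < 150 || nominal_mass > 1000) {
    stop("nominal mass ", nominal_mass, " outside the instrument range 150-1000 Da")
  }
  if (inherits(ms1, "ms1_scan")) ms1 <- list(ms1)
  rts <- vapply(ms1, function(s) s$rt, numeric(1))
  scan <- ms1[[which.min(abs(rts - spectrum$rt))]]
  if (is.null(isolation_halfwidth)) isolation_halfwidth <- spectrum$isolation_halfwidth

  pk <- scan$peaks
  inwin <- abs(pk$mz - nominal_mass) <= isolation_halfwidth
  prec_mz <- pk$mz[inwin]; prec_int <- pk$intensity[inwin]
  if (length(prec_int)) {
    keep <- prec_int >= min_rel_intensity * max(prec_int)
    prec_mz <- prec_mz[keep]; prec_int <- prec_int[keep]
  }
  assignments <- lapply(prec_mz, assign_formula, bounds = assign_bounds,
                        tol_ppm = tol_ppm)
  ok <- !vapply(assignments, is.null, logical(1))
  precursors <- data.frame(mz = prec_mz[ok], intensity = prec_int[ok],
                           formula = vapply(assignments[ok],
                                            function(a) format(a$formula),
                                            character(1)))
  if (!nrow(precursors)) {
    warning("no assignable precursors in the isolation window at nominal mass ",
            nominal_mass)
  }

  fg_list <- list()
  for (i in seq_len(nrow(precursors))) {
    a <- assignments[ok][[i]]
    neutral <- if (a$electron_config == "even_electron_deprotonated") {
      a$formula
    } else a$formula  # loss arithmetic is on the elemental composition
    if (neutral[["H"]] < 1L) next
    losses <- enumerate_losses(neutral, max_total)
    if (!nrow(losses)) next
    fg_list[[length(fg_list) + 1L]] <- data.frame(
      mz = a$mz - losses$neutral_mass,
      label = sprintf("%s -%dxCO2 -%dxH2O -%dxCH4O", precursors$formula[i],
                      losses$n_co2, losses$n_h2o, losses$n_ch4o)
    )
  }
  fg_targets <- if (length(fg_list)) do.call(rbind, fg_list) else
    data.frame(mz = numeric(0), label = character(0))
  if (nrow(fg_targets)) {
    # deduplicate targets that coincide within tolerance (shared losses)
    fg_targets <- fg_targets[order(fg_targets$mz), ]
    dup <- c(FALSE, diff(fg_targets$mz) / fg_targets$mz[-1] * 1e6 <= tol_ppm)
    fg_targets <- fg_targets[!dup, ]
  }

  res <- .assign_peaks(spectrum$peaks, precursors$mz, fg_targets,
                       tol_ppm, radical_bounds, mass_defect_filter)
  out <- .frag_metrics(res$ledger, res$raw_total, res$filtered_total,
                       sample_id = spectrum$sample_id,
                       target = paste0("m", nominal_mass), nce = spectrum$nce)
  attr(out, "precursors") <- precursors
  out
}

#' Nominal fragment mass after one acetic-acid (C2H4O2) neutral loss
#'
#' The acetate-ester transition: an acetyl ester sheds one C2H4O2 unit,
#' e.g. nominal m/z 327 -> 267.
#'
#' @param parent_mz Parent m/z; must be at least the mass of C2H4O2.
#' @return Integer nominal m/z of the residual fragment.
#' @examples
#' acetate_transition_check(327)  # 267
#' @export
acetate_transition_check <- function(parent_mz) {
  loss <- monoisotopic_mass("C2H4O2")
  if (parent_mz < loss) {
    stop("parent m/z ", parent_mz, " below the C2H4O2 loss mass; ",
         "the loss would leave a non-positive fragment mass")
  }
  as.integer(round(parent_mz - loss))
}
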