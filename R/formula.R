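# Exact-mass and electron-parity arithmetic for small-molecule formulas.
# All masses are monoisotopic, in Da, from the IUPAC/CODATA atomic mass
# evaluation; hard-coded so results are bit-stable across platforms.

.ELEMENT_MASS <- c(
  C  = 12.0,           # exact by definition
  H  = 1.00782503207,
  O  = 15.99491461956,
  N  = 14.00307400480,
  S  = 31.97207100000,
  Cl = 34.96885268000,
  Br = 78.91833710000
)

.ELECTRON_MASS <- 0.00054857990907

# mass removed when a neutral loses H+ while keeping both bonding electrons:
# one H atom out, one electron back in
.DEPROTONATION_MASS <- .ELEMENT_MASS[["H"]] - .ELECTRON_MASS

#' Parse a molecular formula in Hill notation
#'
#' Converts a formula string such as `"C14H14O6"` into a `mol_formula`
#' object (a named integer vector of element counts). Only plain element
#' counts are accepted: isotope labels (`[13C]`), charges (`+`/`-`) and
#' parentheses are rejected, as are element symbols outside the supported
#' set (C, H, O, N, S, Cl, Br).
#'
#' @param x A formula string, or an existing `mol_formula` (returned
#'   unchanged), or a named numeric vector of counts.
#' @return A `mol_formula` object.
#' @examples
#' parse_formula("C2H4O2")
#' parse_formula("C12H7Cl3O2")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "mol_formula")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(mol_formula(x))
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("formula must be a single string or a named count vector")
  }
  if (grepl("[][()+^>< ]|[0-9]+[A-Z]*\\[", x) || grepl("-", x, fixed = TRUE)) {
    stop("formula string may not contain isotopes, charges or grouping: ", x)
  }
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", x)) {
    stop("malformed formula string: ", x)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  counts <- stats::setNames(integer(length(.ELEMENT_MASS)), names(.ELEMENT_MASS))
  for (i in seq_along(sym)) {
    if (!sym[i] %in% names(.ELEMENT_MASS)) {
      stop("unknown element symbol: ", sym[i])
    }
    counts[[sym[i]]] <- counts[[sym[i]]] + cnt[i]
  }
  mol_formula(counts)
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named numeric vector, element symbol -> non-negative count.
#' @return A `mol_formula` object (named integer vector over the full
#'   supported element set, zero for absent elements).
#' @export
mol_formula <- function(counts) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("counts must be a fully named vector")
  }
  bad <- setdiff(names(counts), names(.ELEMENT_MASS))
  if (length(bad)) stop("unknown element symbol: ", paste(bad, collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  full <- stats::setNames(integer(length(.ELEMENT_MASS)), names(.ELEMENT_MASS))
  full[names(counts)] <- as.integer(round(counts))
  structure(full, class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  # Hill order: C, H, then remaining elements alphabetically
  elems <- names(.ELEMENT_MASS)
  rest <- sort(setdiff(elems, c("C", "H")))
  ord <- c("C", "H", rest)
  parts <- character(0)
  for (e in ord) {
    n <- x[[e]]
    if (n > 0) parts <- c(parts, paste0(e, if (n > 1) n else ""))
  }
  if (!length(parts)) "(empty)" else paste(parts, collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format(x), sep = "")
  if (formula_size(x) > 0) cat("  (", format(monoisotopic_mass(x), nsmall = 6), " Da)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
Ops.mol_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    stop("operation '", .Generic, "' not defined for formulas")
  }
  f1 <- parse_formula(e1)
  f2 <- parse_formula(e2)
  if (.Generic == "==") return(all(unclass(f1) == unclass(f2)))
  out <- unclass(f1) + if (.Generic == "+") unclass(f2) else -unclass(f2)
  if (any(out < 0)) {
    stop("formula subtraction would give a negative ",
         paste(names(out)[out < 0], collapse = ","), " count")
  }
  structure(out, class = "mol_formula")
}

formula_size <- function(f) sum(unclass(parse_formula(f)))

#' Monoisotopic mass of a formula
#'
#' @param formula A formula string or `mol_formula`.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("CO2")   # 43.989829
#' monoisotopic_mass("H2O")   # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  if (formula_size(f) == 0L) stop("cannot take the mass of an empty formula")
  sum(unclass(f) * .ELEMENT_MASS)
}

#' m/z of the deprotonated anion [M-H]-
#'
#' The even-electron negative-mode species: the neutral loses a proton,
#' i.e. an H atom minus one electron.
#'
#' @param neutral A formula string or `mol_formula` with at least one H.
#' @return m/z at charge -1.
#' @examples
#' mz_deprotonated("C2H4O2")  # acetate, 59.013853
#' @export
mz_deprotonated <- function(neutral) {
  f <- parse_formula(neutral)
  if (f[["H"]] < 1L) stop("cannot deprotonate ", format(f), ": no hydrogen")
  monoisotopic_mass(f) - .DEPROTONATION_MASS
}

#' m/z of the radical anion M.-
#'
#' The odd-electron species: the intact composition plus one electron.
#'
#' @param neutral A formula string or `mol_formula`.
#' @return m/z at charge -1.
#' @export
mz_radical <- function(neutral) {
  monoisotopic_mass(neutral) + .ELECTRON_MASS
}

#' Rings plus double-bond equivalents
#'
#' Computed on the neutral reading of a formula:
#' `C - (H + Cl + Br)/2 + N/2 + 1`. O and S do not contribute.
#'
#' @param formula A formula string or `mol_formula`.
#' @return RDBE (may be half-integral for odd-electron compositions).
#' @export
rdbe <- function(formula) {
  f <- parse_formula(formula)
  f[["C"]] - (f[["H"]] + f[["Cl"]] + f[["Br"]]) / 2 + f[["N"]] / 2 + 1
}

#' Is an observed anion composition best read as an odd-electron radical?
#'
#' For a CHO composition observed as a singly charged anion there are two
#' electron-bookkeeping readings: a closed-shell deprotonated fragment
#' [X-H]- (the neutral X then has one more H than observed) or an intact
#' odd-electron radical anion X.-. CHO neutrals always carry an even
#' hydrogen count, so a closed-shell [M-H]- composition has odd H; an
#' observed CHO anion composition with even H is only consistent with the
#' radical reading.
#'
#' @param anion A formula string or `mol_formula`: the elemental
#'   composition of the observed anion (CHO only).
#' @return `TRUE` if the parity-consistent reading is odd-electron.
#' @examples
#' is_radical_assignment("C7H4O4")  # TRUE: even H
#' is_radical_assignment("C7H3O4")  # FALSE: ordinary [M-H]-
#' @export
is_radical_assignment <- function(anion) {
  f <- parse_formula(anion)
  if (any(unclass(f)[c("N", "S", "Cl", "Br")] > 0)) {
    stop("radical-parity test is defined for CHO compositions only")
  }
  if (f[["C"]] < 1L) stop("anion composition must contain carbon")
  f[["H"]] %% 2L == 0L
}

#' Assign a molecular formula to an observed m/z
#'
#' Searches CHO(+optional heteroatom) compositions within element bounds,
#' under both negative-mode electron configurations (even-electron
#' deprotonated `[M-H]-` and odd-electron radical `M.-`), and returns the
#' candidate whose theoretical m/z is closest to the observation, subject
#' to a ppm tolerance and a neutral-reading RDBE >= 0 feasibility filter.
#' Ties are broken by lower absolute ppm error, then fewer heteroatoms,
#' then lower RDBE.
#'
#' Candidates must satisfy the electron-parity rule for valence-valid
#' compositions: the neutral (or intact radical) composition must have an
#' even H + Cl + Br + N sum. This is what distinguishes the two electron
#' configurations, which are otherwise exactly mass-degenerate (the
#' radical reading of composition x and the deprotonated reading of
#' x + H share one m/z): a closed-shell `[M-H]-` ion has an odd-parity
#' composition, an intact radical anion an even-parity one.
#'
#' For each combination of non-hydrogen element counts, the hydrogen count
#' is solved from the target mass (and its immediate neighbours checked),
#' which is equivalent to the exhaustive grid at any realistic tolerance.
#'
#' @param observed_mz Observed m/z (Da), charge -1 assumed.
#' @param bounds Named vector of maximum element counts; default
#'   `c(C = 40, H = 60, O = 25)`. Add e.g. `Cl = 4` to consider chlorine.
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @param configs Electron configurations to consider.
#' @return An `ion_species` object (fields `formula`, `electron_config`,
#'   `charge`, `mz`, `ppm_error`) or `NULL` if nothing lies in tolerance.
#' @examples
#' assign_formula(59.013853)              # acetate [M-H]-
#' assign_formula(43.990378)              # CO2 radical anion
#' @export
assign_formula <- function(observed_mz,
                           bounds = c(C = 40, H = 60, O = 25),
                           tol_ppm = 5,
                           configs = c("even_electron_deprotonated",
                                       "odd_electron_radical")) {
  if (!is.numeric(observed_mz) || length(observed_mz) != 1L || observed_mz <= 0) {
    stop("observed_mz must be a single positive number")
  }
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  if (!length(bounds) || is.null(names(bounds))) stop("element bounds must be named and non-empty")
  bad <- setdiff(names(bounds), names(.ELEMENT_MASS))
  if (length(bad)) stop("unknown element symbol in bounds: ", paste(bad, collapse = ", "))
  configs <- match.arg(configs, several.ok = TRUE)

  h_max <- if ("H" %in% names(bounds)) bounds[["H"]] else 60
  heavy <- setdiff(names(bounds), "H")
  if (!length(heavy)) stop("bounds must include at least one non-hydrogen element")
  grid <- expand.grid(lapply(bounds[heavy], function(n) 0:n))
  heavy_mass <- as.vector(as.matrix(grid) %*% .ELEMENT_MASS[heavy])

  best <- NULL
  for (cfg in configs) {
    target <- observed_mz +
      if (cfg == "even_electron_deprotonated") .DEPROTONATION_MASS else -.ELECTRON_MASS
    h0 <- round((target - heavy_mass) / .ELEMENT_MASS[["H"]])
    for (dh in -2:2) {
      h <- h0 + dh
      h_min <- if (cfg == "even_electron_deprotonated") 1L else 0L
      ok <- h >= h_min & h <= h_max
      if (!any(ok)) next
      mass <- heavy_mass + h * .ELEMENT_MASS[["H"]]
      mz <- mass - if (cfg == "even_electron_deprotonated") .DEPROTONATION_MASS else -.ELECTRON_MASS
      ppm <- (mz - observed_mz) / observed_mz * 1e6
      cC <- if ("C" %in% heavy) grid[["C"]] else 0
      cN <- if ("N" %in% heavy) grid[["N"]] else 0
      cX <- (if ("Cl" %in% heavy) grid[["Cl"]] else 0) +
            (if ("Br" %in% heavy) grid[["Br"]] else 0)
      dbe <- cC - (h + cX) / 2 + cN / 2 + 1
      hetero <- rowSums(grid[, setdiff(heavy, c("C", "O")), drop = FALSE])
      parity_ok <- (h + cX + cN) %% 2 == 0  # valence-valid composition
      ok <- ok & parity_ok & abs(ppm) <= tol_ppm & dbe >= 0 & cC >= 1
      if (!any(ok)) next
      idx <- which(ok)
      for (i in idx) {
        cand <- list(
          counts = c(as.numeric(grid[i, ]), H = h[i]),
          names = c(heavy, "H"),
          config = cfg, mz = mz[i], ppm = ppm[i],
          hetero = hetero[i], dbe = dbe[i]
        )
        if (is.null(best) ||
            abs(cand$ppm) < abs(best$ppm) - 1e-12 ||
            (abs(cand$ppm) <= abs(best$ppm) + 1e-12 &&
             (cand$hetero < best$hetero ||
              (cand$hetero == best$hetero && cand$dbe < best$dbe)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  counts <- stats::setNames(best$counts, best$names)
  structure(
    list(
      formula = mol_formula(counts[counts > 0 | names(counts) == "C"]),
      charge_state = -1L,
      electron_config = best$config,
      mz = best$mz,
      ppm_error = best$ppm
    ),
    class = "ion_species"
  )
}

#' @export
print.ion_species <- function(x, ...) {
  tag <- if (x$electron_config == "odd_electron_radical") ".-" else " [M-H]-"
  cat(sprintf("<ion> %s%s  m/z %.6f  (%+.2f ppm)\n",
              format(x$formula), tag, x$mz, x$ppm_error))
  invisible(x)
}
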