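# Independent oracles used to cross-check the package's implementations.
# These deliberately re-derive results by brute force / first principles
# and share no code with the functions they check.

ORACLE_MASS <- c(C = 12.0, H = 1.00782503207, O = 15.99491461956)
ORACLE_ELECTRON <- 0.00054857990907

oracle_mass_cho <- function(c, h, o) {
  c * ORACLE_MASS[["C"]] + h * ORACLE_MASS[["H"]] + o * ORACLE_MASS[["O"]]
}

# Brute-force enumeration of feasible (a,b,c) = (CO2, H2O, CH4O) loss
# combinations by explicit triple loop with first-principles feasibility.
oracle_loss_grid <- function(C, H, O, max_total) {
  out <- NULL
  for (a in 0:max_total) for (b in 0:max_total) for (c in 0:max_total) {
    n <- a + b + c
    if (n < 1 || n > max_total) next
    fc <- C - a - c
    fh <- H - 2 * b - 4 * c
    fo <- O - 2 * a - b - c
    if (fc < 0 || fh < 1 || fo < 0) next          # observable [frag-H]-
    if (fc - fh / 2 + 1 < 0) next                  # RDBE of the fragment
    out <- rbind(out, data.frame(n_co2 = a, n_h2o = b, n_ch4o = c))
  }
  out
}

# Electron-count parity oracle: a singly charged anion of composition
# CcHhOo carries 6c + h + 8o + 1 electrons; an odd total forces an
# open-shell (radical) species.
oracle_is_radical <- function(c, h, o) {
  (6 * c + h + 8 * o + 1) %% 2 == 1
}

# Exhaustive-grid formula assignment over small CHO bounds: every (c,h,o)
# with both electron readings, valence-parity-valid compositions only,
# RDBE >= 0, closest in ppm wins.
oracle_assign <- function(mz, c_max = 20, h_max = 40, o_max = 15,
                          tol_ppm = 5) {
  best <- NULL
  for (c in 1:c_max) for (h in 0:h_max) for (o in 0:o_max) {
    if (h %% 2 != 0) next                          # valence-valid composition
    m <- oracle_mass_cho(c, h, o)
    cand <- list()
    if (h >= 1 && c - h / 2 + 1 >= 0) {
      cand$even <- m - ORACLE_MASS[["H"]] + ORACLE_ELECTRON
    }
    if (c - h / 2 + 1 >= 0) {
      cand$odd <- m + ORACLE_ELECTRON
    }
    for (cfg in names(cand)) {
      ppm <- (cand[[cfg]] - mz) / mz * 1e6
      if (abs(ppm) <= tol_ppm &&
          (is.null(best) || abs(ppm) < abs(best$ppm))) {
        best <- list(c = c, h = h, o = o, config = cfg, ppm = ppm)
      }
    }
  }
  best
}

# Random valence-valid CHO neutral (even H, H <= 2C+2, RDBE >= 0).
random_cho_formula <- function(c_max = 20, o_max = 12) {
  c <- sample(2:c_max, 1)
  h <- 2 * sample(1:(c + 1), 1)
  o <- sample(0:o_max, 1)
  mol_formula(c(C = c, H = h, O = o))
}

# A small deterministic run for I/O tests: 3 MS1 scans + 1 MS2 spectrum.
make_tiny_run <- function() {
  list(
    ms1 = list(
      ms1_scan(1.0, peak_list(c(200.1, 300.2), c(10, 20))),
      ms1_scan(1.5, peak_list()),
      ms1_scan(2.0, peak_list(c(200.1), c(5)))
    ),
    ms2 = list(
      ms2_spectrum(300.2, peak_list(c(100.05, 256.15), c(40, 60)),
                   nce = 35, sample_id = "tiny", rt = 1.5)
    )
  )
}
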