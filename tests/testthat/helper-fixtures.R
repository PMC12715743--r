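# shared fixtures: compounds, small simulated runs, and an independent
# brute-force formula-decomposition oracle

std_compounds <- paraben_compounds()

spec_for <- function(name, conc = 25, ...) {
  r <- std_compounds[std_compounds$name == name, ]
  compound_spec(r$name, r$formula, r$rt, r$class, conc = conc, ...)
}

# small, fast run: five analytes spanning both classes, 3-9 min window
quick_specs <- function(conc = 25) {
  lapply(c("MeP", "EtP", "PrP", "OH-MeP", "OH-EtP"), spec_for, conc = conc)
}

quick_run <- function(seed, mode = "DDA", conc = 25, compounds = quick_specs(conc),
                      ...) {
  generate_run(compounds, mode = mode, seed = seed, rt_range = c(3, 9), ...)
}

quick_blank <- function(seed, ...) {
  generate_run(list(), matrix = NULL, seed = seed, rt_range = c(3, 9), ...)$run
}

# independent oracle: full nested enumeration over all in-bound element
# counts, no arithmetic shortcuts shared with decompose_mass()
brute_force_decompose <- function(mz, bounds = element_bounds()) {
  hits <- character(0)
  for (nC in bounds$C[1]:bounds$C[2])
    for (nH in bounds$H[1]:bounds$H[2])
      for (nO in bounds$O[1]:bounds$O[2])
        for (nS in bounds$S[1]:bounds$S[2]) {
          m <- nC * 12 + nH * 1.00782503207 + nO * 15.9949146196 +
            nS * 31.97207100
          ion <- m - 1.00782503207
          r <- nC - nH / 2 + 1
          if (abs(1e6 * (mz - ion) / ion) <= bounds$tolerance_ppm &&
              r >= bounds$rdbe[1] && r <= bounds$rdbe[2]) {
            f <- paste0("C", nC, "H", nH, "O", nO,
                        if (nS == 1) "S" else if (nS > 1) paste0("S", nS) else "")
            hits <- c(hits, f)
          }
        }
  sort(hits)
}
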