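## Seeded simulator of DDA/DIA runs of a biofluid matrix spiked with
## parabens, their phase I metabolites and phase II conjugates, with
## process blanks and ground-truth manifests. The simulator emulates the
## acquisition scheme of the screening workflow: full scans over 80-1000
## m/z, ddMS2 at 10/20/40 eV with TopN = 5 and 7 s dynamic exclusion, or
## AIF scans at the same three collision energies.

#' Reference compound table
#'
#' Parabens, alkyl protocatechuates and phenolic acids with neutral
#' formulas, compound class, SMILES, and default retention times on a
#' reversed-phase biphenyl-type gradient (minutes; user-adjustable).
#'
#' @return `data.frame` with columns `name`, `formula`, `class`, `rt`,
#'   `smiles`.
#' @export
paraben_compounds <- function() {
  data.frame(
    name = c("MeP", "EtP", "PrP", "iPrP", "BuP", "iBuP", "BzP",
             "4-HB", "3,4-DHB", "OH-MeP", "OH-EtP"),
    formula = c("C8H8O3", "C9H10O3", "C10H12O3", "C10H12O3", "C11H14O3",
                "C11H14O3", "C14H12O3", "C7H6O3", "C7H6O4", "C8H8O4",
                "C9H10O4"),
    class = c(rep("paraben", 7), "phenolic_acid", "phenolic_acid",
              "protocatechuate", "protocatechuate"),
    rt = c(5.9, 6.7, 7.5, 7.3, 8.2, 8.0, 8.4, 4.3, 3.6, 4.9, 5.8),
    smiles = c("COC(=O)c1ccc(O)cc1", "CCOC(=O)c1ccc(O)cc1",
               "CCCOC(=O)c1ccc(O)cc1", "CC(C)OC(=O)c1ccc(O)cc1",
               "CCCCOC(=O)c1ccc(O)cc1", "CC(C)COC(=O)c1ccc(O)cc1",
               "O=C(OCc1ccccc1)c1ccc(O)cc1", "O=C(O)c1ccc(O)cc1",
               "O=C(O)c1ccc(O)c(O)c1", "COC(=O)c1ccc(O)c(O)c1",
               "CCOC(=O)c1ccc(O)c(O)c1"),
    stringsAsFactors = FALSE)
}

## registry ions each compound class can form, respecting the MeP/BzP
## exclusions; values are relative fragment intensities per CE (fraction of
## the precursor MS1 intensity at that instant)
.default_profile <- function(class, name = "") {
  prof <- switch(class,
    paraben = list(
      `10` = c(A1 = .55, A2 = .45, B1 = .06, B2 = .04),
      `20` = c(A1 = .45, A2 = .40, B1 = .25, B2 = .12, B3 = .08, C = .10,
               D2 = .04, E = .08),
      `40` = c(A1 = .08, A2 = .10, B1 = .30, B2 = .18, B3 = .28, C = .30,
               D2 = .08, E = .32)),
    protocatechuate = list(
      `10` = c(F1 = .55, F2 = .45, G1 = .06),
      `20` = c(F1 = .45, F2 = .40, G1 = .25, C = .12, G3 = .06, D1 = .10,
               D2 = .05, E = .06, B3 = .05, H = .05, J = .05),
      `40` = c(F1 = .08, F2 = .10, G1 = .30, C = .28, G3 = .12, D1 = .15,
               D2 = .08, E = .25, B3 = .22, H = .08, J = .12, K = .06)),
    phenolic_acid = if (name == "3,4-DHB") list(
      `10` = c(G1 = .40),
      `20` = c(G1 = .50, C = .15, B3 = .10),
      `40` = c(G1 = .30, C = .30, B3 = .30))
    else list(
      `10` = c(B1 = .30), `20` = c(B1 = .50), `40` = c(B1 = .60)),
    stop("unknown compound class '", class, "'"))
  if (name %in% c("MeP", "BzP"))
    prof <- lapply(prof, function(p) p[setdiff(names(p), c("A1", "B1"))])
  prof
}

## sulfate-conjugate MS2 pattern: free-form ion + SO3/HSO4 markers + the
## free form's own diagnostic ions at reduced yield
.conjugate_profile <- function(class, name, conjugation) {
  base <- lapply(.default_profile(class, name), function(p) p * 0.4)
  marker <- switch(conjugation,
    sulfate = list(`10` = c(free = .50, SO3 = .15, HSO4 = .04),
                   `20` = c(free = .60, SO3 = .25, HSO4 = .08),
                   `40` = c(free = .35, SO3 = .35, HSO4 = .10)),
    glucuronide = ,
    glycine = list(`10` = c(free = .50), `20` = c(free = .60),
                   `40` = c(free = .40)))
  Map(function(b, m) c(m, b), base, marker)
}

#' Specify a spiked compound for simulation
#'
#' @param name Compound name; used for registry applicability exceptions.
#' @param formula Neutral formula of the free form.
#' @param rt Retention time, minutes.
#' @param class `"paraben"`, `"protocatechuate"` or `"phenolic_acid"`.
#' @param conc Concentration, ng/mL.
#' @param response_factor Precursor intensity per ng/mL (default 4e4, so
#'   the 25 ng/mL spike level sits at 1e6 before matrix suppression).
#' @param profile Optional per-CE named relative-intensity vectors; default
#'   the class profile (A-series dominant at low CE, ring fragments growing
#'   at 40 eV), with MeP/BzP exclusions applied.
#' @param conjugation Optional `"sulfate"`, `"glucuronide"` or `"glycine"`;
#'   the simulated species is then the phase II conjugate of `formula`.
#' @return A `compound_spec` list.
#' @export
compound_spec <- function(name, formula, rt, class, conc = 25,
                          response_factor = 4e4, profile = NULL,
                          conjugation = NULL) {
  if (is.null(profile)) {
    profile <- if (is.null(conjugation)) .default_profile(class, name)
               else .conjugate_profile(class, name, conjugation)
  }
  stopifnot(all(unlist(profile) >= 0), all(unlist(profile) <= 1))
  mz <- if (is.null(conjugation)) mz_deprotonated(formula)
        else conjugate_mass(formula, conjugation)
  structure(list(name = name, formula = formula, rt = as.numeric(rt),
                 class = class, conc = as.numeric(conc),
                 response_factor = as.numeric(response_factor),
                 profile = profile, conjugation = conjugation,
                 free_mz = mz_deprotonated(formula), mz = mz),
            class = "compound_spec")
}

#' Matrix model for simulated runs
#'
#' @param noise_level Baseline chemical-noise intensity scale (arbitrary
#'   units; exponential-tailed peaks well below the DDA trigger).
#' @param suppression Multiplicative matrix-suppression factor on analyte
#'   responses, in (0, 1]; default 0.85 (15% suppression, the middle of the
#'   10-30% band typical of protein-precipitated biofluid extracts).
#' @param interferences `data.frame(name, mz, rt, height, fragment_mz,
#'   fragment_rel)` of co-extracted channels. The default is a
#'   benzophenone-like interferent that fragments into the 91.0184 channel
#'   but yields no other diagnostic ion, so it probes the >= 4-ion rule.
#' @return A `matrix_model` list.
#' @export
matrix_model <- function(noise_level = 30, suppression = 0.85,
                         interferences = NULL) {
  stopifnot(noise_level > 0, suppression > 0, suppression <= 1)
  if (is.null(interferences)) {
    interferences <- data.frame(
      name = "benzophenone-like", mz = 213.0552, rt = 7.8, height = 6e5,
      stringsAsFactors = FALSE)
    interferences$fragments <- list(c("91.0184" = 0.45, "135.0446" = 0.6,
                                      "169.0658" = 0.3))
  }
  structure(list(noise_level = as.numeric(noise_level),
                 suppression = as.numeric(suppression),
                 interferences = interferences),
            class = "matrix_model")
}

## intensity noise: Poisson-like counting noise in the Gaussian limit
.jitter_intensity <- function(x) pmax(0, x + stats::rnorm(length(x), 0, sqrt(pmax(x, 1))))

## m/z jitter, sigma = 2 ppm, clamped at 3 sigma so ground-truth ions stay
## inside the 10 ppm screening window
.jitter_mz <- function(mz, sigma_ppm = 2) {
  ppm <- pmin(3 * sigma_ppm, pmax(-3 * sigma_ppm,
                                  stats::rnorm(length(mz), 0, sigma_ppm)))
  mz * (1 + ppm * 1e-6)
}

.noise_peaks <- function(n, scan_range, noise_level) {
  if (n == 0) return(NULL)
  cbind(mz = stats::runif(n, scan_range[1], scan_range[2]),
        intensity = stats::rexp(n, 1 / noise_level))
}

## fragment peak list for one species at one CE, given its instantaneous
## precursor intensity
.fragment_peaks <- function(spec, ce, inten, registry) {
  prof <- spec$profile[[as.character(ce)]]
  if (is.null(prof) || !length(prof)) return(NULL)
  labs <- names(prof)
  mzs <- numeric(length(labs))
  for (i in seq_along(labs)) {
    lab <- labs[i]
    mzs[i] <- if (lab == "free") spec$free_mz
      else if (lab %in% names(SULFATE_MARKERS)) SULFATE_MARKERS[[lab]]
      else if (lab %in% registry$label) registry[registry$label == lab, "mz"]
      else as.numeric(lab)  # literal m/z channels (interference style)
  }
  keep <- prof * inten > 5
  if (!any(keep)) return(NULL)
  cbind(mz = .jitter_mz(mzs[keep]),
        intensity = .jitter_intensity(prof[keep] * inten))
}

#' Simulate a DDA or DIA run with ground truth
#'
#' Chromatographic peaks are Gaussian (default 0.15 min FWHM). Every cycle
#' emits one full scan; in DDA mode, the top `top_n` precursors above
#' `trigger_threshold` (and outside a 7 s dynamic-exclusion analog) each
#' receive one ddMS2 scan per collision energy; in DIA mode each cycle
#' appends one AIF scan per collision energy containing the fragments of
#' all co-eluting species plus the attenuated surviving precursors
#' (survival 0.55/0.30/0.08 at 10/20/40 eV, so precursor intensity
#' decreases consistently with CE). Fragment m/z values carry seeded
#' Gaussian jitter (sigma 2 ppm, clamped at 6 ppm) and Poisson-like
#' intensity noise. Compounds simulated below the trigger threshold never
#' acquire MS2, reproducing the missed-trigger failure mode of DDA.
#'
#' @param compounds List of [compound_spec()] objects (or a single one).
#' @param matrix A [matrix_model()]; `NULL` for a process blank's clean
#'   background (noise only, no interferences, no suppression).
#' @param mode `"DDA"` or `"DIA"`.
#' @param seed Integer seed; identical seeds reproduce identical runs.
#' @param rt_range Simulated acquisition window, minutes.
#' @param cycle Full-scan cycle time, minutes (default 0.02, ~1.2 s).
#' @param fwhm Chromatographic peak FWHM, minutes.
#' @param trigger_threshold DDA intensity trigger (default 1e5).
#' @param top_n DDA loop count (default 5).
#' @param dyn_exclusion_s DDA dynamic exclusion, seconds (default 7).
#' @param ce_scheme Collision energies, eV.
#' @param registry Diagnostic-ion registry.
#' @return List with `run` (a [spectrum_run()]) and `truth`
#'   (`data.frame` manifest: name, class, formula, mz, rt, conc,
#'   apex_height, conjugation, triggered).
#' @export
generate_run <- function(compounds, matrix = matrix_model(), mode = c("DDA", "DIA"),
                         seed = 1, rt_range = c(0, 10), cycle = 0.02,
                         fwhm = 0.15, trigger_threshold = 1e5, top_n = 5,
                         dyn_exclusion_s = 7, ce_scheme = c(10, 20, 40),
                         registry = build_registry()) {
  mode <- match.arg(mode)
  if (inherits(compounds, "compound_spec")) compounds <- list(compounds)
  stopifnot(all(vapply(compounds, inherits, logical(1), "compound_spec")))
  if (anyDuplicated(vapply(compounds, `[[`, character(1), "name")))
    stop("compound names must be distinct")
  for (cs in compounds)
    if (cs$rt < rt_range[1] || cs$rt > rt_range[2])
      stop("compound '", cs$name, "' elutes outside the acquisition window")
  set.seed(as.integer(seed))
  scan_range <- c(80, 1000)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  supp <- if (is.null(matrix)) 1 else matrix$suppression
  noise_level <- if (is.null(matrix)) 10 else matrix$noise_level
  interf <- if (is.null(matrix)) NULL else matrix$interferences

  ## unified species table: analytes + interference channels
  species <- lapply(compounds, function(cs) {
    list(name = cs$name, mz = cs$mz, rt = cs$rt,
         apex = cs$conc * cs$response_factor * supp, spec = cs)
  })
  if (!is.null(interf)) for (i in seq_len(nrow(interf))) {
    frs <- interf$fragments[[i]]
    fake <- list(name = interf$name[i], formula = NA, rt = interf$rt[i],
                 class = "interference", conc = NA, response_factor = NA,
                 profile = stats::setNames(rep(list(frs), length(ce_scheme)),
                                           as.character(ce_scheme)),
                 conjugation = NULL, free_mz = NA, mz = interf$mz[i])
    class(fake) <- "compound_spec"
    species <- c(species, list(list(name = fake$name, mz = interf$mz[i],
                                    rt = interf$rt[i], height = NULL,
                                    apex = interf$height[i], spec = fake)))
  }

  times <- seq(rt_range[1], rt_range[2], by = cycle)
  spectra <- vector("list", 4L * length(times) * (1 + length(species)))
  ns <- 0L
  add <- function(s) { ns <<- ns + 1L; spectra[[ns]] <<- s }
  last_trigger <- stats::setNames(rep(-Inf, length(species)),
                                  vapply(species, `[[`, character(1), "name"))
  dyn_excl <- dyn_exclusion_s / 60
  ms2_dt <- cycle / (2 * length(ce_scheme) * max(1, top_n) + 2)

  for (t in times) {
    inten <- vapply(species, function(sp)
      sp$apex * exp(-(t - sp$rt)^2 / (2 * sigma^2)), numeric(1))
    live <- which(inten > 1)
    pk <- .noise_peaks(15L, scan_range, noise_level)
    if (length(live)) {
      mzs <- .jitter_mz(vapply(species[live], `[[`, numeric(1), "mz"))
      pk <- rbind(pk, cbind(mz = mzs, intensity = .jitter_intensity(inten[live])))
    }
    add(spectrum(1L, t, pk, ce = 0, acquisition = "full"))
    if (mode == "DIA") {
      survival <- stats::setNames(c(0.55, 0.30, 0.08)[seq_along(ce_scheme)],
                                  as.character(ce_scheme))
      for (k in seq_along(ce_scheme)) {
        ce <- ce_scheme[k]
        fpk <- .noise_peaks(10L, scan_range, noise_level)
        for (j in live) {
          sp <- species[[j]]
          fpk <- rbind(fpk, .fragment_peaks(sp$spec, ce, inten[j], registry))
          surv <- survival[[as.character(ce)]] * inten[j]
          if (surv > 5)
            fpk <- rbind(fpk, cbind(mz = .jitter_mz(sp$mz),
                                    intensity = .jitter_intensity(surv)))
        }
        add(spectrum(2L, t + k * ms2_dt, fpk, ce = ce, acquisition = "AIF"))
      }
    } else {
      cand <- live[inten[live] >= trigger_threshold]
      cand <- cand[t - last_trigger[cand] >= dyn_excl]
      cand <- cand[order(-inten[cand])]
      cand <- utils::head(cand, top_n)
      sc <- 0L
      for (j in cand) {
        sp <- species[[j]]
        last_trigger[j] <- t
        for (ce in ce_scheme) {
          sc <- sc + 1L
          fpk <- .fragment_peaks(sp$spec, ce, inten[j], registry)
          ## residual unfragmented precursor
          res_frac <- c(0.25, 0.10, 0.02)[match(ce, ce_scheme)]
          fpk <- rbind(fpk, cbind(mz = .jitter_mz(sp$mz),
                                  intensity = .jitter_intensity(res_frac * inten[j])))
          add(spectrum(2L, t + sc * ms2_dt, fpk, ce = ce,
                       precursor_mz = sp$mz, iso_width = 1.5,
                       acquisition = "ddMS2"))
        }
      }
    }
  }
  run <- spectrum_run(spectra[seq_len(ns)], ce_scheme = ce_scheme,
                      scan_range = scan_range)
  ## force the declared mode even when nothing triggered (blank DDA runs)
  run$mode <- if (mode == "DIA") "DIA" else "DDA"
  truth <- do.call(rbind, lapply(compounds, function(cs) {
    apex <- cs$conc * cs$response_factor * supp
    data.frame(name = cs$name, class = cs$class, formula = cs$formula,
               mz = cs$mz, rt = cs$rt, conc = cs$conc, apex_height = apex,
               conjugation = if (is.null(cs$conjugation)) NA_character_
                             else cs$conjugation,
               triggered = apex >= trigger_threshold,
               stringsAsFactors = FALSE)
  }))
  list(run = run, truth = truth)
}

#' Simulate a calibration-style spike series with blanks
#'
#' Emulates the spiked-sample design: per spiking level one run per
#' replicate sharing compound retention times but with independent noise,
#' plus process blanks sharing only the background.
#'
#' @param compounds List of [compound_spec()]s; `conc` is overridden by
#'   `levels`.
#' @param levels Spike levels, ng/mL, ascending (default `c(1, 5, 25)`).
#' @param replicates Replicates per level (default 3).
#' @param n_blanks Process blanks (default 3).
#' @param seed Integer seed.
#' @param ... Passed to [generate_run()].
#' @return List with `runs` (list of lists `level`, `replicate`, `run`),
#'   `blanks` (list of runs), and `truth` manifest.
#' @export
generate_spike_series <- function(compounds, levels = c(1, 5, 25),
                                  replicates = 3, n_blanks = 3, seed = 1,
                                  ...) {
  if (is.unsorted(levels)) stop("levels must be ascending")
  if (inherits(compounds, "compound_spec")) compounds <- list(compounds)
  runs <- list(); truth <- list(); k <- 0L
  for (li in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      cmp <- lapply(compounds, function(cs) { cs$conc <- levels[li]; cs })
      g <- generate_run(cmp, seed = seed * 1000L + k, ...)
      runs[[k]] <- list(level = levels[li], replicate = r, run = g$run)
      tr <- g$truth; tr$level <- levels[li]; tr$replicate <- r
      truth[[k]] <- tr
    }
  }
  blanks <- lapply(seq_len(n_blanks), function(b)
    generate_run(list(), matrix = NULL, seed = seed * 1000L + 500L + b, ...)$run)
  list(runs = runs, blanks = blanks, truth = do.call(rbind, truth))
}
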