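## Precursor prioritization by diagnostic fragment ions.
##
## DDA rule: a precursor is kept when (1) its MS1 peak is at least
## `blank_ratio`-fold above the process blanks and (2) at least
## `min_diagnostic_ions` distinct diagnostic-ion labels are matched (mass
## error < `fragment_tol` ppm) in the ddMS2 spectra merged across the CE
## scheme, and (3) at least one elemental formula survives the composition
## restrictions.
##
## DIA rule: candidate precursors (>= `dia_min_intensity` at CE 0) are
## selected at the retention times of observed diagnostic-fragment EIC
## peaks if their intensity decreases consistently with increasing CE.

#' Screening parameters
#'
#' Defaults are the workflow's published thresholds: >= 4 diagnostic ions
#' at < 10 ppm, 5 ppm precursor tolerance, 3-fold blank ratio, 1e5 DIA
#' intensity floor, CE scheme 10/20/40 eV, and the precursor elemental
#' bounds of [element_bounds()].
#'
#' @param min_diagnostic_ions Minimum distinct diagnostic-ion labels.
#' @param fragment_tol Fragment match tolerance, ppm.
#' @param precursor_tol Precursor m/z tolerance, ppm.
#' @param blank_ratio Minimum sample/blank EIC height ratio (fold).
#' @param coelution_window Apex coherence window, minutes (default 0.1,
#'   matching the QC retention-time shift bound).
#' @param element_bounds Precursor composition restrictions.
#' @param dia_min_intensity DIA full-scan intensity floor.
#' @param dia_decrease_slack Allowed relative slack in the DIA
#'   CE-decrease rule (0 = strictly decreasing).
#' @param ce_scheme Collision energies, eV.
#' @param min_snr Minimum S/N for chromatographic peak detection.
#' @return A `screen_params` list.
#' @export
screen_params <- function(min_diagnostic_ions = 4L, fragment_tol = 10,
                          precursor_tol = 5, blank_ratio = 3,
                          coelution_window = 0.1,
                          element_bounds = NULL,
                          dia_min_intensity = 1e5, dia_decrease_slack = 0,
                          ce_scheme = c(10, 20, 40), min_snr = 3) {
  if (is.null(element_bounds)) element_bounds <- element_bounds()
  p <- list(min_diagnostic_ions = as.integer(min_diagnostic_ions),
            fragment_tol = fragment_tol, precursor_tol = precursor_tol,
            blank_ratio = blank_ratio, coelution_window = coelution_window,
            element_bounds = element_bounds,
            dia_min_intensity = dia_min_intensity,
            dia_decrease_slack = dia_decrease_slack,
            ce_scheme = ce_scheme, min_snr = min_snr)
  stopifnot(p$min_diagnostic_ions >= 1L, p$fragment_tol > 0,
            p$precursor_tol > 0, p$blank_ratio > 0, p$coelution_window > 0,
            p$dia_min_intensity > 0)
  structure(p, class = "screen_params")
}

## max blank EIC height near an rt window (0 when the channel is silent)
.blank_height <- function(blanks, mz, rt_lo, rt_hi, tol_ppm) {
  if (!length(blanks)) return(0)
  max(vapply(blanks, function(b) {
    e <- extract_eic(b, mz, tol_ppm, ms_level = 1L)
    sel <- e$rt >= rt_lo & e$rt <= rt_hi
    if (!any(sel)) 0 else max(e$intensity[sel])
  }, numeric(1)))
}

## match merged fragment peaks against the registry screening ions;
## returns data.frame(label, mz, ppm, ce)
.match_diagnostics <- function(peaklist, registry, tol_ppm) {
  ions <- registry[registry$screening, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ions))) {
    win <- ions$mz[i] * tol_ppm * 1e-6
    hits <- peaklist[abs(peaklist[, "mz"] - ions$mz[i]) <= win, , drop = FALSE]
    if (nrow(hits)) {
      best <- hits[which.max(hits[, "intensity"]), ]
      out[[length(out) + 1L]] <- data.frame(
        label = ions$label[i], mz = best[["mz"]],
        ppm = ppm_error(best[["mz"]], ions$mz[i]), ce = best[["ce"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(label = character(), mz = numeric(), ppm = numeric(),
                      ce = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## per-class distinct-label counts within the class screening sets; ions
## sharing one m/z (C/G2) carry one label and count once
.class_counts <- function(matched, registry) {
  sets <- list(
    paraben = c(attr(registry, "common_set"), attr(registry, "paraben_extra")),
    protocatechuate = c(attr(registry, "common_set"),
                        attr(registry, "protocatechuate_extra")))
  vapply(sets, function(s) length(intersect(matched$label, s)), integer(1))
}

.empty_candidates <- function() {
  structure(data.frame(precursor_mz = numeric(), rt = numeric(),
                       height = numeric(), n_matched = integer(),
                       blank_ratio_observed = numeric(),
                       class_call = character(), n_formulas = integer(),
                       top_formula = character(), source = character(),
                       stringsAsFactors = FALSE),
            matched_ions = list(), formula_candidates = list(),
            class = c("dfi_candidates", "data.frame"))
}

.bind_candidates <- function(rows, matched, formulas) {
  if (!length(rows)) return(.empty_candidates())
  out <- do.call(rbind, rows)
  o <- order(out$rt, out$precursor_mz)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, matched_ions = matched[o], formula_candidates = formulas[o],
            class = c("dfi_candidates", "data.frame"))
}

#' @export
print.dfi_candidates <- function(x, ...) {
  cat("<dfi_candidates>", nrow(x), "prioritized precursor(s)\n")
  if (nrow(x)) print.data.frame(as.data.frame(x), digits = 6, ...)
  invisible(x)
}

#' Matched diagnostic-ion evidence of screening candidates
#' @param candidates A `dfi_candidates` object.
#' @return List of per-candidate data.frames (label, m/z, ppm, CE).
#' @export
matched_ions <- function(candidates) attr(candidates, "matched_ions")

#' Surviving formula candidates of screening hits
#' @param candidates A `dfi_candidates` object.
#' @return List of per-candidate [decompose_mass()] tables.
#' @export
formula_candidates <- function(candidates) attr(candidates, "formula_candidates")

#' Screen a DDA run for diagnostic-ion-prioritized precursors
#'
#' For each distinct ddMS2 precursor the MS1 EIC is peak-picked; MS2 scans
#' across all collision energies whose retention time falls inside a peak
#' (widened by the coelution window) are merged, distinct diagnostic-ion
#' labels are counted per class screening set, the blank ratio is computed
#' as sample EIC peak height over the highest corresponding blank height
#' (a silent blank channel gives an infinite, passing ratio), and the
#' precursor composition is constrained by [decompose_mass()]. Candidates
#' failing any of the three rules are dropped.
#'
#' @param sample A DDA [spectrum_run()].
#' @param blanks List of process-blank runs (at least one).
#' @param registry A [build_registry()] object.
#' @param params A [screen_params()] object.
#' @return A `dfi_candidates` data.frame (precursor m/z, apex rt, height,
#'   n_matched, blank ratio, class call, formula summary) with
#'   [matched_ions()] and [formula_candidates()] attributes.
#' @export
screen_dda <- function(sample, blanks, registry = build_registry(),
                       params = screen_params()) {
  stopifnot(inherits(sample, "spectrum_run"))
  if (sample$mode != "DDA") stop("screen_dda requires a DDA run")
  if (!length(blanks)) stop("at least one process blank is required")
  if (inherits(blanks, "spectrum_run")) blanks <- list(blanks)
  ms2 <- Filter(function(s) s$acquisition == "ddMS2", sample$spectra)
  if (!length(ms2)) return(.empty_candidates())
  pmz <- vapply(ms2, `[[`, numeric(1), "precursor_mz")
  rt2 <- vapply(ms2, `[[`, numeric(1), "rt")
  ## group precursors by m/z within the precursor tolerance
  o <- order(pmz)
  grp <- integer(length(pmz)); g <- 0L; last <- -Inf
  for (i in o) {
    if (pmz[i] - last > params$precursor_tol * 1e-6 * pmz[i]) g <- g + 1L
    grp[i] <- g; last <- pmz[i]
  }
  rows <- list(); matched_l <- list(); formulas_l <- list()
  for (gi in seq_len(g)) {
    idx <- which(grp == gi)
    mz_g <- stats::median(pmz[idx])
    eic <- extract_eic(sample, mz_g, params$precursor_tol, ms_level = 1L)
    pks <- detect_peaks(eic, min_snr = params$min_snr)
    for (pi in seq_len(nrow(pks))) {
      lo <- pks$rt_min[pi] - params$coelution_window
      hi <- pks$rt_max[pi] + params$coelution_window
      member <- idx[rt2[idx] >= lo & rt2[idx] <= hi]
      if (!length(member)) next
      merged <- do.call(rbind, lapply(member, function(i)
        cbind(ms2[[i]]$peaks, ce = ms2[[i]]$ce)))
      m <- .match_diagnostics(merged, registry, params$fragment_tol)
      cc <- .class_counts(m, registry)
      n_matched <- max(cc)
      if (n_matched < params$min_diagnostic_ions) next
      bh <- .blank_height(blanks, mz_g, lo - params$coelution_window,
                          hi + params$coelution_window, params$precursor_tol)
      ratio <- if (bh <= 0) Inf else pks$height[pi] / bh
      if (ratio < params$blank_ratio) next
      fc <- decompose_mass(mz_g, params$element_bounds)
      if (!nrow(fc)) next
      call_ <- if (all(cc >= params$min_diagnostic_ions)) "ambiguous"
               else names(cc)[which.max(cc)]
      rows[[length(rows) + 1L]] <- data.frame(
        precursor_mz = mz_g, rt = pks$rt[pi], height = pks$height[pi],
        n_matched = n_matched, blank_ratio_observed = ratio,
        class_call = call_, n_formulas = nrow(fc),
        top_formula = fc$formula[1], source = "DDA",
        stringsAsFactors = FALSE)
      matched_l[[length(rows)]] <- m
      formulas_l[[length(rows)]] <- fc
    }
  }
  .bind_candidates(rows, matched_l, formulas_l)
}

#' Screen a DIA (AIF) run with the CE-decrease rule
#'
#' Diagnostic-ion EIC peaks are located in the AIF traces; at each such
#' retention time, full-scan ions above the intensity floor are paired
#' with their per-CE AIF intensities and retained when the sequence
#' (CE 0, then each AIF energy in order) decreases at every step. The
#' blank-ratio and formula constraints of the DDA rule then apply, and
#' surviving candidates are flagged for inclusion-list reacquisition.
#'
#' @inheritParams screen_dda
#' @return A `dfi_candidates` data.frame with `source = "DIA"`.
#' @export
screen_dia <- function(sample, blanks, registry = build_registry(),
                       params = screen_params()) {
  stopifnot(inherits(sample, "spectrum_run"))
  if (sample$mode != "DIA") stop("screen_dia requires a DIA (AIF) run")
  if (inherits(blanks, "spectrum_run")) blanks <- list(blanks)
  ions <- registry[registry$screening, , drop = FALSE]
  ## (a) diagnostic-ion apexes across AIF traces
  diag_hits <- list()
  for (i in seq_len(nrow(ions))) for (ce in params$ce_scheme) {
    e <- extract_eic(sample, ions$mz[i], params$fragment_tol, ms_level = 2L,
                     ce = ce, acquisition = "AIF")
    if (!nrow(e)) next
    pks <- detect_peaks(e, min_snr = params$min_snr)
    if (nrow(pks))
      diag_hits[[length(diag_hits) + 1L]] <- data.frame(
        label = ions$label[i], rt = pks$rt, stringsAsFactors = FALSE)
  }
  if (!length(diag_hits)) return(.empty_candidates())
  diag_hits <- do.call(rbind, diag_hits)
  ## cluster the apex rts
  rts <- sort(unique(diag_hits$rt))
  anchor <- rts[c(TRUE, diff(rts) > params$coelution_window)]
  full <- Filter(function(s) s$ms_level == 1L, sample$spectra)
  full_rt <- vapply(full, `[[`, numeric(1), "rt")
  rows <- list(); matched_l <- list(); formulas_l <- list()
  seen <- numeric(0)
  for (rt0 in anchor) {
    sc <- full[[which.min(abs(full_rt - rt0))]]
    p <- sc$peaks
    cand_mz <- p[p[, 2] >= params$dia_min_intensity, 1]
    for (mz in cand_mz) {
      if (any(abs(seen - mz) <= params$precursor_tol * 1e-6 * mz)) next
      e0 <- extract_eic(sample, mz, params$precursor_tol, ms_level = 1L)
      pk0 <- detect_peaks(e0, min_snr = params$min_snr)
      if (!nrow(pk0)) next
      pk0 <- pk0[abs(pk0$rt - rt0) <= params$coelution_window, , drop = FALSE]
      if (!nrow(pk0)) next
      i0 <- pk0$height[1]; apex_rt <- pk0$rt[1]
      if (i0 < params$dia_min_intensity) next
      ## per-CE surviving-precursor intensities in the AIF traces
      seq_i <- i0
      for (ce in params$ce_scheme) {
        e <- extract_eic(sample, mz, params$precursor_tol, ms_level = 2L,
                         ce = ce, acquisition = "AIF")
        sel <- abs(e$rt - apex_rt) <= params$coelution_window
        seq_i <- c(seq_i, if (any(sel)) max(e$intensity[sel]) else 0)
      }
      dec <- all(utils::tail(seq_i, -1) <
                   utils::head(seq_i, -1) * (1 - params$dia_decrease_slack))
      if (!dec) next
      seen <- c(seen, mz)
      ## diagnostic evidence co-eluting with this candidate
      m_lab <- unique(diag_hits$label[abs(diag_hits$rt - apex_rt) <=
                                        params$coelution_window])
      m <- data.frame(label = m_lab,
                      mz = ions$mz[match(m_lab, ions$label)],
                      ppm = NA_real_, ce = NA_real_, stringsAsFactors = FALSE)
      cc <- .class_counts(m, registry)
      bh <- .blank_height(blanks, mz, apex_rt - 3 * params$coelution_window,
                          apex_rt + 3 * params$coelution_window,
                          params$precursor_tol)
      ratio <- if (bh <= 0) Inf else i0 / bh
      if (ratio < params$blank_ratio) next
      fc <- decompose_mass(mz, params$element_bounds)
      if (!nrow(fc)) next
      call_ <- if (max(cc) == 0L) "ambiguous"
               else if (cc[1] == cc[2]) "ambiguous"
               else names(cc)[which.max(cc)]
      rows[[length(rows) + 1L]] <- data.frame(
        precursor_mz = mz, rt = apex_rt, height = i0,
        n_matched = max(cc), blank_ratio_observed = ratio,
        class_call = call_, n_formulas = nrow(fc),
        top_formula = fc$formula[1], source = "DIA",
        stringsAsFactors = FALSE)
      matched_l[[length(rows)]] <- m
      formulas_l[[length(rows)]] <- fc
    }
  }
  .bind_candidates(rows, matched_l, formulas_l)
}

#' Export an inclusion list for targeted reacquisition
#'
#' One row per candidate with a retention-time window (default width 0.4
#' min) centered on the apex; candidates sharing an m/z at distinct
#' retention times stay distinct rows.
#'
#' @param candidates A `dfi_candidates` object.
#' @param rt_window Window width, minutes.
#' @param path Optional CSV path; written when given.
#' @return `data.frame(mz, rt_start, rt_end)` (m/z rounded to 4 decimals).
#' @export
export_inclusion_list <- function(candidates, rt_window = 0.4, path = NULL) {
  out <- data.frame(mz = round(candidates$precursor_mz, 4),
                    rt_start = candidates$rt - rt_window / 2,
                    rt_end = candidates$rt + rt_window / 2)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
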