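## Phase II conjugate screening on unhydrolyzed data, and
## hydrolyzed-vs-unhydrolyzed comparison for metabolite speciation.
##
## A conjugate precursor fragments by neutral loss of the conjugate moiety
## into the deprotonated free form, which then follows its own diagnostic
## pathways; sulfates additionally show the SO3 radical anion (79.9568)
## and sometimes hydrogensulfate (96.9596).

#' Screen a DDA run for phase II conjugates of target compounds
#'
#' For every target and conjugation type, ddMS2 spectra whose isolation
#' center lies within the precursor tolerance of [conjugate_mass()] are
#' merged and inspected for evidence ions: the free-form [M-H]- fragment,
#' the sulfate marker ions (sulfate only), and the free form's class
#' diagnostic ions. A hit requires the free-form fragment plus at least
#' one additional evidence ion.
#'
#' @param run A DDA [spectrum_run()] of an unhydrolyzed sample.
#' @param registry A [build_registry()] object.
#' @param targets `data.frame(name, formula, class)` of free-form
#'   compounds (e.g. from [paraben_compounds()]).
#' @param params A [screen_params()] object.
#' @param conjugations Conjugation types to screen (default all three).
#' @return `data.frame` with one row per hit: `conjugation`,
#'   `precursor_mz`, `rt`, `target`, `free_mz`, `n_evidence`, `evidence`
#'   (comma-joined ion names).
#' @export
screen_conjugates <- function(run, registry = build_registry(), targets,
                              params = screen_params(),
                              conjugations = c("sulfate", "glucuronide",
                                               "glycine")) {
  stopifnot(inherits(run, "spectrum_run"))
  if (run$mode != "DDA") stop("conjugate screening requires a DDA run")
  ms2 <- Filter(function(s) s$acquisition == "ddMS2", run$spectra)
  out <- list()
  if (!length(ms2)) return(.conjugate_hits_frame(out))
  pmz <- vapply(ms2, `[[`, numeric(1), "precursor_mz")
  rt2 <- vapply(ms2, `[[`, numeric(1), "rt")
  for (ti in seq_len(nrow(targets))) {
    free_formula <- targets$formula[ti]
    free_mz <- mz_deprotonated(free_formula)
    cls <- targets$class[ti]
    dions <- if (cls %in% c("paraben", "protocatechuate"))
      diagnostic_set(registry, cls, targets$name[ti])
    else registry[registry$screening, , drop = FALSE]
    for (cj in conjugations) {
      cmz <- conjugate_mass(free_formula, cj)
      sel <- which(abs(pmz - cmz) <= params$precursor_tol * 1e-6 * cmz)
      if (!length(sel)) next
      ## split co-isolated scans into rt clusters
      ord <- sel[order(rt2[sel])]
      cl <- cumsum(c(TRUE, diff(rt2[ord]) > 3 * params$coelution_window))
      for (ci in unique(cl)) {
        mem <- ord[cl == ci]
        merged <- do.call(rbind, lapply(mem, function(i) ms2[[i]]$peaks))
        near <- function(target, tol = params$fragment_tol)
          any(abs(merged[, "mz"] - target) <= target * tol * 1e-6)
        ev <- character(0)
        if (near(free_mz)) ev <- c(ev, "free_form")
        if (cj == "sulfate") {
          if (near(SULFATE_MARKERS[["SO3"]])) ev <- c(ev, "SO3")
          if (near(SULFATE_MARKERS[["HSO4"]])) ev <- c(ev, "HSO4")
        }
        for (k in seq_len(nrow(dions)))
          if (near(dions$mz[k])) ev <- c(ev, dions$label[k])
        if (!("free_form" %in% ev) || length(ev) < 2) next
        out[[length(out) + 1L]] <- data.frame(
          conjugation = cj, precursor_mz = stats::median(pmz[mem]),
          rt = stats::median(rt2[mem]), target = targets$name[ti],
          free_mz = free_mz, n_evidence = length(ev),
          evidence = paste(ev, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  .conjugate_hits_frame(out)
}

.conjugate_hits_frame <- function(rows) {
  if (!length(rows))
    return(data.frame(conjugation = character(), precursor_mz = numeric(),
                      rt = numeric(), target = character(),
                      free_mz = numeric(), n_evidence = integer(),
                      evidence = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare hydrolyzed and unhydrolyzed runs to infer speciation
#'
#' The free-form [M-H]- EIC apex height is measured in both runs with
#' identical parameters; the fold change (hydrolyzed / unhydrolyzed, with
#' undetected mapped to 0) and the presence of conjugate hits drive the
#' verdict rule table:
#' \itemize{
#'   \item `not_detected`: free form absent from both runs;
#'   \item `predominantly_conjugated`: fold >= `fold_conjugated` (default
#'     5), or the unhydrolyzed free form is undetected while a conjugate
#'     hit exists;
#'   \item `predominantly_free`: fold <= `fold_free` (default 1.5) and no
#'     conjugate hit;
#'   \item `partially_conjugated`: everything else.
#' }
#'
#' @param hydrolyzed,unhydrolyzed [spectrum_run()]s processed identically.
#' @param targets `data.frame(name, formula, class)`.
#' @param conjugate_hits Output of [screen_conjugates()] on the
#'   unhydrolyzed run.
#' @param params A [screen_params()].
#' @param fold_conjugated,fold_free Verdict thresholds (fold change).
#' @return `data.frame` per target: apex heights, fold change, conjugate
#'   evidence, verdict.
#' @export
compare_hydrolysis <- function(hydrolyzed, unhydrolyzed, targets,
                               conjugate_hits, params = screen_params(),
                               fold_conjugated = 5, fold_free = 1.5) {
  apex <- function(run, mz) {
    e <- extract_eic(run, mz, params$precursor_tol, ms_level = 1L)
    pk <- detect_peaks(e, min_snr = params$min_snr)
    if (nrow(pk)) pk$height[1] else 0
  }
  rows <- lapply(seq_len(nrow(targets)), function(ti) {
    mz <- mz_deprotonated(targets$formula[ti])
    h <- apex(hydrolyzed, mz)
    u <- apex(unhydrolyzed, mz)
    has_conj <- targets$name[ti] %in% conjugate_hits$target
    fold <- if (u > 0) h / u else if (h > 0) Inf else NA_real_
    verdict <-
      if (h == 0 && u == 0) "not_detected"
      else if ((u == 0 && has_conj) ||
               (!is.na(fold) && fold >= fold_conjugated)) "predominantly_conjugated"
      else if (!is.na(fold) && fold <= fold_free && !has_conj) "predominantly_free"
      else "partially_conjugated"
    data.frame(target = targets$name[ti], free_mz = mz,
               hydrolyzed_height = h, unhydrolyzed_height = u,
               fold_change = fold, conjugate_hit = has_conj,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
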