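## Spectral-library matching, Schymanski-scale confidence assignment, and
## QA/QC estimators (IDL, MDL upper bound, recovery, matrix effect, RSD).

#' Build an in-house MS2 spectral library
#'
#' @param entries List of entries, each `list(compound, precursor_mz, ce,
#'   peaks)` with `peaks` a two-column (m/z, intensity) matrix.
#' @return A `spectral_library` object.
#' @export
spectral_library <- function(entries) {
  entries <- lapply(entries, function(e) {
    p <- matrix(as.numeric(e$peaks), ncol = 2,
                dimnames = list(NULL, c("mz", "intensity")))
    e$peaks <- p[order(p[, 1]), , drop = FALSE]
    e
  })
  structure(list(entries = entries), class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library>", length(x$entries), "entries\n")
  invisible(x)
}

#' Read/write a spectral library in MSP text format
#'
#' @param library A `spectral_library`.
#' @param path MSP file path.
#' @return `read_msp` returns a `spectral_library`.
#' @export
write_msp <- function(library, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (e in library$entries) {
    writeLines(c(paste0("Name: ", e$compound),
                 paste0("PrecursorMZ: ", format(e$precursor_mz, digits = 10)),
                 paste0("CollisionEnergy: ", e$ce),
                 paste0("Num Peaks: ", nrow(e$peaks)),
                 paste(format(e$peaks[, 1], digits = 10),
                       format(e$peaks[, 2], digits = 10)),
                 ""), con)
  }
  invisible(path)
}

#' @rdname write_msp
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  entries <- list(); cur <- NULL; peaks <- NULL
  flush_entry <- function() {
    if (!is.null(cur)) {
      cur$peaks <- do.call(rbind, peaks)
      entries[[length(entries) + 1L]] <<- cur
    }
  }
  for (ln in lines) {
    if (grepl("^Name:", ln)) {
      flush_entry()
      cur <- list(compound = trimws(sub("^Name:", "", ln)),
                  precursor_mz = NA_real_, ce = NA_real_)
      peaks <- list()
    } else if (grepl("^PrecursorMZ:", ln)) {
      cur$precursor_mz <- as.numeric(sub("^PrecursorMZ:", "", ln))
    } else if (grepl("^CollisionEnergy:", ln)) {
      cur$ce <- as.numeric(sub("^CollisionEnergy:", "", ln))
    } else if (grepl("^[0-9]", trimws(ln))) {
      v <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
      peaks[[length(peaks) + 1L]] <- v[1:2]
    }
  }
  flush_entry()
  spectral_library(entries)
}

## cosine similarity of square-root-intensity-weighted, ppm-matched peak
## vectors, 0..1
.cosine_score <- function(query, ref, tol_ppm) {
  q <- matrix(as.numeric(query), ncol = 2)
  r <- matrix(as.numeric(ref), ncol = 2)
  if (!nrow(q) || !nrow(r)) return(0)
  ## greedy alignment: each reference peak takes the nearest unused query
  ## peak inside the ppm window
  used <- rep(FALSE, nrow(q))
  qv <- numeric(0); rv <- numeric(0)
  for (i in seq_len(nrow(r))) {
    win <- r[i, 1] * tol_ppm * 1e-6
    j <- which(!used & abs(q[, 1] - r[i, 1]) <= win)
    if (length(j)) {
      j <- j[which.min(abs(q[j, 1] - r[i, 1]))]
      used[j] <- TRUE
      qv <- c(qv, sqrt(q[j, 2])); rv <- c(rv, sqrt(r[i, 2]))
    } else {
      qv <- c(qv, 0); rv <- c(rv, sqrt(r[i, 2]))
    }
  }
  ## unmatched query peaks dilute the score
  if (any(!used)) {
    qv <- c(qv, sqrt(q[!used, 2])); rv <- c(rv, rep(0, sum(!used)))
  }
  den <- sqrt(sum(qv^2)) * sqrt(sum(rv^2))
  if (den == 0) 0 else sum(qv * rv) / den
}

#' Match an MS2 spectrum against a spectral library
#'
#' The score is 100 times the cosine similarity of
#' square-root-intensity-weighted, ppm-tolerance-matched peak vectors --
#' a transparent stand-in for proprietary library scores, with the
#' conventional acceptance threshold of 70. The best entry across
#' compounds and collision energies is returned.
#'
#' @param query Two-column (m/z, intensity) matrix; non-empty.
#' @param library A [spectral_library()].
#' @param tol_ppm Peak-match tolerance, ppm (default 10).
#' @return List with `compound`, `ce`, `score` (0-100); `compound = NA`
#'   for an empty library.
#' @export
match_spectrum <- function(query, library, tol_ppm = 10) {
  q <- matrix(as.numeric(query), ncol = 2)
  if (!nrow(q)) stop("query spectrum is empty")
  if (!length(library$entries))
    return(list(compound = NA_character_, ce = NA_real_, score = 0))
  scores <- vapply(library$entries, function(e)
    .cosine_score(q, e$peaks, tol_ppm), numeric(1))
  best <- which.max(scores)
  list(compound = library$entries[[best]]$compound,
       ce = library$entries[[best]]$ce, score = 100 * scores[best])
}

#' Schymanski-scale confidence level from annotation evidence
#'
#' Level 1: retention time confirmed against a reference standard with MS2
#' evidence. Level 2: no standard, but the gap between the QSRR-predicted
#' and the measured retention time is at most `delta_rt_threshold`
#' (default 1.0 min). Level 3: larger gaps. Decreasing the retention-time
#' gap can never worsen the level.
#'
#' @param standard_rt_match Logical: retention time matches a standard.
#' @param ms2_match Logical: MS2 evidence (library match or diagnostic
#'   ions) supports the structure.
#' @param delta_rt Absolute model-vs-measured RT gap, minutes (may be
#'   `NA` when a standard match is available).
#' @param delta_rt_threshold Level-2 cutoff, minutes (default 1.0; a
#'   stricter 0.5 is sometimes warranted for conjugate proposals).
#' @return Integer confidence level 1, 2 or 3.
#' @export
assign_confidence <- function(standard_rt_match = FALSE, ms2_match = FALSE,
                              delta_rt = NA_real_,
                              delta_rt_threshold = 1.0) {
  if (!isTRUE(standard_rt_match) && is.na(delta_rt))
    stop("need either a standard RT match or a delta RT")
  if (isTRUE(standard_rt_match) && isTRUE(ms2_match)) return(1L)
  if (!is.na(delta_rt) && delta_rt <= delta_rt_threshold) return(2L)
  3L
}

#' Instrument detection limit from a calibration S/N series
#'
#' The smallest calibration concentration whose precursor S/N strictly
#' exceeds 3.
#'
#' @param calibration `data.frame(conc, sn)`, concentrations ascending.
#' @param sn_threshold S/N cutoff (default 3; strict inequality).
#' @return IDL in the calibration units, or `NA` if no level passes.
#' @export
estimate_idl <- function(calibration, sn_threshold = 3) {
  if (!nrow(calibration)) stop("empty calibration table")
  if (is.unsorted(calibration$conc)) stop("concentrations must be ascending")
  pass <- calibration$conc[calibration$sn > sn_threshold]
  if (length(pass)) min(pass) else NA_real_
}

#' Method detection limit (upper bound) from spike levels
#'
#' The lowest spiking level at which the precursor signal is at least
#' `blank_ratio` times the process blank and a clear MS2 spectrum was
#' acquired in DDA.
#'
#' @param spikes `data.frame(conc, sample_height, blank_height,
#'   ms2_triggered)`, ascending concentrations.
#' @param blank_ratio Fold threshold (default 3).
#' @return MDL upper bound, or `NA` if no level qualifies.
#' @export
estimate_mdl <- function(spikes, blank_ratio = 3) {
  if (is.unsorted(spikes$conc)) stop("concentrations must be ascending")
  ok <- spikes$sample_height >= blank_ratio * spikes$blank_height &
    spikes$ms2_triggered
  if (any(ok)) min(spikes$conc[ok]) else NA_real_
}

#' Recovery and matrix effect from the post-extraction-spike scheme
#'
#' Recovery (%) = 100 (A_spiked - A_unspiked) /
#' (A_post_extraction_spiked - A_unspiked): the fraction of analyte
#' surviving extraction relative to analyte added after extraction.
#' Matrix effect (%) = 100 (A_post_extraction_spiked / A_solvent - 1):
#' negative values are ionization suppression.
#'
#' @param spiked,unspiked,post_extraction_spiked,solvent_standard Peak
#'   areas (>= 0).
#' @param nominal_conc Nominal spike concentration (> 0); recorded in the
#'   output.
#' @return List with `recovery_pct`, `matrix_effect_pct`, `nominal_conc`,
#'   and `flags` (character vector, e.g. zero denominators or negative
#'   recovery).
#' @export
recovery_and_matrix_effect <- function(spiked, unspiked,
                                       post_extraction_spiked,
                                       solvent_standard, nominal_conc) {
  stopifnot(all(c(spiked, unspiked, post_extraction_spiked,
                  solvent_standard) >= 0), nominal_conc > 0)
  flags <- character(0)
  den_rec <- post_extraction_spiked - unspiked
  recovery <- if (den_rec > 0) 100 * (spiked - unspiked) / den_rec else {
    flags <- c(flags, "undefined_recovery"); NA_real_
  }
  me <- if (solvent_standard > 0)
    100 * (post_extraction_spiked / solvent_standard - 1)
  else { flags <- c(flags, "undefined_matrix_effect"); NA_real_ }
  if (!is.na(recovery) && recovery < 0)
    flags <- c(flags, "negative_recovery")
  list(recovery_pct = recovery, matrix_effect_pct = me,
       nominal_conc = nominal_conc, flags = flags)
}

#' Relative standard deviation (percent)
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return `100 * sd(values) / mean(values)`.
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m == 0) stop("undefined RSD: zero mean")
  100 * stats::sd(values) / m
}
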