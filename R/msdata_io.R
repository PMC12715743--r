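## In-memory model of a centroided LC-MS/MS run plus mzML round-trip via
## mzR. Retention times are minutes everywhere; mzML stores seconds and the
## conversion happens at the I/O boundary.

#' Construct a single centroid spectrum
#'
#' @param ms_level 1 or 2.
#' @param rt Retention time, minutes.
#' @param peaks Two-column matrix (m/z, intensity), sorted by m/z.
#' @param ce Collision energy, eV (0 for full scans).
#' @param precursor_mz Isolation center for ddMS2 scans (NA otherwise).
#' @param iso_width Isolation width, Th (ddMS2).
#' @param acquisition `"full"`, `"ddMS2"` or `"AIF"`.
#' @return A `spectrum` list.
#' @export
spectrum <- function(ms_level, rt, peaks, ce = 0, precursor_mz = NA_real_,
                     iso_width = NA_real_, acquisition = c("full", "ddMS2", "AIF")) {
  acquisition <- match.arg(acquisition)
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(peaks) > 1 && is.unsorted(peaks[, 1])) {
    peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  }
  if (any(peaks[, 2] < 0)) stop("negative intensity")
  if (ms_level == 2 && acquisition == "full")
    stop("MS2 spectrum requires ddMS2 or AIF acquisition tag")
  if (acquisition == "ddMS2" && is.na(precursor_mz))
    stop("ddMS2 spectrum requires precursor information")
  structure(list(ms_level = as.integer(ms_level), rt = as.numeric(rt),
                 ce = as.numeric(ce), peaks = peaks,
                 precursor_mz = as.numeric(precursor_mz),
                 iso_width = as.numeric(iso_width),
                 acquisition = acquisition),
            class = "parascreen_spectrum")
}

#' Assemble spectra into a run
#'
#' @param spectra List of [spectrum()] objects; sorted by rt on assembly.
#' @param ce_scheme Collision-energy scheme in eV, default `c(10, 20, 40)`.
#' @param scan_range Full-scan m/z range, default `c(80, 1000)`.
#' @param isolation_width ddMS2 isolation width, Th, default 1.5.
#' @return An object of class `spectrum_run` with an inferred `mode`
#'   (`"DDA"`, `"DIA"` or `"full_only"`).
#' @export
spectrum_run <- function(spectra, ce_scheme = c(10, 20, 40),
                         scan_range = c(80, 1000), isolation_width = 1.5) {
  stopifnot(is.list(spectra))
  if (length(spectra)) {
    rt <- vapply(spectra, `[[`, numeric(1), "rt")
    spectra <- spectra[order(rt)]
  }
  acq <- vapply(spectra, `[[`, character(1), "acquisition")
  mode <- if (any(acq == "AIF")) "DIA" else if (any(acq == "ddMS2")) "DDA"
          else "full_only"
  if (mode != "full_only" && length(ce_scheme) == 0)
    stop("ce_scheme must be non-empty for DDA/DIA runs")
  structure(list(spectra = spectra, mode = mode,
                 ce_scheme = as.numeric(ce_scheme),
                 metadata = list(scan_range = as.numeric(scan_range),
                                 isolation_width = as.numeric(isolation_width))),
            class = "spectrum_run")
}

#' @export
print.spectrum_run <- function(x, ...) {
  n <- length(x$spectra)
  lev <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat(sprintf("<spectrum_run> mode=%s, %d spectra (%d MS1, %d MS2), CE scheme %s eV\n",
              x$mode, n, sum(lev == 1L), sum(lev == 2L),
              paste(x$ce_scheme, collapse = "/")))
  if (n) {
    rt <- range(vapply(x$spectra, `[[`, numeric(1), "rt"))
    cat(sprintf("  rt %.2f-%.2f min, scan range %g-%g m/z\n",
                rt[1], rt[2], x$metadata$scan_range[1], x$metadata$scan_range[2]))
  }
  invisible(x)
}

#' Write a run to centroid mzML
#'
#' ddMS2 scans carry their isolation center and width; AIF scans are
#' encoded with an isolation window spanning the full scan range, which is
#' how they are recognized again on reading.
#'
#' @param run A [spectrum_run()].
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "spectrum_run"))
  n <- length(run$spectra)
  sr <- run$metadata$scan_range
  if (n == 0L) {
    ## minimal valid empty centroid mzML (mzR cannot serialize 0 spectra)
    writeLines(c(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="empty">',
      '<cvList count="2">',
      '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '<cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
      '</cvList>',
      '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
      '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
      '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="0" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
      '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
      '<spectrumList count="0" defaultDataProcessingRef="dp">',
      '</spectrumList>',
      '</run>',
      '</mzML>',
      '</indexedmzML>'), path)
    return(invisible(path))
  }
  lev <- vapply(run$spectra, `[[`, integer(1), "ms_level")
  acq <- vapply(run$spectra, `[[`, character(1), "acquisition")
  rt_s <- vapply(run$spectra, `[[`, numeric(1), "rt") * 60
  ce <- vapply(run$spectra, `[[`, numeric(1), "ce")
  pmz <- vapply(run$spectra, `[[`, numeric(1), "precursor_mz")
  iso <- vapply(run$spectra, `[[`, numeric(1), "iso_width")
  iso[acq == "AIF"] <- diff(sr)
  pmz[acq == "AIF"] <- mean(sr)
  pk <- lapply(run$spectra, function(s) {
    p <- s$peaks
    if (nrow(p) == 0L) p <- matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("mz", "intensity")))
    p
  })
  npk <- vapply(pk, nrow, integer(1))
  tic <- vapply(pk, function(p) sum(p[, 2]), numeric(1))
  bp <- function(p, col) if (nrow(p)) p[which.max(p[, 2]), col] else 0
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lev,
    polarity = 0L, peaksCount = npk, totIonCurrent = tic,
    retentionTime = rt_s,
    basePeakMZ = vapply(pk, bp, numeric(1), 1L),
    basePeakIntensity = vapply(pk, bp, numeric(1), 2L),
    collisionEnergy = ifelse(lev == 2L, ce, 0),
    ionisationEnergy = 0, lowMZ = sr[1], highMZ = sr[2],
    precursorScanNum = 0L,
    precursorMZ = ifelse(lev == 2L, pmz, 0),
    precursorCharge = ifelse(lev == 2L, 1L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(lev == 2L, pmz, NA_real_),
    isolationWindowLowerOffset = ifelse(lev == 2L, iso / 2, NA_real_),
    isolationWindowUpperOffset = ifelse(lev == 2L, iso / 2, NA_real_),
    scanWindowLowerLimit = sr[1], scanWindowUpperLimit = sr[2],
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a centroid mzML file into a run
#'
#' Collision energy is taken from per-scan metadata; DDA vs DIA is inferred
#' from the MS2 isolation windows (narrow: ddMS2, full-range: AIF). Profile
#' spectra are rejected: the workflow operates on centroided data only.
#'
#' @param path mzML file.
#' @return A [spectrum_run()].
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0L) return(spectrum_run(list()))
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("profile-mode spectra are not supported; centroid the data first")
  sr <- c(min(hdr$scanWindowLowerLimit, na.rm = TRUE),
          max(hdr$scanWindowUpperLimit, na.rm = TRUE))
  if (!all(is.finite(sr))) sr <- c(80, 1000)
  spectra <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    p <- mzR::peaks(fh, i)
    if (is.null(dim(p))) p <- matrix(p, ncol = 2)
    lev <- hdr$msLevel[i]
    width <- hdr$isolationWindowLowerOffset[i] + hdr$isolationWindowUpperOffset[i]
    acqu <- if (lev == 1L) "full"
            else if (!is.na(width) && width > 10) "AIF" else "ddMS2"
    spectra[[i]] <- spectrum(
      ms_level = lev, rt = hdr$retentionTime[i] / 60, peaks = p,
      ce = ifelse(is.na(hdr$collisionEnergy[i]), 0, hdr$collisionEnergy[i]),
      precursor_mz = if (acqu == "ddMS2") hdr$precursorMZ[i] else NA_real_,
      iso_width = if (acqu == "ddMS2") width else NA_real_,
      acquisition = acqu)
  }
  ces <- sort(unique(vapply(spectra, `[[`, numeric(1), "ce")))
  ces <- ces[ces > 0]
  spectrum_run(spectra, ce_scheme = if (length(ces)) ces else c(10, 20, 40),
               scan_range = sr)
}

#' Extracted ion chromatogram
#'
#' Per qualifying scan, the intensity is the sum of all peak intensities
#' within `tol_ppm` of `target`; scans with no peak in the window
#' contribute zero, so the trace always covers every qualifying scan.
#'
#' @param run A [spectrum_run()].
#' @param target Target m/z (Th).
#' @param tol_ppm Window half-width in ppm (> 0).
#' @param ms_level Scan level to extract from (default 1).
#' @param ce Optional collision-energy filter (eV).
#' @param acquisition Optional acquisition filter (`"full"`, `"ddMS2"`, `"AIF"`).
#' @return An `eic` data.frame with columns `rt`, `intensity`.
#' @export
extract_eic <- function(run, target, tol_ppm = 10, ms_level = 1L, ce = NULL,
                        acquisition = NULL) {
  stopifnot(inherits(run, "spectrum_run"), tol_ppm > 0, target > 0)
  lo <- target * (1 - tol_ppm * 1e-6)
  hi <- target * (1 + tol_ppm * 1e-6)
  keep <- vapply(run$spectra, function(s) {
    s$ms_level == ms_level &&
      (is.null(ce) || isTRUE(all.equal(s$ce, ce))) &&
      (is.null(acquisition) || s$acquisition == acquisition)
  }, logical(1))
  sp <- run$spectra[keep]
  rt <- vapply(sp, `[[`, numeric(1), "rt")
  intensity <- vapply(sp, function(s) {
    p <- s$peaks
    sum(p[p[, 1] >= lo & p[, 1] <= hi, 2])
  }, numeric(1))
  structure(data.frame(rt = rt, intensity = intensity),
            target = target, tol_ppm = tol_ppm,
            class = c("eic", "data.frame"))
}

#' Detect chromatographic peaks in an EIC
#'
#' Local-maximum detection with a robust noise estimate: noise is the
#' median absolute deviation (scaled by 1.4826) of the trace after masking
#' detected peak regions; S/N is apex height over that noise. Peaks whose
#' S/N falls below `min_snr` are dropped. Deterministic.
#'
#' @param eic An [extract_eic()] trace.
#' @param min_snr Minimum signal-to-noise ratio (default 3).
#' @return `data.frame` with `rt`, `height`, `area`, `rt_min`, `rt_max`,
#'   `snr`, ordered by decreasing height.
#' @export
detect_peaks <- function(eic, min_snr = 3) {
  y <- eic$intensity
  rt <- eic$rt
  n <- length(y)
  empty <- data.frame(rt = numeric(), height = numeric(), area = numeric(),
                      rt_min = numeric(), rt_max = numeric(), snr = numeric())
  if (n < 3 || max(y) <= 0) return(empty)
  ## light 3-point smoothing for apex detection only; heights stay raw
  ys <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  ys[1] <- y[1]; ys[n] <- y[n]
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) ys[i - 1] else -Inf
    r <- if (i < n) ys[i + 1] else -Inf
    ys[i] > 0 && ys[i] >= l && ys[i] > r
  }, logical(1))
  apex <- which(is_max)
  if (!length(apex)) return(empty)
  ## suppress shoulder maxima: keep the higher of any two apexes < 3 scans apart
  apex <- apex[order(-ys[apex])]
  keep <- integer(0)
  for (a in apex) if (!any(abs(a - keep) < 3)) keep <- c(keep, a)
  apex <- sort(keep)
  ## peak bounds by monotone descent on the smoothed trace
  bounds <- lapply(apex, function(a) {
    l <- a; while (l > 1 && ys[l - 1] <= ys[l] && ys[l - 1] > 0) l <- l - 1
    r <- a; while (r < n && ys[r + 1] <= ys[r] && ys[r + 1] > 0) r <- r + 1
    c(l, r)
  })
  ## baseline and noise from the peak-free portion: first mask everything
  ## above 3 robust sigma of the whole trace, then re-estimate
  noise0 <- max(stats::mad(y), 1e-12)
  base0 <- stats::median(y)
  masked <- rep(FALSE, n)
  for (k in seq_along(apex))
    if (y[apex[k]] - base0 > 3 * noise0)
      masked[bounds[[k]][1]:bounds[[k]][2]] <- TRUE
  quiet <- y[!masked]
  baseline <- if (length(quiet)) stats::median(quiet) else 0
  noise <- if (length(quiet) > 2) stats::mad(quiet) else noise0
  if (!is.finite(noise) || noise <= 0) noise <- max(noise0, 1e-12)
  ## apex shape requirement: at least 3 scans above half height suppresses
  ## single-scan noise spikes
  wide_enough <- vapply(seq_along(apex), function(k) {
    idx <- bounds[[k]][1]:bounds[[k]][2]
    sum(ys[idx] - baseline >= (ys[apex[k]] - baseline) / 2) >= 3
  }, logical(1))
  out <- do.call(rbind, Map(function(a, b) {
    idx <- b[1]:b[2]
    area <- if (length(idx) > 1)
      sum(diff(rt[idx]) * (utils::head(y[idx], -1) + utils::tail(y[idx], -1)) / 2)
    else 0
    data.frame(rt = rt[a], height = y[a], area = area,
               rt_min = rt[b[1]], rt_max = rt[b[2]],
               snr = (ys[a] - baseline) / noise)
  }, apex, bounds))
  out <- out[wide_enough & out$snr >= min_snr, , drop = FALSE]
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an EIC or a peak table to CSV
#' @param x An `eic` or peak `data.frame`.
#' @param path Output path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
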