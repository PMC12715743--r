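test_that("mzML round-trip preserves scans, peaks and acquisition metadata", {
  g <- quick_run(seed = 11, compounds = list(spec_for("MeP")))
  f <- tempfile(fileext = ".mzML")
  write_run(g$run, f)
  r2 <- read_run(f)
  expect_identical(r2$mode, "DDA")
  expect_identical(length(r2$spectra), length(g$run$spectra))
  expect_equal(r2$ce_scheme, g$run$ce_scheme)
  for (i in seq_along(r2$spectra)) {
    a <- g$run$spectra[[i]]; b <- r2$spectra[[i]]
    expect_identical(a$ms_level, b$ms_level)
    expect_equal(a$rt, b$rt, tolerance = 1e-6)
    expect_equal(a$peaks[, 1], b$peaks[, 1], tolerance = 1e-4)
    if (nrow(a$peaks))
      expect_equal(a$peaks[, 2], b$peaks[, 2],
                   tolerance = 1e-3 * max(a$peaks[, 2]))
  }
  ## ddMS2 isolation width is written and read back as 1.5 Th
  ms2 <- Filter(function(s) s$acquisition == "ddMS2", r2$spectra)
  expect_gt(length(ms2), 0)
  expect_equal(unique(vapply(ms2, `[[`, numeric(1), "iso_width")), 1.5)
})

test_that("DIA runs round-trip with AIF tagging intact", {
  g <- quick_run(seed = 12, mode = "DIA", compounds = list(spec_for("EtP")))
  f <- tempfile(fileext = ".mzML")
  write_run(g$run, f)
  r2 <- read_run(f)
  expect_identical(r2$mode, "DIA")
  acq <- vapply(r2$spectra, `[[`, character(1), "acquisition")
  expect_setequal(unique(acq), c("full", "AIF"))
  ces <- vapply(Filter(function(s) s$acquisition == "AIF", r2$spectra),
                `[[`, numeric(1), "ce")
  expect_setequal(unique(ces), c(10, 20, 40))
})

test_that("an empty run writes a valid mzML and malformed input errors", {
  f <- tempfile(fileext = ".mzML")
  write_run(spectrum_run(list()), f)
  expect_length(read_run(f)$spectra, 0)
  bad <- tempfile(fileext = ".mzML")
  writeLines("", bad)
  expect_error(suppressWarnings(read_run(bad)))
  expect_error(read_run(tempfile(fileext = ".mzML")), "no such file")
})

test_that("profile-mode data is rejected loudly", {
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 0L,
    peaksCount = 2L, totIonCurrent = 3, retentionTime = 60,
    basePeakMZ = 100, basePeakIntensity = 2, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 80, highMZ = 1000, precursorScanNum = 0L,
    precursorMZ = 0, precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = "scan=1", centroided = FALSE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = 80,
    scanWindowUpperLimit = 1000, stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".mzML")
  mzR::writeMSData(list(cbind(mz = c(100, 101), intensity = c(1, 2))),
                   file = f, header = hdr)
  expect_error(read_run(f), "profile")
})

test_that("EICs match a naive per-scan windowed sum", {
  g <- quick_run(seed = 13, compounds = list(spec_for("PrP")))
  target <- mz_deprotonated("C10H12O3")
  e <- extract_eic(g$run, target, tol_ppm = 10, ms_level = 1L)
  full <- Filter(function(s) s$ms_level == 1L, g$run$spectra)
  naive <- vapply(full, function(s) {
    p <- s$peaks
    sum(p[abs(p[, 1] - target) <= target * 1e-5, 2])
  }, numeric(1))
  expect_equal(e$intensity, naive)
  expect_false(is.unsorted(e$rt, strictly = TRUE))
  ## absent channel gives an all-zero trace
  e0 <- extract_eic(g$run, 600, tol_ppm = 10, ms_level = 1L)
  expect_true(all(e0$intensity == 0))
})

test_that("ppm windowing separates nearby peaks", {
  run <- spectrum_run(lapply(1:5, function(i)
    spectrum(1L, i / 10, cbind(200.001, 1000))))  # 5 ppm off target 200
  hit <- extract_eic(run, 200, tol_ppm = 10)
  miss <- extract_eic(run, 200, tol_ppm = 1)
  expect_true(all(hit$intensity == 1000))
  expect_true(all(miss$intensity == 0))
})

test_that("peak detection recovers resolved Gaussians and ignores flat traces", {
  rt <- seq(0, 10, by = 0.02)
  gauss <- function(mu, h) h * exp(-(rt - mu)^2 / (2 * 0.064^2))
  set.seed(1)
  y <- gauss(3, 1e6) + gauss(7, 5e5) + abs(rnorm(length(rt), 0, 1e3))
  e <- structure(data.frame(rt = rt, intensity = y),
                 class = c("eic", "data.frame"))
  pk <- detect_peaks(e, min_snr = 3)
  expect_identical(nrow(pk), 2L)
  expect_equal(sort(pk$rt), c(3, 7), tolerance = 0.03)
  expect_true(all(pk$snr > 3))
  expect_true(all(pk$rt_min <= pk$rt & pk$rt <= pk$rt_max))
  flat <- structure(data.frame(rt = rt, intensity = rep(0, length(rt))),
                    class = c("eic", "data.frame"))
  expect_identical(nrow(detect_peaks(flat)), 0L)
})

test_that("peak detection recovers >=95% of injected peaks at 10x noise", {
  rt <- seq(0, 6, by = 0.02)
  found <- 0L; total <- 0L
  for (s in 1:100) {
    set.seed(s)
    mu <- runif(2, 1, 5)
    if (abs(diff(mu)) < 0.6) mu[2] <- mu[1] + 0.8
    noise <- 1e3
    y <- abs(rnorm(length(rt), 0, noise))
    for (m in mu) y <- y + 10 * noise * exp(-(rt - m)^2 / (2 * 0.064^2))
    e <- structure(data.frame(rt = rt, intensity = y),
                   class = c("eic", "data.frame"))
    pk <- detect_peaks(e, min_snr = 3)
    total <- total + 2L
    found <- found + sum(vapply(mu, function(m)
      any(abs(pk$rt - m) <= 0.06), logical(1)))
  }
  expect_gte(found / total, 0.95)
})
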