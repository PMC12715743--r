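blanks1 <- list(quick_blank(901))

test_that("DDA screening recovers all spiked analytes with correct classes", {
  g <- quick_run(seed = 21)
  cand <- screen_dda(g$run, blanks1)
  expect_identical(nrow(cand), 5L)
  for (i in seq_len(nrow(g$truth))) {
    hit <- which(abs(cand$precursor_mz - g$truth$mz[i]) <=
                   5e-6 * g$truth$mz[i])
    expect_length(hit, 1)
    expect_lt(abs(cand$rt[hit] - g$truth$rt[i]), 0.1)
    expect_gte(cand$n_matched[hit], 4)
    expect_identical(cand$class_call[hit],
                     sub("phenolic_acid", "paraben", g$truth$class[i]))
    expect_identical(attr(cand, "formula_candidates")[[hit]]$formula[1],
                     g$truth$formula[i])
  }
  ## MeP matched through its reduced applicable set
  mep <- which(abs(cand$precursor_mz - mz_deprotonated("C8H8O3")) < 0.01)
  expect_identical(cand$n_matched[mep], 5L)
  expect_false(any(c("A1", "B1") %in% matched_ions(cand)[[mep]]$label))
})

test_that("fragment mass errors of matched ions stay below the tolerance", {
  g <- quick_run(seed = 22)
  cand <- screen_dda(g$run, blanks1)
  for (m in matched_ions(cand)) expect_true(all(abs(m$ppm) < 10))
})

test_that("a blank screened against itself yields nothing", {
  b <- quick_blank(23)
  expect_identical(nrow(screen_dda(b, list(b))), 0L)
})

test_that("the benzophenone-like interference fails the >=4-ion rule", {
  g <- generate_run(list(spec_for("EtP")), mode = "DDA", seed = 24,
                    rt_range = c(5, 9))
  cand <- screen_dda(g$run, blanks1)
  ## interference elutes at 7.8 with only one diagnostic channel (91.0184)
  expect_false(any(abs(cand$precursor_mz - 213.0552) < 0.01))
  expect_true(any(abs(cand$precursor_mz - mz_deprotonated("C9H10O3")) < 0.01))
})

test_that("a precursor with only 3 diagnostic ions is excluded", {
  weak <- compound_spec("weak", "C8H8O3", 5.0, "paraben", conc = 25,
                        profile = list(`10` = c(A2 = .5),
                                       `20` = c(A2 = .5, B2 = .2, B3 = .2),
                                       `40` = c(A2 = .2, B2 = .3, B3 = .3)))
  g <- generate_run(list(weak), mode = "DDA", seed = 25, rt_range = c(4, 6))
  expect_identical(nrow(screen_dda(g$run, blanks1)), 0L)
  ## the same run passes once the threshold drops to 3
  p3 <- screen_params(min_diagnostic_ions = 3)
  expect_identical(nrow(screen_dda(g$run, blanks1, params = p3)), 1L)
})

test_that("candidate filters are monotone in their thresholds", {
  g <- quick_run(seed = 26)
  n_at <- function(k) nrow(screen_dda(g$run, blanks1,
                                      params = screen_params(min_diagnostic_ions = k)))
  counts <- vapply(c(1, 4, 6, 8), n_at, integer(1))
  expect_false(is.unsorted(rev(counts)))  # raising the rule never adds
  lo <- screen_dda(g$run, blanks1, params = screen_params(blank_ratio = 0.5))
  hi <- screen_dda(g$run, blanks1, params = screen_params(blank_ratio = 3))
  expect_true(all(round(hi$precursor_mz, 3) %in% round(lo$precursor_mz, 3)))
})

test_that("the blank ratio gate removes matrix-present channels", {
  g <- quick_run(seed = 27)
  ## a blank that already contains the MeP channel at comparable height
  fake_blank <- quick_run(seed = 28, compounds = list(spec_for("MeP")))$run
  cand <- screen_dda(g$run, list(fake_blank))
  expect_false(any(abs(cand$precursor_mz - mz_deprotonated("C8H8O3")) < 0.01))
  expect_true(any(abs(cand$precursor_mz - mz_deprotonated("C9H10O3")) < 0.01))
})

test_that("DIA screening applies the floor and the CE-decrease rule", {
  g <- quick_run(seed = 29, mode = "DIA")
  cand <- screen_dia(g$run, blanks1)
  for (i in seq_len(nrow(g$truth))) {
    hit <- which(abs(cand$precursor_mz - g$truth$mz[i]) <=
                   5e-6 * g$truth$mz[i])
    expect_length(hit, 1)
    expect_gte(cand$height[hit], 1e5)
  }
  ## below-floor species (1 ng/mL -> 3.4e4 apex) are never selected; only
  ## the above-floor benzophenone-like matrix channel may remain
  lo <- quick_run(seed = 30, mode = "DIA", conc = 1)
  lo_cand <- screen_dia(lo$run, blanks1)
  for (mz in lo$truth$mz)
    expect_false(any(abs(lo_cand$precursor_mz - mz) <= 5e-6 * mz))
})

test_that("a non-monotone CE series is rejected", {
  ## hand-built AIF cycle: full-scan precursor 1e6, AIF 5e5 / 7e5 / 1e5
  mzp <- mz_deprotonated("C8H8O3")
  frag <- 91.0184
  mk <- function(t, h, hf) {
    g <- exp(-(t - 5)^2 / (2 * 0.064^2))
    list(spectrum(1L, t, cbind(mzp, 1e6 * g)),
         spectrum(2L, t + 0.002, rbind(cbind(mzp, 5e5 * g), cbind(frag, hf * g)),
                  ce = 10, acquisition = "AIF"),
         spectrum(2L, t + 0.004, rbind(cbind(mzp, 7e5 * g), cbind(frag, hf * g)),
                  ce = 20, acquisition = "AIF"),
         spectrum(2L, t + 0.006, rbind(cbind(mzp, 1e5 * g), cbind(frag, hf * g)),
                  ce = 40, acquisition = "AIF"))
  }
  run <- spectrum_run(do.call(c, lapply(seq(4, 6, 0.02), mk, h = 1e6, hf = 2e5)))
  expect_identical(nrow(screen_dia(run, blanks1)), 0L)
})

test_that("DDA and DIA report the same analytes at matching m/z and rt", {
  specs <- quick_specs()
  a <- quick_run(seed = 31, compounds = specs)
  b <- quick_run(seed = 31, mode = "DIA", compounds = specs)
  ca <- screen_dda(a$run, blanks1)
  cb <- screen_dia(b$run, blanks1)
  for (i in seq_len(nrow(a$truth))) {
    ia <- which(abs(ca$precursor_mz - a$truth$mz[i]) <= 5e-6 * a$truth$mz[i])
    ib <- which(abs(cb$precursor_mz - a$truth$mz[i]) <= 5e-6 * a$truth$mz[i])
    expect_length(ia, 1); expect_length(ib, 1)
    expect_lt(abs(ca$rt[ia] - cb$rt[ib]), 0.1)
    expect_lt(abs(ppm_error(ca$precursor_mz[ia], cb$precursor_mz[ib])), 10)
  }
})

test_that("inclusion lists center a 0.4 min window on the apex", {
  cand <- structure(data.frame(precursor_mz = c(151.03952, 151.03952),
                               rt = c(6.20, 8.10)),
                    class = c("dfi_candidates", "data.frame"))
  il <- export_inclusion_list(cand)
  expect_identical(nrow(il), 2L)  # same m/z, distinct rt: no merging
  expect_equal(il$mz, c(151.0395, 151.0395))
  expect_equal(il$rt_start[1], 6.0)
  expect_equal(il$rt_end[1], 6.4)
  f <- tempfile(fileext = ".csv")
  export_inclusion_list(cand, path = f)
  expect_identical(nrow(utils::read.csv(f)), 2L)
  empty <- export_inclusion_list(.rows <- structure(
    data.frame(precursor_mz = numeric(), rt = numeric()),
    class = c("dfi_candidates", "data.frame")))
  expect_identical(nrow(empty), 0L)
})

test_that("mode preconditions are enforced", {
  dda <- quick_run(seed = 32, compounds = list(spec_for("MeP")))$run
  dia <- quick_run(seed = 32, mode = "DIA", compounds = list(spec_for("MeP")))$run
  expect_error(screen_dda(dia, blanks1), "DDA")
  expect_error(screen_dia(dda, blanks1), "DIA")
  expect_error(screen_dda(dda, list()), "blank")
})
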