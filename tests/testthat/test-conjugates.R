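targets <- std_compounds[std_compounds$name %in%
                           c("MeP", "EtP", "PrP", "4-HB", "3,4-DHB",
                             "OH-MeP"), ]

sulfate_spec <- function(name, rt_shift = 0.5, conc = 25) {
  r <- std_compounds[std_compounds$name == name, ]
  compound_spec(paste0(name, "-sulfate"), r$formula, r$rt - rt_shift,
                r$class, conc = conc, conjugation = "sulfate")
}

test_that("a simulated MeP sulfate yields one hit with the marker-ion evidence", {
  g <- generate_run(list(sulfate_spec("MeP")), mode = "DDA", seed = 41,
                    rt_range = c(4, 7))
  hits <- screen_conjugates(g$run, targets = targets)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$target, "MeP")
  expect_identical(hits$conjugation, "sulfate")
  expect_equal(hits$precursor_mz, 230.9963, tolerance = 0.005)
  expect_gte(hits$n_evidence, 3)
  ev <- strsplit(hits$evidence, ",")[[1]]
  expect_true("free_form" %in% ev)
  expect_true("SO3" %in% ev)
  ## the conjugate-free-form mass linkage closes to within 5 ppm
  expect_lt(abs(1e6 * (hits$precursor_mz - hits$free_mz -
                         (conjugate_mass("C8H8O3", "sulfate") -
                            mz_deprotonated("C8H8O3"))) / hits$precursor_mz), 5)
})

test_that("all six sulfate species link to their correct free forms", {
  specs <- lapply(c("MeP", "EtP", "PrP", "4-HB", "3,4-DHB", "OH-MeP"),
                  sulfate_spec)
  g <- generate_run(specs, mode = "DDA", seed = 42, rt_range = c(2.5, 8))
  hits <- screen_conjugates(g$run, targets = targets)
  sul <- hits[hits$conjugation == "sulfate", ]
  expect_setequal(sul$target, c("MeP", "EtP", "PrP", "4-HB", "3,4-DHB",
                                "OH-MeP"))
  expect_identical(nrow(sul), 6L)
  expect_identical(nrow(hits[hits$conjugation == "glucuronide", ]), 0L)
  expect_identical(nrow(hits[hits$conjugation == "glycine", ]), 0L)
})

test_that("a precursor at the conjugate mass without the free-form fragment is no hit", {
  ## impostor: right precursor m/z, fragments unrelated to MeP
  impostor <- compound_spec("impostor", "C8H8O6S", 5.5, "paraben", conc = 25,
                            profile = list(`10` = c(`120.0000` = .5),
                                           `20` = c(`120.0000` = .5),
                                           `40` = c(`120.0000` = .5)))
  expect_equal(impostor$mz, conjugate_mass("C8H8O3", "sulfate"),
               tolerance = 1e-6)
  g <- generate_run(list(impostor), mode = "DDA", seed = 43, rt_range = c(5, 6))
  expect_identical(nrow(screen_conjugates(g$run, targets = targets)), 0L)
})

test_that("no sulfate hits arise from sulfate-free runs", {
  for (s in 44:47) {
    g <- quick_run(seed = s, compounds = list(spec_for("MeP"), spec_for("EtP")))
    expect_identical(nrow(screen_conjugates(g$run, targets = targets)), 0L,
                     label = sprintf("seed %d", s))
  }
})

test_that("hydrolysis comparison applies the verdict rule table", {
  ## predominantly conjugated: 10-fold gain on hydrolysis + sulfate hit
  free25 <- list(spec_for("MeP", conc = 25))
  free2 <- list(spec_for("MeP", conc = 2.5))
  hyd <- generate_run(free25, mode = "DDA", seed = 48, rt_range = c(5, 7))$run
  unhyd <- generate_run(c(free2, list(sulfate_spec("MeP"))), mode = "DDA",
                        seed = 49, rt_range = c(5, 7))$run
  hits <- screen_conjugates(unhyd, targets = targets)
  rep1 <- compare_hydrolysis(hyd, unhyd, targets[targets$name == "MeP", ], hits)
  expect_identical(rep1$verdict, "predominantly_conjugated")
  expect_gte(rep1$fold_change, 5)
  expect_true(rep1$conjugate_hit)

  ## predominantly free: equal apexes, no conjugate
  h2 <- generate_run(free25, mode = "DDA", seed = 50, rt_range = c(5, 7))$run
  u2 <- generate_run(free25, mode = "DDA", seed = 51, rt_range = c(5, 7))$run
  rep2 <- compare_hydrolysis(h2, u2, targets[targets$name == "MeP", ],
                             screen_conjugates(u2, targets = targets))
  expect_identical(rep2$verdict, "predominantly_free")

  ## not detected anywhere
  b1 <- quick_blank(52); b2 <- quick_blank(53)
  rep3 <- compare_hydrolysis(b1, b2, targets[targets$name == "PrP", ],
                             screen_conjugates(
                               generate_run(list(), matrix = NULL, seed = 54,
                                            rt_range = c(3, 9))$run,
                               targets = targets))
  expect_identical(rep3$verdict, "not_detected")
})

test_that("verdicts are perfect on a mixed ground-truth panel", {
  panel <- list(
    list(name = "MeP", hyd = 25, unhyd = 2.5, conj = TRUE,
         want = "predominantly_conjugated"),
    list(name = "EtP", hyd = 25, unhyd = 25, conj = FALSE,
         want = "predominantly_free"),
    list(name = "PrP", hyd = 25, unhyd = 10, conj = TRUE,
         want = "partially_conjugated"))
  hyd_specs <- lapply(panel, function(p) spec_for(p$name, conc = p$hyd))
  unhyd_specs <- lapply(panel, function(p) spec_for(p$name, conc = p$unhyd))
  conj_specs <- lapply(Filter(function(p) p$conj, panel),
                       function(p) sulfate_spec(p$name))
  hyd <- generate_run(hyd_specs, mode = "DDA", seed = 55, rt_range = c(4, 9))$run
  unhyd <- generate_run(c(unhyd_specs, conj_specs), mode = "DDA", seed = 56,
                        rt_range = c(4, 9))$run
  hits <- screen_conjugates(unhyd, targets = targets)
  tg <- targets[match(vapply(panel, `[[`, character(1), "name"), targets$name), ]
  rep <- compare_hydrolysis(hyd, unhyd, tg, hits)
  expect_identical(rep$verdict, vapply(panel, `[[`, character(1), "want"))
})
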