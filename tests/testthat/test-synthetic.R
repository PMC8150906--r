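# Synthetic-data generators: determinism, ground-truth round trips,
# calibration of the planted noise levels.

test_that("identical scenario specs give identical outputs", {
  s1 <- scenario_spec(seed = 42)
  s2 <- scenario_spec(seed = 42)
  t1 <- gen_traces(s1)
  t2 <- gen_traces(s2)
  expect_identical(t1, t2)
  expect_identical(gen_compound_table(s1), gen_compound_table(s2))
  o1 <- gen_oxidation_curves(s1)
  o2 <- gen_oxidation_curves(s2)
  expect_identical(o1, o2)
  # and a different seed gives different noise
  expect_false(identical(t1[[1]]$absorbance,
                         gen_traces(scenario_spec(seed = 43))[[1]]$absorbance))
})

test_that("written scenario directories are byte-identical across runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(scenario_spec(seed = 7), d1)
  write_scenario(scenario_spec(seed = 7), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_gt(length(f1), 60)  # traces + oxidation + table + manifest
})

test_that("noiseless traces let fit_first_order recover the planted k_obs", {
  sp <- scenario_spec(seed = 1, trace_sigma = 0, kobs_cv = 0)
  traces <- gen_traces(sp)
  tr <- traces[[1]]
  row <- sp$compounds[sp$compounds$compound == attr(tr, "compound"), ]
  part <- if (row$region_pair == "water_interface")
    partition_set(p_wi = row$p) else partition_set(p_oi = row$p)
  k_true <- kobs_model(row$k_i, part,
                       emulsion_composition(sp$phi_oil, sp$phi_water,
                                            attr(tr, "phi_interface")),
                       sp$total_ao)
  fit <- fit_first_order(tr)
  expect_equal(fit$k_obs, k_true, tolerance = 1e-7)
})

test_that("replicate scatter of fitted k_obs averages inside the 7-9% band", {
  cvs <- unlist(lapply(1:5, function(seed) {
    sp <- scenario_spec(seed = seed, trace_sigma = 0)  # isolate k-level CV
    fits <- lapply(gen_traces(sp), fit_first_order)
    by_c <- split(fits, vapply(fits, function(f) f$compound, character(1)))
    unlist(lapply(names(by_c), function(nm) {
      pair <- sp$compounds$region_pair[sp$compounds$compound == nm]
      aggregate_kobs(by_c[[nm]], total_ao = sp$total_ao,
                     region_pair = pair)$summary$cv
    }))
  }))
  expect_gte(mean(cvs), 0.07)
  expect_lte(mean(cvs), 0.09)
})

test_that("oxidation curves encode the planted induction times", {
  sp <- scenario_spec(seed = 1, cd_sigma = 0, t_control = 10)
  sp$compounds$t_induction[1] <- 170  # plant a 16-fold compound
  ox <- gen_oxidation_curves(sp, stability_from = "t_induction")
  st <- relative_stability(ox$samples[[1]], ox$control)
  expect_equal(st$relative_increase, 16.0, tolerance = 0.02)
  expect_equal(st$t_control, 10, tolerance = 0.05)
  # control-only scenario: every stability is 0
  sp0 <- scenario_spec(seed = 1, cd_sigma = 0)
  sp0$compounds$t_induction <- rep(sp0$t_control, nrow(sp0$compounds))
  ox0 <- gen_oxidation_curves(sp0, stability_from = "t_induction")
  for (cu in ox0$samples)
    expect_equal(relative_stability(cu, ox0$control)$relative_increase, 0,
                 tolerance = 1e-6)
  expect_error(gen_oxidation_curves(
    scenario_spec(seed = 1, t_control = -1)), "positive")
})

test_that("default-mode curves encode the planted linear stability model", {
  sp <- scenario_spec(seed = 4, cd_sigma = 0)
  for (phi in sp$phi_levels[1:2]) {
    ox <- gen_oxidation_curves(sp, phi = phi)
    comp <- emulsion_composition(sp$phi_oil, sp$phi_water, phi)
    for (ci in seq_len(nrow(sp$compounds))) {
      row <- sp$compounds[ci, ]
      prof <- distribution_two_region(
        if (row$region_pair == "water_interface")
          partition_set(p_wi = row$p) else partition_set(p_oi = row$p),
        comp, sp$total_ao)
      mu <- sp$beta0 + sp$beta[["c_interface"]] * prof$c_interface * 1e3 +
        sp$beta[["epa"]] * row$epa +
        sp$beta[["c_water"]] * prof$c_water * 1e3
      st <- relative_stability(ox$samples[[row$compound]], ox$control)
      expect_equal(st$relative_increase, max(mu, 0.02), tolerance = 5e-3)
      expect_equal(ox$planted_stability[[row$compound]], max(mu, 0.02),
                   tolerance = 1e-12)
    }
  }
})

test_that("compound table carries the planted linear structure", {
  sp <- scenario_spec(seed = 1, stability_sigma = 0)
  tab <- gen_compound_table(sp)
  # beta = (1, 0, 0), sigma = 0: stability is exactly proportional to
  # c_interface
  sp1 <- scenario_spec(seed = 1, stability_sigma = 0,
                       beta = c(c_interface = 1, epa = 0, c_water = 0),
                       beta0 = 0)
  tab1 <- gen_compound_table(sp1)
  expect_equal(pearson_matrix(tab1, "relative_stability", "c_interface")$r,
               1, tolerance = 1e-12)
  # default spec: c_interface is selected first
  m <- suppressWarnings(stepwise_regression(
    tab, "relative_stability", c("c_interface", "epa", "c_water")))
  expect_identical(m$predictors[1], "c_interface")
  # concentrations agree with the distribution model on the true constants
  row <- sp$compounds[2, ]
  prof <- distribution_two_region(
    partition_set(p_oi = row$p),
    emulsion_composition(sp$phi_oil, sp$phi_water, sp$phi_levels[2]),
    sp$total_ao)
  got <- tab[tab$compound == row$compound &
               tab$phi_interface == sp$phi_levels[2], ]
  expect_equal(got$c_interface, prof$c_interface * 1e3, tolerance = 1e-12)
})

test_that("generated datasets satisfy their consumers' preconditions", {
  sp <- scenario_spec(seed = 13)
  for (tr in gen_traces(sp)) {
    expect_s3_class(tr, "absorbance_trace")   # constructor validates
    expect_gte(nrow(tr), 5)
  }
  ox <- gen_oxidation_curves(sp)
  expect_s3_class(ox$control, "oxidation_curve")
  tab <- gen_compound_table(sp)
  expect_true(all(complete.cases(
    tab[, c("relative_stability", "c_interface", "epa", "c_water")])))
})
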