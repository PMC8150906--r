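# Pseudophase distribution math: two- and three-region profiles,
# conservation, monotonicity, limits.

comp_at <- function(phi_i) emulsion_composition(0.4, 0.6, phi_i)
AOT <- 0.24e-3

test_that("composition and partition constructors enforce their invariants", {
  expect_error(emulsion_composition(0, 0.6, 0.01), "between 0 and 1")
  expect_error(emulsion_composition(0.5, 0.6, 0.01), "sum above 1.05")
  expect_warning(emulsion_composition(0.3, 0.6, 0.1), "outside the usual")
  expect_error(partition_set(), "at least one")
  expect_error(partition_set(p_oi = -1), ">= 0")
  expect_error(distribution_two_region(
    partition_set(p_oi = 368, p_wi = 53), comp_at(0.01), AOT), "both")
})

test_that("two-region water+interface profile matches the closed form", {
  # hydroxytyrosol-like constant: 47-fold interfacial enhancement at
  # phi_I = 0.01
  prof <- distribution_two_region(partition_set(p_wi = 53), comp_at(0.01),
                                  AOT)
  expect_equal(prof$f_interface, 53 * 0.01 / (0.6 + 53 * 0.01))
  expect_equal(prof$f_water, 1 - prof$f_interface)
  expect_identical(prof$f_oil, 0)
  expect_identical(prof$c_oil, 0)
  expect_equal(round(interfacial_enhancement(prof)), 47)
  # mass balance
  expect_equal(prof$c_interface * 0.01 + prof$c_water * 0.6, AOT,
               tolerance = 1e-9)
})

test_that("octyl dihydrocaffeate reaches ~39 mM interfacially at phi_I = 0.005", {
  prof <- distribution_two_region(partition_set(p_oi = 368),
                                  comp_at(0.005), AOT)
  expect_equal(round(prof$c_interface * 1e3), 39)
  expect_equal(prof$f_interface, 368 * 0.005 / (0.4 + 368 * 0.005))
})

test_that("zero partition constant puts everything in the bulk region", {
  prof <- distribution_two_region(partition_set(p_wi = 0), comp_at(0.01),
                                  AOT)
  expect_identical(prof$f_interface, 0)
  expect_identical(prof$f_water, 1)
  expect_identical(prof$c_interface, 0)
})

test_that("three-region profile agrees with a brute-force mass-balance solver", {
  cases <- list(c(500, 200), c(1, 1), c(368, 53), c(0.2, 40))
  for (ps in cases) {
    comp <- comp_at(0.005)
    prof <- distribution_three_region(
      partition_set(p_oi = ps[1], p_wi = ps[2]), comp, AOT)
    oracle <- brute_force_three_region(ps[1], ps[2], 0.4, 0.6, 0.005, AOT)
    expect_equal(c(prof$f_oil, prof$f_water, prof$f_interface),
                 unname(oracle$f), tolerance = 1e-9)
    expect_equal(c(prof$c_oil, prof$c_water, prof$c_interface),
                 unname(oracle$c), tolerance = 1e-9)
  }
})

test_that("equal partition constants distribute in proportion to region volume", {
  prof <- distribution_three_region(partition_set(p_oi = 1, p_wi = 1),
                                    comp_at(0.005), AOT)
  tot <- 0.4 + 0.6 + 0.005
  expect_equal(prof$f_oil, 0.4 / tot, tolerance = 1e-12)
  expect_equal(prof$f_water, 0.6 / tot, tolerance = 1e-12)
  expect_equal(prof$f_interface, 0.005 / tot, tolerance = 1e-12)
})

test_that("a huge constant collapses three regions to the two-region limit", {
  comp <- comp_at(0.01)
  three <- distribution_three_region(
    partition_set(p_oi = 5e9, p_wi = 53), comp, AOT)
  two <- distribution_two_region(partition_set(p_wi = 53), comp, AOT)
  expect_equal(three$f_interface, two$f_interface, tolerance = 1e-6)
  expect_equal(three$c_interface, two$c_interface, tolerance = 1e-6)
  expect_equal(three$f_oil, 0, tolerance = 1e-6)
  # and a merely-large but sub-threshold constant converges numerically
  near <- distribution_three_region(
    partition_set(p_oi = 1e8, p_wi = 53), comp, AOT)
  expect_equal(near$f_interface, two$f_interface, tolerance = 1e-6)
})

test_that("mass is conserved and fractions sum to 1 on a randomized grid", {
  set.seed(42)
  n <- 2000
  p1 <- 10^runif(n, -1, 3)
  p2 <- 10^runif(n, -1, 3)
  phi <- runif(n, 0.005, 0.04)
  for (i in seq_len(n)) {
    comp <- comp_at(phi[i])
    prof <- distribution_three_region(
      partition_set(p_oi = p1[i], p_wi = p2[i]), comp, AOT)
    expect_lt(abs(prof$f_oil + prof$f_water + prof$f_interface - 1), 1e-9)
    expect_lt(abs(prof$c_oil * 0.4 + prof$c_water * 0.6 +
                    prof$c_interface * phi[i] - AOT), 1e-9 * AOT)
  }
})

test_that("interfacial fraction rises but interfacial concentration falls with phi_I", {
  # the dilution paradox: more emulsifier recruits a larger share of the
  # antioxidant into a disproportionately larger interfacial volume
  set.seed(43)
  for (p in 10^runif(20, -1, 3)) {
    phis <- sort(runif(8, 0.005, 0.04))
    profs <- lapply(phis, function(ph) distribution_two_region(
      partition_set(p_wi = p), comp_at(ph), AOT))
    f <- vapply(profs, function(x) x$f_interface, numeric(1))
    cc <- vapply(profs, function(x) x$c_interface, numeric(1))
    expect_true(all(diff(f) > 0))
    expect_true(all(diff(cc) < 0))
  }
})

test_that("error cases: no interfacial volume, bad partition input", {
  expect_error(distribution_two_region(partition_set(p_wi = 53),
                                       comp_at(0.01), 0), "positive")
  expect_error(distribution_three_region(partition_set(p_oi = 368),
                                         comp_at(0.01), AOT),
               "both partition constants")
})
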