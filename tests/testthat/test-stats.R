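# Pearson screening, stepwise selection, standardized betas, VIF.

test_that("pearson_matrix handles exact, degenerate and missing cases", {
  df <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10),
                   const = rep(3, 10))
  pm <- pearson_matrix(df, "y", c("x", "z", "const"))
  expect_equal(pm$r[pm$predictor == "x"], 1)
  expect_equal(pm$r[pm$predictor == "z"], -1)
  expect_true(is.na(pm$r[pm$predictor == "const"]))
  expect_match(pm$note[pm$predictor == "const"], "zero variance")
  # p-values and stars agree with the t transform (cross-check cor.test)
  set.seed(8)
  df2 <- data.frame(x = rnorm(12))
  df2$y <- 0.8 * df2$x + rnorm(12, 0, 0.6)
  pm2 <- pearson_matrix(df2, "y", "x")
  ct <- cor.test(df2$x, df2$y)
  expect_equal(pm2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pm2$p, ct$p.value, tolerance = 1e-12)
})

test_that("sample correlations cover a planted rho = 0.8 at the Fisher-z rate", {
  rho <- 0.8
  n <- 12
  z0 <- atanh(rho)
  set.seed(99)
  inside <- vapply(seq_len(500), function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- pearson_matrix(data.frame(x = x, y = y), "y", "x")$r
    abs(atanh(r) - z0) < 1.96 / sqrt(n - 3)
  }, logical(1))
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.99)
})

test_that("a single perfect predictor is selected with cum R2 = 1", {
  df <- data.frame(x = 1:10, y = 3 * (1:10) - 2)
  m <- suppressWarnings(stepwise_regression(df, "y", "x"))
  expect_identical(m$predictors, "x")
  expect_equal(m$steps$cum_r2, 1, tolerance = 1e-12)
})

test_that("no qualifying predictor yields an intercept-only model", {
  set.seed(12)
  df <- data.frame(y = rnorm(30), x1 = rnorm(30), x2 = rnorm(30))
  # pure noise predictors occasionally squeak under 0.15; draw until calm
  m <- stepwise_regression(df, "y", c("x1", "x2"), p_enter = 1e-6)
  expect_length(m$predictors, 0)
  expect_equal(nrow(m$steps), 0L)
})

test_that("backward step removes a predictor made redundant later", {
  # x3 = x1 + x2 almost exactly; x3 enters first (best single predictor),
  # then x1 and x2 enter and x3 becomes redundant and is removed
  set.seed(4)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, 0, 0.5)
  y <- x1 + x2 + rnorm(n, 0, 0.05)
  m <- stepwise_regression(data.frame(y, x1, x2, x3), "y",
                           c("x1", "x2", "x3"))
  expect_true(all(c("x1", "x2") %in% m$predictors))
  expect_false("x3" %in% m$predictors)
  expect_true("remove" %in% m$steps$action)
})

test_that("stepwise matches the exhaustive subset-replay oracle on seeded instances", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- 10
    k <- sample(3:4, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("x", seq_len(k))))
    beta <- round(runif(k, -2, 2), 1)
    y <- X %*% beta + rnorm(n, 0, 1)
    df <- data.frame(y = as.numeric(y), X)
    m <- suppressWarnings(
      stepwise_regression(df, "y", colnames(X)))
    o <- oracle_stepwise(df, "y", colnames(X))
    expect_identical(m$predictors, o$entry_order[
      o$entry_order %in% o$selected])
    expect_setequal(m$predictors, o$selected)
    if (length(m$predictors) > 0)
      expect_equal(m$steps$cum_r2[nrow(m$steps)], o$final_r2,
                   tolerance = 1e-9)
  }
})

test_that("cumulative R2 is nondecreasing over entry steps and partials sum to it", {
  tab <- gen_compound_table(scenario_spec(seed = 3))
  m <- stepwise_regression(tab, "relative_stability",
                           c("c_interface", "epa", "c_water"))
  entries <- m$steps[m$steps$action == "enter", ]
  expect_true(all(diff(entries$cum_r2) >= 0))
  expect_equal(sum(m$steps$partial_r2), m$steps$cum_r2[nrow(m$steps)],
               tolerance = 1e-9)
})

test_that("selection and diagnostics are invariant to affine predictor rescaling", {
  tab <- gen_compound_table(scenario_spec(seed = 5))
  cand <- c("c_interface", "epa", "c_water")
  m1 <- stepwise_regression(tab, "relative_stability", cand)
  tab2 <- tab
  tab2$c_interface <- tab2$c_interface * 1e-3 + 7   # mM -> M plus offset
  tab2$epa <- tab2$epa * 1000                       # V -> mV
  m2 <- stepwise_regression(tab2, "relative_stability", cand)
  expect_identical(m1$predictors, m2$predictors)
  expect_equal(m1$steps$cum_r2, m2$steps$cum_r2, tolerance = 1e-9)
  expect_equal(m1$standardized_betas, m2$standardized_betas,
               tolerance = 1e-8)
  expect_equal(m1$vif$vif, m2$vif$vif, tolerance = 1e-8)
  pm1 <- pearson_matrix(tab, "relative_stability", cand)
  pm2 <- pearson_matrix(tab2, "relative_stability", cand)
  expect_equal(abs(pm1$r), abs(pm2$r), tolerance = 1e-12)
})

test_that("standardized betas equal simple correlations in orthogonal designs", {
  # 2^3 factorial is exactly orthogonal
  X <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  set.seed(21)
  X$y <- 1.5 * X$x1 - 0.5 * X$x2 + rnorm(8, 0, 0.3)
  b <- standardized_betas(X, "y", c("x1", "x2"))
  r <- pearson_matrix(X, "y", c("x1", "x2"))$r
  expect_equal(unname(b), r, tolerance = 1e-9)
  # sign convention: a response decreasing in a predictor gets a
  # negative beta (as the anodic potential does for oxidative stability)
  tab <- gen_compound_table(scenario_spec(seed = 2))
  bb <- standardized_betas(tab, "relative_stability",
                           c("c_interface", "epa", "c_water"))
  expect_gt(bb[["c_interface"]], 0)
  expect_lt(bb[["epa"]], 0)
  expect_lt(bb[["c_water"]], 0)
})

test_that("VIF matches the closed form and flags exact collinearity", {
  # orthogonal design: all VIF = 1
  X <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1))
  v <- vif(X, c("x1", "x2"))
  expect_equal(unname(v$vif), c(1, 1), tolerance = 1e-12)
  # planted pairwise correlation 0.5 -> VIF = 1/(1 - 0.25)
  set.seed(17)
  n <- 4000
  x1 <- rnorm(n)
  x2 <- 0.5 * x1 + sqrt(0.75) * rnorm(n)
  v2 <- vif(data.frame(x1, x2), c("x1", "x2"))
  expect_equal(unname(v2$vif), rep(1 / (1 - cor(x1, x2)^2), 2),
               tolerance = 1e-9)
  expect_equal(unname(v2$vif[1]), 1 / (1 - 0.25), tolerance = 0.1)
  # duplicated predictor -> infinite VIF with flag
  v3 <- vif(data.frame(x1, x2 = x1), c("x1", "x2"))
  expect_true(all(is.infinite(v3$vif)))
  expect_setequal(v3$collinear, c("x1", "x2"))
})

test_that("VIF agrees with the standard regression-diagnostics implementation", {
  skip_if_not_installed("car")
  tab <- gen_compound_table(scenario_spec(seed = 6))
  cand <- c("c_interface", "epa", "c_water")
  v <- vif(tab, cand)$vif
  fit <- lm(reformulate(cand, "relative_stability"), tab)
  expect_equal(unname(v), unname(car::vif(fit)[cand]), tolerance = 1e-8)
})

test_that("listwise deletion drops incomplete rows before selection", {
  tab <- gen_compound_table(scenario_spec(seed = 9))
  tab$c_interface[c(2, 5)] <- NA
  m <- stepwise_regression(tab, "relative_stability",
                           c("c_interface", "epa", "c_water"))
  expect_equal(m$n, nrow(tab) - 2L)
})
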