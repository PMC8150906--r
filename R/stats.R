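# Predictor analysis: which compound properties explain antioxidant
# efficiency? Pearson correlation screening plus stepwise linear
# regression with probability-of-F enter/remove rules (the SPSS-style
# procedure), standardized coefficients and variance inflation factors.

# RSS of an OLS fit of y on an intercept plus the named columns.
.ols_rss <- function(df, response, predictors) {
  y <- df[[response]]
  x <- cbind(`(Intercept)` = 1,
             as.matrix(df[, predictors, drop = FALSE]))
  qx <- qr(x)
  if (qx$rank < ncol(x)) return(list(rss = NA_real_, rank_deficient = TRUE))
  res <- qr.resid(qx, y)
  list(rss = sum(res^2), rank_deficient = FALSE)
}

# R-squared of y on predictors (empty predictor set -> 0).
.ols_r2 <- function(df, response, predictors) {
  y <- df[[response]]
  tss <- sum((y - mean(y))^2)
  if (length(predictors) == 0L) return(0)
  1 - .ols_rss(df, response, predictors)$rss / tss
}

# Partial-F p-value for moving between nested predictor sets differing by
# one term. n rows; k = size of the larger set.
.partial_f_p <- function(rss_reduced, rss_full, n, k) {
  df2 <- n - k - 1L
  if (df2 <= 0L) return(list(f = NA_real_, p = NA_real_))
  if (rss_full <= 0) return(list(f = Inf, p = 0))
  f <- (rss_reduced - rss_full) / (rss_full / df2)
  list(f = f, p = stats::pf(f, 1L, df2, lower.tail = FALSE))
}

#' Pearson correlation of a response with candidate predictors
#'
#' Pairwise product-moment correlations with two-tailed p-values from the
#' t transform `t = r * sqrt((n - 2)/(1 - r^2))` on n - 2 degrees of
#' freedom, with significance stars at the 0.05 (`*`) and 0.01 (`**`)
#' levels. Missing values are dropped pairwise; a correlation needs at
#' least 3 complete pairs. A zero-variance column yields `NA` with the
#' reason recorded.
#'
#' @param records Data frame of compound records.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return Data frame with columns `predictor`, `n`, `r`, `p`, `stars`,
#'   `note`.
#' @export
pearson_matrix <- function(records, response, predictors) {
  stopifnot(is.data.frame(records), response %in% names(records),
            all(predictors %in% names(records)))
  rows <- lapply(predictors, function(px) {
    ok <- stats::complete.cases(records[, c(response, px)])
    n <- sum(ok)
    if (n < 3L)
      return(data.frame(predictor = px, n = n, r = NA_real_, p = NA_real_,
                        stars = "", note = "fewer than 3 complete pairs"))
    x <- records[[px]][ok]
    y <- records[[response]][ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(predictor = px, n = n, r = NA_real_, p = NA_real_,
                        stars = "", note = "zero variance"))
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    }
    stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    data.frame(predictor = px, n = n, r = r, p = p, stars = stars, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise linear regression with probability-of-F enter/remove rules
#'
#' Forward selection with backward elimination, the variable-selection
#' procedure of classical statistical packages: at each step the candidate
#' with the smallest partial-F p-value enters if that p-value is below
#' `p_enter`; after every entry, any included predictor whose partial-F
#' p-value for removal exceeds `p_remove` is dropped (largest p first).
#' The procedure stops when no entry or removal changes the model. The
#' partial F for adding x to a k-predictor model on n rows is
#' \deqn{F = \frac{RSS_{reduced} - RSS_{full}}{RSS_{full}/(n - k - 1)}}
#' on (1, n - k - 1) degrees of freedom.
#'
#' Rows with a missing value in the response or any candidate are dropped
#' (listwise deletion). Entry ties are broken by the larger partial F, then
#' by predictor name. A candidate whose entry would make the design
#' rank-deficient is skipped with a logged reason.
#'
#' @param records Data frame.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor names.
#' @param p_enter Probability-of-F-to-enter threshold (default 0.150).
#' @param p_remove Probability-of-F-to-remove threshold (default 0.200).
#' @return An object of class `stepwise_model`: `predictors` (selected, in
#'   entry order), `steps` (one row per model change: action, predictor,
#'   `cum_r2`, `adj_r2`, `partial_r2`), `coefficients` (final OLS table
#'   with p-values), `standardized_betas`, `vif`, `n`, `response`, `log`.
#' @seealso [standardized_betas()], [vif()]
#' @export
stepwise_regression <- function(records, response, candidates,
                                p_enter = 0.150, p_remove = 0.200) {
  stopifnot(is.data.frame(records), response %in% names(records),
            all(candidates %in% names(records)))
  df <- records[stats::complete.cases(records[, c(response, candidates),
                                             drop = FALSE]),
                c(response, candidates), drop = FALSE]
  n <- nrow(df)
  if (n < length(candidates) + 2L)
    warning(sprintf(
      "only %d complete rows for %d candidates; selection may be unstable",
      n, length(candidates)), call. = FALSE)
  if (n < 3L)
    stop("need at least 3 complete rows", call. = FALSE)
  tss <- sum((df[[response]] - mean(df[[response]]))^2)
  if (tss == 0) stop("response has zero variance", call. = FALSE)

  selected <- character(0)
  log <- character(0)
  steps <- list()
  prev_r2 <- 0
  step_no <- 0L

  record_step <- function(action, predictor) {
    r2 <- .ols_r2(df, response, selected)
    k <- length(selected)
    adj <- if (n - k - 1L > 0L) 1 - (1 - r2) * (n - 1L) / (n - k - 1L)
    else NA_real_
    step_no <<- step_no + 1L
    steps[[step_no]] <<- data.frame(
      step = step_no, action = action, predictor = predictor,
      cum_r2 = r2, adj_r2 = adj, partial_r2 = r2 - prev_r2)
    prev_r2 <<- r2
  }

  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      rss_cur <- if (length(selected) == 0L) tss else
        .ols_rss(df, response, selected)$rss
      stats_in <- lapply(pool, function(cand) {
        full <- .ols_rss(df, response, c(selected, cand))
        if (full$rank_deficient)
          return(list(p = NA_real_, f = NA_real_, reason = "collinear"))
        c(.partial_f_p(rss_cur, full$rss, n, length(selected) + 1L),
          reason = "")
      })
      names(stats_in) <- pool
      bad <- vapply(stats_in, function(s) identical(s$reason, "collinear"),
                    logical(1))
      for (b in pool[bad])
        log <- c(log, sprintf("skipped '%s': collinear with current model", b))
      ps <- vapply(stats_in, function(s) s$p, numeric(1))
      fs <- vapply(stats_in, function(s) s$f, numeric(1))
      ok <- !is.na(ps) & ps < p_enter
      if (any(ok)) {
        cand <- pool[ok]
        ord <- order(ps[ok], -fs[ok], cand)
        best <- cand[ord[1L]]
        selected <- c(selected, best)
        log <- c(log, sprintf("entered '%s' (p = %.4g)", best,
                              ps[[best]]))
        record_step("enter", best)
        changed <- TRUE
      }
    }
    # backward sweep after each entry (and as the terminal check)
    repeat {
      if (length(selected) < 1L) break
      rss_full <- .ols_rss(df, response, selected)$rss
      p_out <- vapply(selected, function(v) {
        red <- .ols_rss(df, response, setdiff(selected, v))
        .partial_f_p(red$rss, rss_full, n, length(selected))$p
      }, numeric(1))
      worst <- which.max(p_out)
      if (length(worst) == 0L || is.na(p_out[worst]) ||
          p_out[worst] <= p_remove) break
      gone <- selected[worst]
      selected <- setdiff(selected, gone)
      log <- c(log, sprintf("removed '%s' (p = %.4g)", gone, p_out[worst]))
      record_step("remove", gone)
      changed <- TRUE
    }
    if (!changed) break
  }

  steps <- if (length(steps) > 0L) do.call(rbind, steps) else
    data.frame(step = integer(0), action = character(0),
               predictor = character(0), cum_r2 = numeric(0),
               adj_r2 = numeric(0), partial_r2 = numeric(0))

  if (length(selected) > 0L) {
    fml <- stats::reformulate(selected, response)
    fit <- stats::lm(fml, data = df)
    coefs <- as.data.frame(summary(fit)$coefficients)
    names(coefs) <- c("estimate", "std_error", "t", "p")
    betas <- standardized_betas(df, response, selected)
    vifs <- if (length(selected) >= 2L) vif(df, selected) else NULL
  } else {
    fit <- stats::lm(stats::reformulate("1", response), data = df)
    coefs <- as.data.frame(summary(fit)$coefficients)
    names(coefs) <- c("estimate", "std_error", "t", "p")
    betas <- numeric(0)
    vifs <- NULL
  }
  structure(list(
    predictors = selected, steps = steps, coefficients = coefs,
    standardized_betas = betas, vif = vifs, n = n,
    response = response, candidates = candidates,
    p_enter = p_enter, p_remove = p_remove,
    fit = fit, log = log),
    class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf(
    "Stepwise linear regression: %s ~ {%s}\n  n = %d, p_enter = %g, p_remove = %g\n",
    x$response, paste(x$candidates, collapse = ", "), x$n, x$p_enter,
    x$p_remove))
  if (length(x$predictors) == 0L) {
    cat("  no predictor passed the entry criterion (intercept-only model)\n")
    return(invisible(x))
  }
  cat("  selected (in order):", paste(x$predictors, collapse = ", "), "\n\n")
  print(x$steps, row.names = FALSE)
  cat("\nFinal model coefficients:\n")
  print(round(x$coefficients, 4))
  cat("\nStandardized betas:\n")
  print(round(x$standardized_betas, 3))
  if (!is.null(x$vif)) {
    cat("\nVariance inflation factors:\n")
    print(round(x$vif$vif, 3))
  }
  invisible(x)
}

#' Standardized regression coefficients
#'
#' Coefficients of the same OLS regression after z-scoring the response and
#' every predictor (sample SD, n - 1 denominator). Dimensionless; their
#' relative magnitudes rank the predictors' influence, and their signs
#' match the raw coefficients.
#'
#' @param records Data frame (complete cases are used).
#' @param response Response column name.
#' @param predictors Predictor column names.
#' @return Named numeric vector of standardized betas.
#' @export
standardized_betas <- function(records, response, predictors) {
  df <- records[stats::complete.cases(records[, c(response, predictors),
                                             drop = FALSE]),
                c(response, predictors), drop = FALSE]
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance column: ",
         paste(names(sds)[sds == 0], collapse = ", "), call. = FALSE)
  z <- as.data.frame(scale(df))
  fit <- stats::lm(stats::reformulate(predictors, response), data = z)
  stats::coef(fit)[predictors]
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the R-squared of regressing
#' predictor j on the remaining predictors. Values near 1 mean negligible
#' multicollinearity; a perfectly collinear predictor gets an infinite VIF
#' and a flag.
#'
#' @param records Data frame (complete cases are used).
#' @param predictors Two or more predictor column names.
#' @return List with `vif` (named numeric, `Inf` where collinear) and
#'   `collinear` (character vector of flagged predictors).
#' @export
vif <- function(records, predictors) {
  if (length(predictors) < 2L)
    stop("need at least 2 predictors for VIF", call. = FALSE)
  df <- records[stats::complete.cases(records[, predictors, drop = FALSE]),
                predictors, drop = FALSE]
  out <- vapply(predictors, function(px) {
    r2 <- .ols_r2(df, px, setdiff(predictors, px))
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  list(vif = out, collinear = names(out)[is.infinite(out)])
}
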