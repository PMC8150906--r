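# Independent oracles used across the suite. These deliberately take a
# different computational route from the package code they check.

# Brute-force three-region distribution: solve the two concentration-ratio
# constraints plus mass conservation numerically for the region amounts.
# Unknowns: moles n_o, n_w, n_i per unit emulsion volume (total_ao total).
#   c_o = n_o/phi_o etc.;  p_oi = c_i/c_o;  p_wi = c_i/c_w.
brute_force_three_region <- function(p_oi, p_wi, phi_o, phi_w, phi_i,
                                     total_ao) {
  resid <- function(ni) {
    ci <- ni / phi_i
    co <- ci / p_oi
    cw <- ci / p_wi
    co * phi_o + cw * phi_w + ni - total_ao
  }
  ni <- uniroot(resid, c(0, total_ao), tol = 1e-15)$root
  ci <- ni / phi_i
  co <- ci / p_oi
  cw <- ci / p_wi
  list(f = c(oil = co * phi_o, water = cw * phi_w, interface = ni) / total_ao,
       c = c(oil = co, water = cw, interface = ci))
}

# Dense-grid root find for the 0.5 crossing of a piecewise-linear
# dose-response (oracle for ec50()).
dense_grid_ec50 <- function(ratio, frac, n_grid = 2e5) {
  g <- seq(min(ratio), max(ratio), length.out = n_grid)
  f <- approx(ratio, frac, xout = g)$y
  i <- which(f <= 0.5)[1]
  if (is.na(i)) return(NA_real_)
  g[i]
}

# Exhaustive stepwise oracle: precompute the RSS of every predictor subset
# with lm(), then replay the probability-of-F enter/remove rules from
# those subset fits. Independent of the package's qr-based implementation.
oracle_stepwise <- function(df, response, candidates,
                            p_enter = 0.150, p_remove = 0.200) {
  df <- df[complete.cases(df[, c(response, candidates)]),
           c(response, candidates)]
  n <- nrow(df)
  subsets <- unlist(lapply(0:length(candidates), function(k)
    combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  key <- function(s) paste0("s:", paste(sort(s), collapse = "+"))
  rss <- new.env()
  for (s in subsets) {
    fml <- if (length(s) == 0) reformulate("1", response) else
      reformulate(s, response)
    assign(key(s), sum(residuals(lm(fml, df))^2), envir = rss)
  }
  pval <- function(small, big) {
    # p-value for the single term distinguishing nested subsets
    rss_s <- get(key(small), rss)
    rss_b <- get(key(big), rss)
    df2 <- n - length(big) - 1
    f <- (rss_s - rss_b) / (rss_b / df2)
    pf(f, 1, df2, lower.tail = FALSE)
  }
  sel <- character(0)
  order_in <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, sel)
    if (length(pool) > 0) {
      ps <- sapply(pool, function(cand) pval(sel, c(sel, cand)))
      fs <- -ps  # larger F <-> smaller p for 1-df tests at fixed df2
      if (any(ps < p_enter, na.rm = TRUE)) {
        okp <- which(!is.na(ps) & ps < p_enter)
        best <- pool[okp][order(ps[okp], fs[okp], pool[okp])][1]
        sel <- c(sel, best)
        order_in <- c(order_in, best)
        changed <- TRUE
      }
    }
    repeat {
      if (length(sel) == 0) break
      ps <- sapply(sel, function(v) pval(setdiff(sel, v), sel))
      w <- which.max(ps)
      if (length(w) == 0 || is.na(ps[w]) || ps[w] <= p_remove) break
      sel <- setdiff(sel, sel[w])
      changed <- TRUE
    }
    if (!changed) break
  }
  r2 <- function(s) {
    tss <- sum((df[[response]] - mean(df[[response]]))^2)
    1 - get(key(s), rss) / tss
  }
  list(selected = sel, entry_order = order_in, final_r2 = r2(sel))
}
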