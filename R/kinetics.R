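# Reduction of raw absorbance-time traces to pseudo-first-order rate
# constants. Unreacted probe is derivatized to a stable azo dye and read at
# 572 nm, so probe consumption appears as an exponential absorbance decay.

#' Absorbance-time kinetic trace
#'
#' @param time_s Times in seconds, strictly increasing, length >= 5.
#' @param absorbance Nonnegative absorbance readings (572 nm), same length.
#' @param compound,phi_interface,replicate Optional metadata.
#' @return An object of class `absorbance_trace` (also a data frame).
#' @export
absorbance_trace <- function(time_s, absorbance, compound = NA_character_,
                             phi_interface = NA_real_, replicate = 1L) {
  if (length(time_s) != length(absorbance))
    stop("'time_s' and 'absorbance' must have the same length", call. = FALSE)
  if (length(time_s) < 5L)
    stop("need at least 5 points in a trace", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(absorbance < 0))
    stop("absorbance must be nonnegative", call. = FALSE)
  structure(
    data.frame(time_s = time_s, absorbance = absorbance),
    compound = compound, phi_interface = phi_interface,
    replicate = replicate,
    class = c("absorbance_trace", "data.frame"))
}

#' Fit the integrated first-order rate law to a trace
#'
#' Least-squares fit of `A(t) = A_inf + (A_0 - A_inf) * exp(-k_obs * t)`.
#' Decay versus growth is auto-detected from the sign of the overall trend;
#' the derivatization assay gives decays but the fit is sign-agnostic. The
#' asymptote `A_inf` is fitted by default (`fix_a_inf` pins it instead).
#' Starting values: `A_inf` from the trailing extreme of the trace and
#' `k_obs` from a log-linear regression of the offset-corrected signal.
#'
#' A flat trace — range below 3x the noise level estimated from the median
#' absolute deviation of first differences — is rejected as "no reaction
#' detected". If the observation window covers less than 2 half-lives of
#' the fitted constant a coverage warning is raised, since rate constants
#' from short windows are poorly constrained.
#'
#' @param trace An [absorbance_trace()].
#' @param fix_a_inf Optional fixed asymptote; `NULL` (default) fits it.
#' @return An object of class `first_order_fit` with `k_obs` (s^-1), `a0`,
#'   `a_inf`, `r_squared`, `half_life` (= log(2)/k_obs, s), and the trace
#'   metadata.
#' @examples
#' tt <- seq(0, 2000, length.out = 20)
#' tr <- absorbance_trace(tt, 0.2 + 0.8 * exp(-0.003 * tt))
#' fit_first_order(tr)$k_obs  # 0.003
#' @export
fit_first_order <- function(trace, fix_a_inf = NULL) {
  stopifnot(inherits(trace, "absorbance_trace"))
  tt <- trace$time_s
  aa <- trace$absorbance
  noise <- stats::mad(diff(aa)) / sqrt(2)
  if (diff(range(aa)) < 3 * max(noise, .Machine$double.eps))
    stop("no reaction detected: trace is flat relative to its noise level",
         call. = FALSE)
  decay <- aa[length(aa)] < aa[1L]
  a_inf0 <- if (!is.null(fix_a_inf)) fix_a_inf else
    if (decay) min(aa) else max(aa)
  # log-linear start for k; shift slightly inside the asymptote so the log
  # is defined at every point
  amp0 <- aa[1L] - a_inf0
  shift <- a_inf0 - sign(amp0) * 0.05 * abs(amp0) -
    (if (amp0 == 0) 1e-6 else 0)
  z <- (aa - shift) / (aa[1L] - shift)
  ok <- z > 0
  k0 <- -stats::coef(stats::lm(log(z[ok]) ~ tt[ok]))[[2]]
  if (!is.finite(k0) || k0 <= 0) k0 <- log(2) / (max(tt) / 2)

  df <- data.frame(tt = tt, aa = aa)
  if (is.null(fix_a_inf)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      aa ~ a_inf + (a0 - a_inf) * exp(-k * tt), data = df,
      start = list(a_inf = a_inf0, a0 = aa[1L], k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("first-order fit did not converge: ", conditionMessage(e),
             call. = FALSE))
    est <- stats::coef(fit)
    a_inf <- est[["a_inf"]]
  } else {
    a_inf <- fix_a_inf
    fit <- tryCatch(minpack.lm::nlsLM(
      aa ~ a_inf + (a0 - a_inf) * exp(-k * tt), data = df,
      start = list(a0 = aa[1L], k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("first-order fit did not converge: ", conditionMessage(e),
             call. = FALSE))
    est <- stats::coef(fit)
  }
  k <- est[["k"]]
  if (!is.finite(k) || k <= 0)
    stop("fitted rate constant is not positive", call. = FALSE)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((aa - mean(aa))^2)
  r2 <- max(0, min(1, 1 - rss / tss))
  half_life <- log(2) / k
  if (max(tt) - min(tt) < 2 * half_life)
    warning(sprintf(
      "trace spans %.2g half-lives (< 2); k_obs poorly constrained",
      (max(tt) - min(tt)) / half_life), call. = FALSE)
  structure(list(
    k_obs = k, a0 = est[["a0"]], a_inf = a_inf,
    r_squared = r2, half_life = half_life,
    compound = attr(trace, "compound"),
    phi_interface = attr(trace, "phi_interface"),
    replicate = attr(trace, "replicate")),
    class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf(
    "First-order fit: k_obs = %.4g s^-1 (t1/2 = %.3g s), A0 = %.3g, Ainf = %.3g, r2 = %.4f\n",
    x$k_obs, x$half_life, x$a0, x$a_inf, x$r_squared))
  invisible(x)
}

#' Aggregate replicate rate constants into a rate series
#'
#' Groups first-order fits by (compound, phi_interface), computes per-group
#' mean, SD and coefficient of variation, and flags groups that fall outside
#' the usual quality bounds of the derivatization assay: replicate CV above
#' 9 percent or any fit with r-squared below 0.995. Returns both the
#' pointwise [rate_series()] (all replicates, ready for [fit_partition()])
#' and the per-group summary.
#'
#' @param fits A list of `first_order_fit` objects for one compound.
#' @param total_ao Stoichiometric antioxidant concentration, M.
#' @param region_pair Passed to [rate_series()].
#' @param cv_limit,r2_limit Quality bounds (defaults 0.09 and 0.995).
#' @return List with `series` (a [rate_series()], or `NULL` when fewer
#'   than two distinct phi levels are present) and `summary` (data frame
#'   with columns `phi_interface`, `n`, `mean_kobs`, `sd_kobs`, `cv`,
#'   `flag`).
#' @export
aggregate_kobs <- function(fits, total_ao,
                           region_pair = c("water_interface",
                                           "oil_interface"),
                           cv_limit = 0.09, r2_limit = 0.995) {
  region_pair <- match.arg(region_pair)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "first_order_fit")))
  compound <- unique(vapply(fits, function(f) f$compound, character(1)))
  if (length(compound) > 1L)
    stop("mixed compounds in one series: ",
         paste(compound, collapse = ", "), call. = FALSE)
  df <- data.frame(
    phi_interface = vapply(fits, function(f) f$phi_interface, numeric(1)),
    k_obs = vapply(fits, function(f) f$k_obs, numeric(1)),
    replicate = vapply(fits, function(f) as.integer(f$replicate), integer(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)))
  groups <- split(df, df$phi_interface)
  summ <- do.call(rbind, lapply(groups, function(g) {
    m <- mean(g$k_obs)
    s <- if (nrow(g) > 1L) stats::sd(g$k_obs) else NA_real_
    cv <- s / m
    flag <- if (nrow(g) == 1L) "no replication"
    else if (!is.na(cv) && cv > cv_limit) sprintf("CV %.1f%% > %.0f%%",
                                                  100 * cv, 100 * cv_limit)
    else if (any(g$r_squared < r2_limit)) sprintf("r2 < %.3f", r2_limit)
    else ""
    data.frame(phi_interface = g$phi_interface[1L], n = nrow(g),
               mean_kobs = m, sd_kobs = s, cv = cv, flag = flag)
  }))
  rownames(summ) <- NULL
  # a fittable series needs >= 2 distinct phi levels; below that only the
  # summary is returned
  series <- if (length(unique(df$phi_interface)) >= 2L)
    rate_series(df$phi_interface, df$k_obs, df$replicate,
                total_ao = total_ao, region_pair = region_pair,
                compound = compound)
  else NULL
  list(series = series, summary = summ)
}
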