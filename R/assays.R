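# Assay-level reductions: FRAP value, DPPH EC50, and relative oxidative
# stability from conjugated-diene oxidation curves.

#' FRAP value from absorbance changes
#'
#' Ferric-reducing antioxidant power, expressed as the Fe(II)-equivalent
#' concentration giving the same 593 nm absorbance change:
#' `FRAP = (dA_sample / dA_standard) * conc_standard`.
#'
#' @param delta_a_sample Absorbance change of the test sample (>= 0).
#' @param delta_a_standard Absorbance change of the Fe(II) standard (> 0).
#' @param conc_standard Concentration of the standard, micromolar.
#' @return FRAP value in micromolar Fe(II) equivalents.
#' @examples
#' frap_value(0.35, 0.20, 1000)  # 1750
#' @export
frap_value <- function(delta_a_sample, delta_a_standard, conc_standard) {
  if (!is.numeric(delta_a_standard) || any(delta_a_standard <= 0))
    stop("'delta_a_standard' must be positive", call. = FALSE)
  if (!is.numeric(conc_standard) || any(conc_standard <= 0))
    stop("'conc_standard' must be positive", call. = FALSE)
  delta_a_sample / delta_a_standard * conc_standard
}

#' DPPH dose-response series
#'
#' @param mole_ratio Antioxidant/DPPH mole ratios (>= 0).
#' @param fraction_remaining Remaining DPPH fraction in [0, 1], same length.
#' @param time_label Reading time label, minutes (the assay is usually read
#'   at both 5 and 60 min).
#' @return An object of class `dose_response` (also a data frame).
#' @export
dose_response <- function(mole_ratio, fraction_remaining, time_label = 60) {
  if (length(mole_ratio) != length(fraction_remaining))
    stop("inputs must have the same length", call. = FALSE)
  if (any(mole_ratio < 0))
    stop("mole ratios must be >= 0", call. = FALSE)
  if (any(fraction_remaining < 0 | fraction_remaining > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  ord <- order(mole_ratio)
  structure(
    data.frame(mole_ratio = mole_ratio[ord],
               fraction_remaining = fraction_remaining[ord]),
    time_label = time_label,
    class = c("dose_response", "data.frame"))
}

#' EC50 of a DPPH dose-response
#'
#' The mole ratio of antioxidant to DPPH radical required to halve the
#' initial radical concentration, obtained by linear interpolation between
#' the two observations bracketing the 0.5 crossing. Weak scavengers (for
#' example monophenols) whose response never reaches 0.5 get a
#' "not reached" sentinel carrying the maximum ratio tested rather than an
#' extrapolated number.
#'
#' @param dr A [dose_response()].
#' @return List with `ec50` (mole ratio, `NA` if not reached), `reached`
#'   (logical), and `max_ratio_tested`.
#' @examples
#' ec50(dose_response(c(0.2, 0.3), c(0.6, 0.4)))$ec50  # 0.25
#' @export
ec50 <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  r <- dr$mole_ratio
  f <- dr$fraction_remaining
  hit <- which(f == 0.5)
  if (length(hit) > 0L)
    return(list(ec50 = r[hit[1L]], reached = TRUE, max_ratio_tested = max(r)))
  below <- which(f < 0.5)
  if (length(below) == 0L)
    return(list(ec50 = NA_real_, reached = FALSE, max_ratio_tested = max(r)))
  j <- below[1L]
  if (j == 1L)
    return(list(ec50 = r[1L], reached = TRUE, max_ratio_tested = max(r)))
  i <- j - 1L
  ec <- r[i] + (0.5 - f[i]) * (r[j] - r[i]) / (f[j] - f[i])
  list(ec50 = ec, reached = TRUE, max_ratio_tested = max(r))
}

#' Lipid-oxidation curve
#'
#' Conjugated-diene content versus storage time for one emulsion sample in
#' an accelerated (60 degree C oven) oxidation test.
#'
#' @param time_h Times in hours, nondecreasing, length >= 3.
#' @param cd_percent Conjugated-diene content, percent, >= 0.
#' @param sample Optional sample label.
#' @param is_control Logical, antioxidant-free control?
#' @return An object of class `oxidation_curve` (also a data frame).
#' @export
oxidation_curve <- function(time_h, cd_percent, sample = NA_character_,
                            is_control = FALSE) {
  if (length(time_h) != length(cd_percent))
    stop("inputs must have the same length", call. = FALSE)
  if (length(time_h) < 3L)
    stop("need at least 3 points in an oxidation curve", call. = FALSE)
  if (any(diff(time_h) < 0))
    stop("times must be nondecreasing", call. = FALSE)
  if (any(cd_percent < 0))
    stop("conjugated-diene content must be >= 0", call. = FALSE)
  structure(
    data.frame(time_h = time_h, cd_percent = cd_percent),
    sample = sample, is_control = is_control,
    class = c("oxidation_curve", "data.frame"))
}

#' Induction time of an oxidation curve
#'
#' Time for the conjugated-diene content to rise by a fixed number of
#' percentage points above the sample's own initial value (default +0.5
#' percentage points, the usual stability threshold). The first upward
#' crossing is located by linear interpolation between the bracketing
#' observations. The threshold is absolute (percentage points), not
#' relative to baseline.
#'
#' @param curve An [oxidation_curve()].
#' @param threshold_increase Threshold rise in CD percentage points
#'   (default 0.5).
#' @param baseline Baseline CD content the rise is measured from; defaults
#'   to the curve's own first observation. A curve already at or above
#'   `baseline + threshold_increase` at its first point gets induction
#'   time 0.
#' @return Induction time in hours.
#' @examples
#' tt <- seq(0, 100, by = 10)
#' induction_time(oxidation_curve(tt, 0.075 + 0.01 * tt))  # 50
#' @export
induction_time <- function(curve, threshold_increase = 0.5,
                           baseline = NULL) {
  stopifnot(inherits(curve, "oxidation_curve"))
  if (threshold_increase <= 0)
    stop("'threshold_increase' must be positive", call. = FALSE)
  tt <- curve$time_h
  cd <- curve$cd_percent
  if (is.null(baseline)) baseline <- cd[1L]
  target <- baseline + threshold_increase
  if (cd[1L] >= target) return(0)
  above <- which(cd >= target)
  if (length(above) == 0L)
    stop("stability horizon not reached within observation window ",
         sprintf("(CD stays below %.3g%% up to %g h)", target, max(tt)),
         call. = FALSE)
  j <- above[1L]
  if (cd[j] == target) return(tt[j])
  i <- j - 1L
  tt[i] + (target - cd[i]) * (tt[j] - tt[i]) / (cd[j] - cd[i])
}

#' Relative increase in oxidative stability
#'
#' Figure of merit for an antioxidant in an emulsion under accelerated
#' oxidation: `(t_AO - t_C) / t_C`, where `t_AO` and `t_C` are the
#' induction times of the antioxidant-bearing sample and the control. A
#' value of 0 means no protection; 16 means a 17-fold longer induction
#' period.
#'
#' @param sample,control [oxidation_curve()] objects.
#' @param threshold_increase Passed to [induction_time()].
#' @return An object of class `stability_result` with `t_ao`, `t_control`,
#'   and `relative_increase`.
#' @export
relative_stability <- function(sample, control, threshold_increase = 0.5) {
  t_ao <- induction_time(sample, threshold_increase)
  t_c <- induction_time(control, threshold_increase)
  if (t_c <= 0)
    stop("control induction time is not positive; relative stability ",
         "undefined", call. = FALSE)
  structure(list(t_ao = t_ao, t_control = t_c,
                 relative_increase = (t_ao - t_c) / t_c),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "Oxidative stability: t_AO = %.3g h, t_C = %.3g h, relative increase = %.3g\n",
    x$t_ao, x$t_control, x$relative_increase))
  invisible(x)
}
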