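# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth. Emulates the measurement structure of the kinetic
# derivatization assay, the accelerated oxidation test, and the compound
# property table, so the whole chain is testable end to end.

#' Scenario specification for the synthetic generators
#'
#' Defines one fully reproducible simulated study: the emulsion, the
#' compound panel with true kinetic/partitioning/redox properties, the
#' noise levels, and the planted linear structure that links predictors to
#' oxidative stability.
#'
#' Defaults mirror the usual experimental design for this assay family: a
#' 4:6 oil/water emulsion, a stoichiometric antioxidant concentration of
#' 0.24 mM, emulsifier volume fractions 0.005--0.04, triplicate kinetic
#' runs with ~8 percent replicate scatter (the assay's stated 7--9 percent
#' band), additive photometric noise of 0.005 absorbance units, and a
#' conjugated-diene baseline of 0.075 percent.
#'
#' @param seed Integer seed; identical specs give identical outputs.
#' @param phi_oil,phi_water Bulk volume fractions.
#' @param phi_levels Emulsifier volume fractions for the kinetic series.
#' @param total_ao Stoichiometric antioxidant concentration, M.
#' @param compounds Data frame with one row per compound: `compound`,
#'   `region_pair` ("water_interface"/"oil_interface"), `p` (true partition
#'   constant), `k_i` (true interfacial rate constant, M^-1 s^-1), `epa`
#'   (anodic peak potential, V), `t_induction` (h, induction time at the
#'   first phi level), optionally `ec50`, `frap`. A default five-compound
#'   panel spanning hydrophilic to hydrophobic behaviour is supplied.
#' @param n_replicates Kinetic replicates per (compound, phi).
#' @param trace_sigma Additive absorbance noise SD.
#' @param kobs_cv Target observed replicate-level CV of k_obs (lognormal
#'   perturbation, scale corrected for the small-sample bias of the
#'   replicate SD).
#' @param cd_sigma Additive noise SD on conjugated-diene curves, percent.
#' @param cd_baseline Initial conjugated-diene content, percent.
#' @param t_control Control induction time, h.
#' @param beta Planted stability model coefficients, named
#'   `c(c_interface =, epa =, c_water =)`, response units per predictor
#'   unit (concentrations in mM, potential in V).
#' @param beta0 Planted intercept.
#' @param stability_sigma Residual SD of the planted stability model.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(
    seed = 1L,
    phi_oil = 0.4, phi_water = 0.6,
    phi_levels = c(0.005, 0.01, 0.02, 0.04),
    total_ao = 0.24e-3,
    compounds = default_compound_panel(),
    n_replicates = 3L,
    trace_sigma = 0.005,
    kobs_cv = 0.08,
    cd_sigma = 0.01,
    cd_baseline = 0.075,
    t_control = 10,
    beta = c(c_interface = 0.45, epa = -12, c_water = -25),
    beta0 = 6,
    stability_sigma = 0.5) {
  stopifnot(is.data.frame(compounds),
            all(c("compound", "region_pair", "p", "k_i", "epa",
                  "t_induction") %in% names(compounds)))
  if (any(c(trace_sigma, kobs_cv, cd_sigma, stability_sigma) < 0))
    stop("noise levels must be >= 0", call. = FALSE)
  if (any(compounds$t_induction <= 0))
    stop("planted induction times must be positive", call. = FALSE)
  if (any(phi_levels <= 0))
    stop("phi levels must be positive", call. = FALSE)
  structure(list(
    seed = as.integer(seed), phi_oil = phi_oil, phi_water = phi_water,
    phi_levels = phi_levels, total_ao = total_ao, compounds = compounds,
    n_replicates = as.integer(n_replicates), trace_sigma = trace_sigma,
    kobs_cv = kobs_cv, cd_sigma = cd_sigma, cd_baseline = cd_baseline,
    t_control = t_control, beta = beta, beta0 = beta0,
    stability_sigma = stability_sigma),
    class = "scenario_spec")
}

#' Default synthetic compound panel
#'
#' Five antioxidants spanning the behaviours seen in phenolipid panels: a
#' hydrophilic parent phenol partitioning between water and interface with
#' a modest constant, and esterified derivatives partitioning between oil
#' and interface with constants from tens to hundreds, paired with anodic
#' potentials in the catechol range (0.33--0.8 V).
#'
#' @return Data frame usable as the `compounds` slot of [scenario_spec()].
#' @export
default_compound_panel <- function() {
  data.frame(
    compound = c("parent", "ester8", "ester16", "weak8", "weak16"),
    region_pair = c("water_interface", rep("oil_interface", 4L)),
    p = c(55, 380, 215, 40, 36),
    k_i = c(0.5, 0.8, 0.6, 0.05, 0.04),
    epa = c(0.35, 0.34, 0.35, 0.76, 0.79),
    t_induction = c(40, 170, 120, 25, 20),
    ec50 = c(0.2, 0.27, 0.27, 21, 22),
    frap = c(2900, 1600, 1500, 60, 55))
}

# Per-compound two-region partition_set from a panel row.
.panel_partition <- function(row) {
  if (row$region_pair == "water_interface") partition_set(p_wi = row$p)
  else partition_set(p_oi = row$p)
}

#' Generate absorbance-time traces
#'
#' For each (compound, phi level, replicate): the true k_obs comes from
#' [kobs_model()] with the compound's true (k_i, P); the replicate draws a
#' lognormal perturbation with the spec's CV; the trace is the first-order
#' decay `A(t) = 0.05 + 0.75 * exp(-k_obs t)` sampled at 25 points over 3
#' half-lives with additive Gaussian noise.
#'
#' @param spec A [scenario_spec()].
#' @return List of [absorbance_trace()] objects.
#' @export
gen_traces <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  out <- list()
  # kobs_cv is the target OBSERVED replicate CV. The sample SD of a small
  # replicate group underestimates the population SD (Gaussian c4 bias,
  # c4(3) = 0.886), so the draw scale is inflated accordingly.
  n <- spec$n_replicates
  c4 <- if (n >= 2L) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  else 1
  sdlog <- sqrt(log(1 + (spec$kobs_cv / c4)^2))
  for (ci in seq_len(nrow(spec$compounds))) {
    row <- spec$compounds[ci, ]
    part <- .panel_partition(row)
    for (phi in spec$phi_levels) {
      comp <- emulsion_composition(spec$phi_oil, spec$phi_water, phi)
      k_true <- kobs_model(row$k_i, part, comp, spec$total_ao)
      for (rep_i in seq_len(spec$n_replicates)) {
        k_rep <- k_true * stats::rlnorm(1, meanlog = -sdlog^2 / 2,
                                        sdlog = sdlog)
        tt <- seq(0, 3 * log(2) / k_rep, length.out = 25L)
        a <- 0.05 + 0.75 * exp(-k_rep * tt) +
          stats::rnorm(length(tt), 0, spec$trace_sigma)
        a <- pmax(a, 0)
        out[[length(out) + 1L]] <- absorbance_trace(
          tt, a, compound = row$compound, phi_interface = phi,
          replicate = rep_i)
      }
    }
  }
  out
}

#' Generate conjugated-diene oxidation curves
#'
#' Control and per-compound curves with the lag-then-rise shape of an
#' accelerated oxidation test: a flat baseline plus a logistic rise
#' positioned so the +0.5 percentage-point crossing lands on the planted
#' induction time, with additive Gaussian noise.
#'
#' Two planting modes. With `stability_from = "linear_model"` (default)
#' the induction times encode the scenario's planted stability model:
#' `t_ind = t_control * (1 + mu)` where `mu` is the planted linear
#' predictor (`beta0 + beta %*% (c_interface, epa, c_water)`) evaluated on
#' the true distributions at the requested phi level, floored at a small
#' positive protection factor — so every downstream stage, through the
#' stepwise regression, sees one coherent truth. With
#' `stability_from = "t_induction"` the compounds' `t_induction` column is
#' used verbatim (at any phi level), which is convenient for planting
#' specific fold-changes.
#'
#' @param spec A [scenario_spec()].
#' @param phi Which phi level's curves to generate (defaults to the first).
#' @param stability_from `"linear_model"` or `"t_induction"` (see above).
#' @return List with `control` (an [oxidation_curve()]), `samples` (named
#'   list of curves, one per compound), and `planted_stability` (named
#'   numeric of the encoded relative stabilities).
#' @export
gen_oxidation_curves <- function(spec, phi = spec$phi_levels[1L],
                                 stability_from = c("linear_model",
                                                    "t_induction")) {
  stopifnot(inherits(spec, "scenario_spec"))
  stability_from <- match.arg(stability_from)
  set.seed(spec$seed + 1L)
  make_curve <- function(t_ind, sample, is_control = FALSE) {
    if (t_ind <= 0) stop("nonpositive induction time", call. = FALSE)
    rise <- 5        # plateau amplitude, % CD
    s <- t_ind / 10  # logistic steepness
    t_mid <- t_ind + s * log(rise / 0.5 - 1)
    tt <- seq(0, 2.5 * t_ind, length.out = 120L)
    cd <- spec$cd_baseline + rise / (1 + exp(-(tt - t_mid) / s)) +
      stats::rnorm(length(tt), 0, spec$cd_sigma)
    oxidation_curve(tt, pmax(cd, 0), sample = sample,
                    is_control = is_control)
  }
  comp <- emulsion_composition(spec$phi_oil, spec$phi_water, phi)
  t_inds <- vapply(seq_len(nrow(spec$compounds)), function(ci) {
    row <- spec$compounds[ci, ]
    if (stability_from == "t_induction") return(row$t_induction)
    prof <- distribution_two_region(.panel_partition(row), comp,
                                    spec$total_ao)
    mu <- spec$beta0 +
      spec$beta[["c_interface"]] * prof$c_interface * 1e3 +
      spec$beta[["epa"]] * row$epa +
      spec$beta[["c_water"]] * prof$c_water * 1e3
    spec$t_control * (1 + max(mu, 0.02))
  }, numeric(1))
  control <- make_curve(spec$t_control, "control", is_control = TRUE)
  samples <- lapply(seq_len(nrow(spec$compounds)), function(ci)
    make_curve(t_inds[ci], spec$compounds$compound[ci]))
  names(samples) <- spec$compounds$compound
  list(control = control, samples = samples,
       planted_stability = stats::setNames(
         t_inds / spec$t_control - 1, spec$compounds$compound))
}

#' Generate a compound property table with a planted stability model
#'
#' Builds one row per (compound, phi level): predictor columns come from
#' the truth (effective regional concentrations via the two-region
#' pseudophase model on the true partition constants; redox and assay
#' properties straight from the panel), and the response is the planted
#' linear model
#' `stability = beta0 + b1 * c_interface + b2 * epa + b3 * c_water + noise`
#' with concentrations in mM.
#'
#' @param spec A [scenario_spec()].
#' @return Data frame of compound records with attribute `truth` carrying
#'   the planted coefficients.
#' @export
gen_compound_table <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed + 2L)
  rows <- list()
  for (ci in seq_len(nrow(spec$compounds))) {
    row <- spec$compounds[ci, ]
    part <- .panel_partition(row)
    for (phi in spec$phi_levels) {
      comp <- emulsion_composition(spec$phi_oil, spec$phi_water, phi)
      prof <- distribution_two_region(part, comp, spec$total_ao)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = row$compound, phi_interface = phi,
        epa = row$epa,
        ec50 = if ("ec50" %in% names(row)) row$ec50 else NA_real_,
        frap = if ("frap" %in% names(row)) row$frap else NA_real_,
        c_interface = prof$c_interface * 1e3,  # mM
        c_water = prof$c_water * 1e3,
        c_oil = prof$c_oil * 1e3)
    }
  }
  tab <- do.call(rbind, rows)
  mu <- spec$beta0 +
    spec$beta[["c_interface"]] * tab$c_interface +
    spec$beta[["epa"]] * tab$epa +
    spec$beta[["c_water"]] * tab$c_water
  tab$relative_stability <- mu +
    stats::rnorm(nrow(tab), 0, spec$stability_sigma)
  attr(tab, "truth") <- list(beta0 = spec$beta0, beta = spec$beta,
                             sigma = spec$stability_sigma)
  tab
}

#' Write a synthetic scenario to disk as CSV files plus a manifest
#'
#' Materialises [gen_traces()], [gen_oxidation_curves()] and
#' [gen_compound_table()] into a directory tree of plain CSV files with a
#' JSON manifest echoing the scenario parameters, for consumption by the
#' file-based readers.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_scenario <- function(spec, dir) {
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "oxidation"), showWarnings = FALSE)
  traces <- gen_traces(spec)
  for (tr in traces) {
    fn <- sprintf("trace_%s_phi%s_rep%d.csv", attr(tr, "compound"),
                  gsub("\\.", "p", format(attr(tr, "phi_interface"))),
                  attr(tr, "replicate"))
    utils::write.csv(
      data.frame(time_s = tr$time_s, absorbance = tr$absorbance),
      file.path(dir, "traces", fn), row.names = FALSE)
  }
  ox <- gen_oxidation_curves(spec)
  utils::write.csv(
    data.frame(time_h = ox$control$time_h,
               cd_percent = ox$control$cd_percent),
    file.path(dir, "oxidation", "control.csv"), row.names = FALSE)
  for (nm in names(ox$samples)) {
    cu <- ox$samples[[nm]]
    utils::write.csv(
      data.frame(time_h = cu$time_h, cd_percent = cu$cd_percent),
      file.path(dir, "oxidation", paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(gen_compound_table(spec),
                   file.path(dir, "compound_table.csv"), row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  sp <- unclass(spec)
  sp$compounds <- as.list(sp$compounds)
  jsonlite::write_json(sp, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
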