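# End-to-end orchestration: traces -> k_obs -> partition constants ->
# distributions -> oxidative stability -> correlation / stepwise model.

#' Default pipeline configuration
#'
#' All tunable pipeline parameters with their defaults: the 4:6 emulsion
#' composition, the 0.24 mM stoichiometric antioxidant concentration, the
#' +0.5 percentage-point conjugated-diene threshold, the phi levels at
#' which distributions and stabilities are reported, and the stepwise
#' thresholds.
#'
#' @param ... Overrides for any default field.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    phi_oil = 0.4, phi_water = 0.6,
    total_ao = 0.24e-3,
    threshold_increase = 0.5,
    phi_report = c(0.005, 0.01),
    candidates = c("c_interface", "epa", "c_water"),
    p_enter = 0.150, p_remove = 0.200,
    weighting = "none")
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(cfg, overrides)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pseudophase analysis pipeline on a synthetic scenario
#'
#' Executes the whole chain on a [scenario_spec()]: generates traces, fits
#' every trace to the integrated first-order law, aggregates replicate
#' k_obs into series, fits (k_I, P) per compound, computes distribution
#' profiles at the reporting phi levels, reduces the oxidation curves to
#' relative stabilities, assembles the compound record table, and runs the
#' Pearson screen and the stepwise regression. Identical spec and config
#' give identical outputs.
#'
#' @param spec A [scenario_spec()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; if given, every output table is also
#'   written there as CSV along with a JSON run manifest.
#' @return List of class `phasekin_run`: `kobs_summary`, `partition_fits`
#'   (per-compound table of fitted k_I and P with errors and truth),
#'   `distributions` (per compound x phi), `stability` (per compound x
#'   phi), `records` (assembled analysis table), `pearson`, `stepwise`,
#'   `manifest`.
#' @examples
#' \donttest{
#' run <- run_pipeline(scenario_spec(seed = 7))
#' run$partition_fits
#' run$stepwise$predictors
#' }
#' @export
run_pipeline <- function(spec, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  comp_base <- emulsion_composition(config$phi_oil, config$phi_water,
                                    spec$phi_levels[1L])

  traces <- .stage("simulate", gen_traces(spec))

  fits <- .stage("fit_kobs", lapply(traces, fit_first_order))

  by_compound <- split(fits, vapply(fits, function(f) f$compound,
                                    character(1)))
  agg <- .stage("aggregate_kobs", {
    lapply(names(by_compound), function(nm) {
      pair <- spec$compounds$region_pair[spec$compounds$compound == nm]
      aggregate_kobs(by_compound[[nm]], total_ao = spec$total_ao,
                     region_pair = pair)
    }) |> stats::setNames(names(by_compound))
  })
  kobs_summary <- do.call(rbind, lapply(names(agg), function(nm)
    cbind(compound = nm, agg[[nm]]$summary)))

  pfits <- .stage("fit_partition", {
    lapply(names(agg), function(nm)
      fit_partition(agg[[nm]]$series, comp_base,
                    weighting = config$weighting)) |>
      stats::setNames(names(agg))
  })
  partition_fits <- do.call(rbind, lapply(names(pfits), function(nm) {
    f <- pfits[[nm]]
    p <- if (f$region_pair == "water_interface") f$partition$p_wi else
      f$partition$p_oi
    perr <- if (f$region_pair == "water_interface") f$partition$p_wi_err
    else f$partition$p_oi_err
    truth <- spec$compounds[spec$compounds$compound == nm, ]
    data.frame(compound = nm, region_pair = f$region_pair,
               k_i = f$k_i, k_i_err = f$k_i_err, p = p, p_err = perr,
               k_i_true = truth$k_i, p_true = truth$p)
  }))

  distributions <- .stage("distribute", {
    do.call(rbind, lapply(names(pfits), function(nm) {
      f <- pfits[[nm]]
      do.call(rbind, lapply(config$phi_report, function(phi) {
        comp <- emulsion_composition(config$phi_oil, config$phi_water, phi)
        part <- f$partition
        prof <- distribution_two_region(part, comp, spec$total_ao)
        data.frame(compound = nm, phi_interface = phi,
                   f_interface = prof$f_interface,
                   c_interface_mM = prof$c_interface * 1e3,
                   c_water_mM = prof$c_water * 1e3,
                   c_oil_mM = prof$c_oil * 1e3,
                   enhancement = interfacial_enhancement(prof))
      }))
    }))
  })

  stability <- .stage("stability", {
    do.call(rbind, lapply(config$phi_report, function(phi) {
      ox <- gen_oxidation_curves(spec, phi = phi)
      do.call(rbind, lapply(names(ox$samples), function(nm) {
        st <- relative_stability(ox$samples[[nm]], ox$control,
                                 config$threshold_increase)
        data.frame(compound = nm, phi_interface = phi,
                   t_ao = st$t_ao, t_control = st$t_control,
                   relative_stability = st$relative_increase)
      }))
    }))
  })

  records <- .stage("assemble", {
    m <- merge(distributions, stability,
               by = c("compound", "phi_interface"))
    m <- merge(m, spec$compounds[, c("compound", "epa")], by = "compound")
    m$c_interface <- m$c_interface_mM
    m$c_water <- m$c_water_mM
    m$c_oil <- m$c_oil_mM
    m
  })

  pearson <- .stage("correlate", pearson_matrix(
    records, "relative_stability",
    intersect(config$candidates, names(records))))
  stepwise <- .stage("slra", stepwise_regression(
    records, "relative_stability",
    intersect(config$candidates, names(records)),
    p_enter = config$p_enter, p_remove = config$p_remove))

  manifest <- list(
    config = config,
    scenario_seed = spec$seed,
    n_traces = length(traces),
    compounds = spec$compounds$compound,
    phi_levels = spec$phi_levels,
    stages = c("simulate", "fit_kobs", "aggregate_kobs", "fit_partition",
               "distribute", "stability", "assemble", "correlate", "slra"),
    selected_predictors = stepwise$predictors)

  out <- structure(list(
    kobs_summary = kobs_summary, partition_fits = partition_fits,
    distributions = distributions, stability = stability,
    records = records, pearson = pearson, stepwise = stepwise,
    manifest = manifest),
    class = "phasekin_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("kobs_summary", "partition_fits", "distributions",
                 "stability", "records", "pearson")) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(stepwise$steps,
                     file.path(out_dir, "stepwise_steps.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.phasekin_run <- function(x, ...) {
  cat("phasekin pipeline run\n")
  cat(sprintf("  %d compounds, %d trace fits\n",
              nrow(x$partition_fits), x$manifest$n_traces))
  cat("\nPartition fits (fitted vs true):\n")
  print(x$partition_fits, row.names = FALSE, digits = 4)
  cat("\nStepwise selection:",
      paste(x$stepwise$predictors, collapse = " -> "), "\n")
  invisible(x)
}
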