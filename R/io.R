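# Plain-CSV readers for the pipeline's file-based inputs. All files are
# UTF-8, comma-separated, decimal point, with a mandatory header; lines
# starting with '#' are comments.

.read_csv <- function(path, required) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Read an absorbance-time trace CSV
#'
#' Expects columns `time_s,absorbance`; metadata is taken from arguments
#' (typically parsed from the filename by the caller).
#'
#' @param path CSV path.
#' @param compound,phi_interface,replicate Metadata for the trace.
#' @return An [absorbance_trace()].
#' @export
read_trace <- function(path, compound = NA_character_,
                       phi_interface = NA_real_, replicate = 1L) {
  df <- .read_csv(path, c("time_s", "absorbance"))
  absorbance_trace(df$time_s, df$absorbance, compound = compound,
                   phi_interface = phi_interface, replicate = replicate)
}

#' Read a rate-constant series CSV
#'
#' Expects columns `phi_interface,k_obs,replicate`.
#'
#' @param path CSV path.
#' @inheritParams rate_series
#' @return A [rate_series()].
#' @export
read_rate_series <- function(path, total_ao,
                             region_pair = c("water_interface",
                                             "oil_interface"),
                             compound = NA_character_) {
  df <- .read_csv(path, c("phi_interface", "k_obs", "replicate"))
  rate_series(df$phi_interface, df$k_obs, df$replicate,
              total_ao = total_ao, region_pair = match.arg(region_pair),
              compound = compound)
}

#' Read an oxidation-curve CSV
#'
#' Expects columns `time_h,cd_percent`.
#'
#' @param path CSV path.
#' @inheritParams oxidation_curve
#' @return An [oxidation_curve()].
#' @export
read_oxidation_curve <- function(path, sample = NA_character_,
                                 is_control = FALSE) {
  df <- .read_csv(path, c("time_h", "cd_percent"))
  oxidation_curve(df$time_h, df$cd_percent, sample = sample,
                  is_control = is_control)
}

#' Read a DPPH dose-response CSV
#'
#' Expects columns `mole_ratio,fraction_remaining`.
#'
#' @param path CSV path.
#' @inheritParams dose_response
#' @return A [dose_response()].
#' @export
read_dose_response <- function(path, time_label = 60) {
  df <- .read_csv(path, c("mole_ratio", "fraction_remaining"))
  dose_response(df$mole_ratio, df$fraction_remaining,
                time_label = time_label)
}

#' Read a compound property table CSV
#'
#' A Table-1-style property table: one row per compound with partition
#' constants (empty cell = constant not measurable), redox and assay
#' properties. Requires at least `compound` plus one of `p_oi`/`p_wi`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_compound_table <- function(path) {
  df <- .read_csv(path, "compound")
  if (!any(c("p_oi", "p_wi") %in% names(df)))
    stop("compound table needs a 'p_oi' or 'p_wi' column", call. = FALSE)
  df
}

#' Bundled reference panel of phenolipid properties
#'
#' Measured properties of tyrosol, hydroxytyrosol, 4-hydroxycinnamic acid,
#' caffeic acid and dihydrocaffeic acid and their octyl/hexadecyl esters in
#' 4:6 olive oil-in-water emulsions: anodic peak potentials, DPPH EC50 at
#' 5 and 60 min, FRAP values, and the oil-interface / water-interface
#' partition constants where the kinetic method could determine them.
#'
#' @return Data frame with one row per compound.
#' @examples
#' head(phenolipid_panel())
#' @export
phenolipid_panel <- function() {
  read_compound_table(system.file("extdata", "phenolipid_panel.csv",
                                  package = "phasekin", mustWork = TRUE))
}

#' Interfacial enhancement across a compound panel
#'
#' For every compound in a property table with a measured partition
#' constant, computes the two-region distribution at the given composition
#' and returns the effective interfacial concentration and its
#' enhancement over the stoichiometric concentration.
#'
#' @param table Compound table as from [read_compound_table()] or
#'   [phenolipid_panel()].
#' @param comp An [emulsion_composition()].
#' @param total_ao Stoichiometric antioxidant concentration, M.
#' @return Data frame with `compound`, `region_pair`, `p`,
#'   `c_interface_mM`, `enhancement` (= c_interface / total_ao),
#'   `f_interface`.
#' @examples
#' panel_distribution(phenolipid_panel(),
#'                    emulsion_composition(0.4, 0.6, 0.01), 0.24e-3)
#' @export
panel_distribution <- function(table, comp, total_ao) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    has_oi <- "p_oi" %in% names(row) && !is.na(row$p_oi)
    has_wi <- "p_wi" %in% names(row) && !is.na(row$p_wi)
    if (!has_oi && !has_wi) return(NULL)
    part <- if (has_oi && has_wi)
      partition_set(p_oi = row$p_oi, p_wi = row$p_wi)
    else if (has_oi) partition_set(p_oi = row$p_oi)
    else partition_set(p_wi = row$p_wi)
    prof <- if (has_oi && has_wi)
      distribution_three_region(part, comp, total_ao)
    else distribution_two_region(part, comp, total_ao)
    data.frame(
      compound = row$compound,
      region_pair = if (has_oi && has_wi) "three_region"
      else if (has_oi) "oil_interface" else "water_interface",
      p = if (has_oi) row$p_oi else row$p_wi,
      c_interface_mM = prof$c_interface * 1e3,
      enhancement = interfacial_enhancement(prof),
      f_interface = prof$f_interface)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
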