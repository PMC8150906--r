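#' Emulsion composition (volume fractions of the three pseudophase regions)
#'
#' Describes a surfactant-stabilised oil-in-water emulsion as three
#' thermodynamic regions: oil, water, and the surfactant interfacial film.
#' The interfacial volume fraction is defined as the volume of surfactant
#' over the total emulsion volume.
#'
#' Fractions follow the additive convention used in kinetic partitioning
#' work: `phi_oil` and `phi_water` are the nominal fractions of the two bulk
#' phases (0.4 and 0.6 for a 4:6 emulsion) and are held fixed while
#' `phi_interface` varies, so the three values may sum slightly above 1.
#'
#' @param phi_oil Volume fraction of the oil region, in (0, 1).
#' @param phi_water Volume fraction of the aqueous region, in (0, 1).
#' @param phi_interface Volume fraction of the interfacial region
#'   (surfactant volume / emulsion volume), in (0, 1). Values outside the
#'   usual experimental span 0.005--0.04 trigger a warning, not an error.
#' @return An object of class `emulsion_composition`.
#' @examples
#' emulsion_composition(0.4, 0.6, 0.01)
#' @export
emulsion_composition <- function(phi_oil = 0.4, phi_water = 0.6,
                                 phi_interface = 0.005) {
  for (nm in c("phi_oil", "phi_water", "phi_interface")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    if (v <= 0 || v >= 1)
      stop(sprintf("'%s' must lie strictly between 0 and 1", nm),
           call. = FALSE)
  }
  if (phi_oil + phi_water + phi_interface > 1.05)
    stop("volume fractions sum above 1.05; check the composition",
         call. = FALSE)
  if (phi_interface < 0.005 || phi_interface > 0.04)
    warning(sprintf(
      "phi_interface = %g is outside the usual experimental span [0.005, 0.04]",
      phi_interface), call. = FALSE)
  structure(
    list(phi_oil = phi_oil, phi_water = phi_water,
         phi_interface = phi_interface),
    class = "emulsion_composition")
}

#' @export
print.emulsion_composition <- function(x, ...) {
  cat(sprintf(
    "Emulsion composition: phi_oil = %g, phi_water = %g, phi_interface = %g\n",
    x$phi_oil, x$phi_water, x$phi_interface))
  invisible(x)
}

#' Partition constants of one antioxidant
#'
#' Holds the oil-interface and/or water-interface partition constants of a
#' single compound. Each constant is the ratio of effective antioxidant
#' concentrations (moles per litre of region) between the interfacial region
#' and the named bulk region, so both are dimensionless. A hydrophobic
#' phenolipid that is oil- and interface-soluble carries only `p_oi`; a
#' water-soluble parent phenol carries only `p_wi`; a compound present in
#' all three regions carries both.
#'
#' @param p_oi Oil-to-interface partition constant (>= 0), or `NA`.
#' @param p_wi Water-to-interface partition constant (>= 0), or `NA`.
#' @param p_oi_err,p_wi_err Optional standard errors.
#' @return An object of class `partition_set`.
#' @examples
#' partition_set(p_oi = 368, p_oi_err = 29)  # octyl dihydrocaffeate
#' partition_set(p_wi = 53, p_wi_err = 7)    # hydroxytyrosol
#' @export
partition_set <- function(p_oi = NA_real_, p_wi = NA_real_,
                          p_oi_err = NA_real_, p_wi_err = NA_real_) {
  vals <- list(p_oi = p_oi, p_wi = p_wi, p_oi_err = p_oi_err,
               p_wi_err = p_wi_err)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) && !is.logical(v) || length(v) != 1L)
      stop(sprintf("'%s' must be a single number or NA", nm), call. = FALSE)
    if (!is.na(v) && v < 0)
      stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  if (is.na(p_oi) && is.na(p_wi))
    stop("at least one of 'p_oi', 'p_wi' must be given", call. = FALSE)
  structure(list(p_oi = as.numeric(p_oi), p_wi = as.numeric(p_wi),
                 p_oi_err = as.numeric(p_oi_err),
                 p_wi_err = as.numeric(p_wi_err)),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  fmt <- function(p, e) {
    if (is.na(p)) return("not measured")
    if (is.na(e)) sprintf("%g", p) else sprintf("%g +/- %g", p, e)
  }
  cat("Partition constants:\n")
  cat("  P_OI (oil -> interface):   ", fmt(x$p_oi, x$p_oi_err), "\n")
  cat("  P_WI (water -> interface): ", fmt(x$p_wi, x$p_wi_err), "\n")
  invisible(x)
}

# Which two-region pair does a one-constant partition_set describe?
region_pair <- function(partition) {
  has_oi <- !is.na(partition$p_oi)
  has_wi <- !is.na(partition$p_wi)
  if (has_oi && has_wi)
    stop("both partition constants present; use distribution_three_region()",
         call. = FALSE)
  if (!has_oi && !has_wi)
    stop("no partition constant present", call. = FALSE)
  if (has_oi) "oil_interface" else "water_interface"
}
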