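# Forward distribution math of the pseudophase model.
#
# Effective concentrations are in moles per litre OF THE REGION, so the
# interfacial concentration can exceed the stoichiometric concentration by
# orders of magnitude when phi_interface is small: c_region = f_region *
# total_ao / phi_region, and mass balance reads
# sum(c_region * phi_region) = total_ao.

# Partition constants at or above this are treated as "exclusively
# interfacial": the compound has no measurable presence in the bulk region.
.P_LARGE <- 1e9

new_distribution_profile <- function(f, c, total_ao, comp) {
  stopifnot(names(f) == c("oil", "water", "interface"))
  structure(list(
    f_oil = f[["oil"]], f_water = f[["water"]], f_interface = f[["interface"]],
    c_oil = c[["oil"]], c_water = c[["water"]], c_interface = c[["interface"]],
    total_ao = total_ao, composition = comp),
    class = "distribution_profile")
}

#' @export
print.distribution_profile <- function(x, ...) {
  cat(sprintf("Antioxidant distribution at phi_interface = %g ([AO_T] = %g M)\n",
              x$composition$phi_interface, x$total_ao))
  df <- data.frame(
    region = c("oil", "water", "interface"),
    fraction = c(x$f_oil, x$f_water, x$f_interface),
    conc_M = c(x$c_oil, x$c_water, x$c_interface))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Two-region antioxidant distribution
#'
#' Distributes an antioxidant between the interfacial region and one bulk
#' region (water for hydrophilic compounds with only a water-interface
#' constant, oil for hydrophobic ones with only an oil-interface constant).
#' For the water + interface case the interfacial mole fraction is
#' \deqn{f_I = P_{WI}\Phi_I / (\Phi_W + P_{WI}\Phi_I)}
#' and symmetrically with the oil fraction for oil + interface. Effective
#' concentrations are per litre of region: `c_interface = f_I * total_ao /
#' phi_interface`, etc.; the absent region's concentration is reported as 0.
#'
#' @param partition A [partition_set()] with exactly one constant present.
#' @param comp An [emulsion_composition()].
#' @param total_ao Stoichiometric antioxidant concentration, mol per litre
#'   of whole emulsion.
#' @return A `distribution_profile` with per-region mole fractions
#'   (`f_oil`, `f_water`, `f_interface`) and effective molarities (`c_oil`,
#'   `c_water`, `c_interface`).
#' @examples
#' # hydroxytyrosol (P_WI = 53) in a 4:6 emulsion at phi_I = 0.01:
#' p <- distribution_two_region(partition_set(p_wi = 53),
#'                              emulsion_composition(0.4, 0.6, 0.01),
#'                              total_ao = 0.24e-3)
#' p$c_interface / 0.24e-3  # interfacial enhancement, ~47-fold
#' @seealso [distribution_three_region()], [kobs_model()]
#' @export
distribution_two_region <- function(partition, comp, total_ao) {
  stopifnot(inherits(partition, "partition_set"),
            inherits(comp, "emulsion_composition"))
  if (!is.numeric(total_ao) || length(total_ao) != 1L || total_ao <= 0)
    stop("'total_ao' must be a single positive concentration", call. = FALSE)
  if (comp$phi_interface <= 0)
    stop("no interfacial volume", call. = FALSE)
  pair <- region_pair(partition)
  phi_i <- comp$phi_interface
  if (pair == "water_interface") {
    p <- partition$p_wi
    phi_bulk <- comp$phi_water
    bulk <- "water"
  } else {
    p <- partition$p_oi
    phi_bulk <- comp$phi_oil
    bulk <- "oil"
  }
  f_i <- if (p >= .P_LARGE) 1 else p * phi_i / (phi_bulk + p * phi_i)
  f <- c(oil = 0, water = 0, interface = f_i)
  f[bulk] <- 1 - f_i
  cc <- c(oil = 0, water = 0, interface = f_i * total_ao / phi_i)
  cc[bulk] <- f[bulk] * total_ao / phi_bulk
  new_distribution_profile(f[c("oil", "water", "interface")],
                           cc[c("oil", "water", "interface")],
                           total_ao, comp)
}

#' Three-region antioxidant distribution
#'
#' Distributes an antioxidant among oil, water and interface when both
#' partition constants are known. Combining the two concentration-ratio
#' definitions with mass balance gives
#' \deqn{f_I = \frac{P_{OI}P_{WI}\Phi_I}
#'   {P_{OI}P_{WI}\Phi_I + P_{WI}\Phi_O + P_{OI}\Phi_W}}
#' with `f_oil` and `f_water` given by the corresponding terms of the
#' denominator. Sending one constant to a very large value (>= 1e9) recovers
#' the two-region limit in the other pair.
#'
#' @inheritParams distribution_two_region
#' @param partition A [partition_set()] with both constants present and
#'   positive.
#' @return A `distribution_profile`.
#' @export
distribution_three_region <- function(partition, comp, total_ao) {
  stopifnot(inherits(partition, "partition_set"),
            inherits(comp, "emulsion_composition"))
  if (!is.numeric(total_ao) || length(total_ao) != 1L || total_ao <= 0)
    stop("'total_ao' must be a single positive concentration", call. = FALSE)
  if (comp$phi_interface <= 0)
    stop("no interfacial volume", call. = FALSE)
  p_oi <- partition$p_oi
  p_wi <- partition$p_wi
  if (is.na(p_oi) || is.na(p_wi))
    stop("both partition constants must be present", call. = FALSE)
  if (p_oi <= 0 || p_wi <= 0)
    stop("partition constants must be positive", call. = FALSE)
  # Large-P guard: an effectively infinite constant empties the bulk region.
  if (p_oi >= .P_LARGE && p_wi >= .P_LARGE) {
    f <- c(oil = 0, water = 0, interface = 1)
  } else if (p_oi >= .P_LARGE) {
    two <- distribution_two_region(partition_set(p_wi = p_wi), comp, total_ao)
    return(two)
  } else if (p_wi >= .P_LARGE) {
    two <- distribution_two_region(partition_set(p_oi = p_oi), comp, total_ao)
    return(two)
  } else {
    denom <- p_oi * p_wi * comp$phi_interface +
      p_wi * comp$phi_oil + p_oi * comp$phi_water
    f <- c(oil = p_wi * comp$phi_oil / denom,
           water = p_oi * comp$phi_water / denom,
           interface = p_oi * p_wi * comp$phi_interface / denom)
  }
  cc <- c(oil = f[["oil"]] * total_ao / comp$phi_oil,
          water = f[["water"]] * total_ao / comp$phi_water,
          interface = f[["interface"]] * total_ao / comp$phi_interface)
  new_distribution_profile(f, cc, total_ao, comp)
}

#' Interfacial enhancement ratio
#'
#' Ratio of the effective interfacial concentration to the stoichiometric
#' concentration, `c_interface / total_ao`. This is the "n-fold higher at
#' the interface" figure of merit that rationalises why interfacially
#' accumulated antioxidants outperform their bulk concentration.
#'
#' @param profile A `distribution_profile`.
#' @return A single dimensionless ratio.
#' @export
interfacial_enhancement <- function(profile) {
  stopifnot(inherits(profile, "distribution_profile"))
  profile$c_interface / profile$total_ao
}
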