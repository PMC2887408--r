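#' Combined female gonadosomatic index
#'
#' Female snails carry reproductive tissue beyond the ovary (pallial
#' gonoduct, ovipositor); a more accurate female gonadosomatic index adds
#' the accessory-tissue relative mass to the ovary relative mass.
#' Standard errors, when supplied, combine in quadrature.
#'
#' @param ovary_fraction ovary relative mass, in (0, 1) or as a percentage
#'   (both fractions must use the same scale).
#' @param accessory_fraction accessory reproductive-tissue relative mass.
#' @param ovary_se,accessory_se optional standard errors on the same scale.
#' @return the combined index; if standard errors are given, a vector with
#'   elements \code{gsi} and \code{se}.
#' @examples
#' combined_female_gsi(7.7, 7.2)                 # 14.9 (percent scale)
#' combined_female_gsi(0.077, 0.072)             # 0.149
#' @export
combined_female_gsi <- function(ovary_fraction, accessory_fraction,
                                ovary_se = NULL, accessory_se = NULL) {
  stopifnot(is.numeric(ovary_fraction), is.numeric(accessory_fraction))
  pct <- ovary_fraction > 1 || accessory_fraction > 1
  upper <- if (pct) 100 else 1
  if (ovary_fraction <= 0 || accessory_fraction < 0)
    stop("fractions must be positive")
  total <- ovary_fraction + accessory_fraction
  if (total >= upper)
    stop("combined index reaches or exceeds the whole body mass")
  if (is.null(ovary_se) && is.null(accessory_se)) return(total)
  se <- sqrt(sum(c(ovary_se, accessory_se)^2))
  c(gsi = total, se = se)
}

#' Relative reproductive allocation
#'
#' The gonadosomatic index divided by the proportional allocation to
#' growth at the mean-sized snail.  Because both are fractions of the same
#' total mass, the index simplifies to reproductive tissue mass over new
#' growth mass; both routes are available and agree algebraically.
#'
#' @param gsi gonadosomatic index (fraction in (0, 1)).
#' @param proportional_growth new growth mass as a fraction of total mass,
#'   > 0.
#' @return the dimensionless allocation ratio.
#' @examples
#' relative_reproductive_allocation(0.2, 0.1)  # 2
#' @export
relative_reproductive_allocation <- function(gsi, proportional_growth) {
  stopifnot(is.numeric(gsi), is.numeric(proportional_growth))
  if (any(gsi <= 0)) stop("gsi must be > 0")
  if (any(proportional_growth <= 0))
    stop("relative reproductive allocation is undefined at zero growth")
  gsi / proportional_growth
}

#' Relative reproductive allocation from masses
#'
#' The mass route: reproductive tissue mass divided by new growth mass.
#' Equivalent to \code{\link{relative_reproductive_allocation}} applied to
#' the corresponding fractions of total mass.
#'
#' @param repro_mass reproductive tissue mass (> 0).
#' @param growth_mass new growth mass (> 0).
#' @return the allocation ratio.
#' @export
rra_from_masses <- function(repro_mass, growth_mass) {
  if (any(repro_mass <= 0)) stop("reproductive mass must be > 0")
  if (any(growth_mass <= 0)) stop("undefined at zero growth mass")
  repro_mass / growth_mass
}

#' Assemble the comparative species-allocation table
#'
#' One row per group: total growth allocation (the area under the group's
#' growth curve), growth at the mean-sized snail, the gonadosomatic index,
#' relative reproductive allocation, and differential mortality.  Groups
#' missing any input are dropped with a warning.  Proportional allocation
#' to growth is (growth mass at the mean size) / (soft-tissue mass at the
#' mean size), with mass = density x volume; the density constant cancels
#' out of cross-species correlations but is exposed for completeness.
#'
#' @param fit a \code{\link{fit_growth}} result.
#' @param mortality data.frame from \code{\link{mortality_table}}.
#' @param gsi named vector (or two-column data.frame \code{group},
#'   \code{gsi}) of gonadosomatic indices as fractions.
#' @param mean_size initial volume (mm^3) of the mean-sized snail; default
#'   the fit's mean initial volume.
#' @param limits integration limits; default
#'   \code{\link{default_integration_limits}}.
#' @param density soft-tissue density in mg per mm^3 (default 1).
#' @return data.frame of class \code{"species_allocation"} with columns
#'   \code{group}, \code{total_growth_allocation}, \code{growth_at_mean},
#'   \code{gsi}, \code{proportional_growth}, \code{rra},
#'   \code{differential_mortality}.
#' @export
build_allocation_table <- function(fit, mortality, gsi,
                                   mean_size = NULL, limits = NULL,
                                   density = 1) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.data.frame(gsi)) gsi <- stats::setNames(gsi$gsi, gsi$group)
  if (anyDuplicated(names(gsi))) stop("duplicate group codes in gsi table")
  if (anyDuplicated(mortality$group))
    stop("duplicate group codes in mortality table")
  if (is.null(mean_size)) mean_size <- fit$mean_initial_volume
  if (is.null(limits)) limits <- default_integration_limits(fit)

  groups <- fit$group_levels
  keep <- groups %in% names(gsi) & groups %in% mortality$group
  dropped <- groups[!keep]
  if (length(dropped))
    warning("dropped group(s) missing gsi or mortality: ",
            paste(dropped, collapse = ", "))
  groups <- groups[keep]
  rows <- lapply(groups, function(g) {
    curve <- growth_curve(fit, g)
    g_mean <- curve$f(mean_size)
    total <- total_growth_allocation(curve, limits[1L], limits[2L])
    prop_growth <- (g_mean * density) / (mean_size * density)
    data.frame(group = g,
               total_growth_allocation = total,
               growth_at_mean = g_mean,
               gsi = unname(gsi[g]),
               proportional_growth = prop_growth,
               rra = relative_reproductive_allocation(unname(gsi[g]),
                                                      prop_growth),
               differential_mortality =
                 mortality$differential_mortality[mortality$group == g],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_allocation", "data.frame")
  out
}
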