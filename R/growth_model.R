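#' Derive growth and size covariates from raw shell measurements
#'
#' Adds \code{growth} (mm^3 of new shell, from final width and degrees of
#' growth) and \code{initial_volume} (mm^3, cone approximation) to a record
#' table.
#'
#' @param records record data.frame with the raw measurement columns.
#' @param scaling a \code{\link{scaling_relation}} (kept for symmetry with
#'   the generator; not used by the cone route).
#' @param radius_fraction cone base radius as a fraction of width.
#' @return the records with \code{growth} and \code{initial_volume} columns.
#' @export
prepare_growth_data <- function(records, scaling = scaling_relation(),
                                radius_fraction = 0.5) {
  ok <- !is.na(records$final_width) & !is.na(records$degrees_growth)
  records$growth <- NA_real_
  records$growth[ok] <- growth_volume(records$final_width[ok],
                                      records$degrees_growth[ok])
  ok0 <- !is.na(records$initial_length) & !is.na(records$initial_width)
  records$initial_volume <- NA_real_
  records$initial_volume[ok0] <- initial_volume(
    records$initial_length[ok0], records$initial_width[ok0],
    radius_fraction = radius_fraction)
  records
}

# assemble the model formula, dropping terms a degenerate design cannot
# support (single estuary, single site, one growing period, ...)
.growth_formula <- function(dat, response) {
  rhs <- if (nlevels(dat$group) > 1L) "group" else character()
  if (stats::sd(dat$initial_volume) > 0) {
    rhs <- c(rhs, "initial_volume")
    if (nlevels(dat$group) > 1L) rhs <- c(rhs, "group:initial_volume")
  }
  multi_est <- nlevels(dat$estuary) > 1L
  multi_hab <- nlevels(dat$habitat) > 1L
  if (multi_est) rhs <- c(rhs, "estuary")
  if (multi_hab) rhs <- c(rhs, if (multi_est) "estuary:habitat" else "habitat")
  if (nlevels(dat$site) > 1L) {
    nest <- c(if (multi_est) "estuary", if (multi_hab) "habitat", "site")
    rhs <- c(rhs, paste(nest, collapse = ":"))
  }
  if (nlevels(dat$period) > 1L)
    rhs <- c(rhs, if (multi_est) "estuary:period" else "period")
  if (length(rhs) == 0L) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit the overdispersed Poisson growth model
#'
#' Fits individual growth (mm^3) with a log link and a Poisson variance
#' inflated by a multiplicative overdispersion parameter (quasi-Poisson;
#' the point estimates equal plain Poisson maximum likelihood, the Pearson
#' dispersion scales the uncertainties).  The full design is
#' species-group, initial size and their interaction, estuary, habitat
#' nested in estuary, site nested in (estuary, habitat), and growing time
#' nested in estuary; terms that a given dataset cannot support (one site,
#' one period, ...) are dropped automatically.  Per-term likelihood-ratio
#' chi-square statistics are sequential deviance drops divided by the
#' dispersion estimate.
#'
#' @param records record table; raw measurement columns are converted with
#'   \code{\link{prepare_growth_data}} if \code{growth} is absent.
#' @param response \code{"absolute"} (growth in mm^3, default) or
#'   \code{"proportional"} (growth divided by initial volume).
#' @param family \code{"quasipoisson"} (default) or \code{"poisson"}.
#' @param reference_site,reference_period site and growing period to which
#'   curves and predictions are standardized; defaults to the first site
#'   level and first period level.
#' @return an object of class \code{"growth_fit"} with elements
#'   \code{glm}, \code{dispersion} (Pearson chi-square / df), \code{terms}
#'   (per-term LR table), \code{reference}, and per-group sampled size
#'   ranges.
#' @examples
#' w <- generate_world(default_world_config(n_per_site = 40), seed = 2)
#' dat <- apply_filters(prepare_growth_data(w$records))$records
#' fit <- fit_growth(dat)
#' fit$terms
#' @export
fit_growth <- function(records, response = c("absolute", "proportional"),
                       family = c("quasipoisson", "poisson"),
                       reference_site = NULL, reference_period = NULL) {
  response <- match.arg(response)
  family <- match.arg(family)
  if (!"growth" %in% names(records))
    records <- prepare_growth_data(records)
  dat <- records[!is.na(records$growth) & !is.na(records$initial_volume) &
                   !is.na(records$group), , drop = FALSE]
  if (nrow(dat) == 0L) stop("no usable growth records")
  for (v in c("group", "estuary", "habitat", "site", "period"))
    dat[[v]] <- factor(dat[[v]])
  zero <- tapply(dat$growth, dat$group, function(g) all(g == 0))
  if (any(zero))
    stop("group(s) with all-zero growth (log-link degeneracy): ",
         paste(names(zero)[zero], collapse = ", "))
  if (response == "proportional") dat$growth <- dat$growth / dat$initial_volume

  form <- .growth_formula(dat, "growth")
  fam <- if (family == "poisson") stats::poisson(link = "log")
         else stats::quasipoisson(link = "log")
  fit <- stats::glm(form, family = fam, data = dat)
  if (!fit$converged) warning("growth GLM did not converge")

  phi <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  an <- stats::anova(fit)
  tt <- data.frame(term = rownames(an)[-1L],
                   df = an$Df[-1L],
                   chisq = an$Deviance[-1L] / phi,
                   stringsAsFactors = FALSE)
  tt$p <- stats::pchisq(tt$chisq, tt$df, lower.tail = FALSE)
  whole <- data.frame(term = "whole model",
                      df = sum(tt$df),
                      chisq = (an$`Resid. Dev`[1L] -
                                 fit$deviance) / phi,
                      stringsAsFactors = FALSE)
  whole$p <- stats::pchisq(whole$chisq, whole$df, lower.tail = FALSE)
  tt <- rbind(tt, whole)

  if (is.null(reference_site)) reference_site <- levels(dat$site)[1L]
  if (is.null(reference_period)) reference_period <- levels(dat$period)[1L]
  ref_row <- dat[dat$site == reference_site, , drop = FALSE][1L, ]
  reference <- list(site = reference_site,
                    estuary = as.character(ref_row$estuary),
                    habitat = as.character(ref_row$habitat),
                    period = reference_period)

  ranges <- do.call(rbind, lapply(split(dat$initial_volume, dat$group),
                                  range))
  structure(list(glm = fit, dispersion = phi, terms = tt,
                 reference = reference,
                 group_levels = levels(dat$group),
                 group_ranges = ranges,
                 pooled_range = range(dat$initial_volume),
                 mean_initial_volume = mean(dat$initial_volume),
                 response = response, family = family,
                 formula = form),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Quasi-Poisson growth model (%s response): %d groups, dispersion %.2f\n",
              x$response, length(x$group_levels), x$dispersion))
  print(transform(x$terms, chisq = round(chisq, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

# model-matrix row for a prediction at the standardization reference
.reference_newdata <- function(fit, group, size) {
  data.frame(group = group,
             initial_volume = size,
             estuary = fit$reference$estuary,
             habitat = fit$reference$habitat,
             site = fit$reference$site,
             period = fit$reference$period,
             stringsAsFactors = FALSE)
}

.predict_eta <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit$glm))
  mf <- stats::model.frame(tt, newdata, xlev = fit$glm$xlevels)
  X <- stats::model.matrix(tt, mf, contrasts.arg = fit$glm$contrasts)
  beta <- stats::coef(fit$glm)
  keep <- !is.na(beta)
  list(X = X[, keep, drop = FALSE], beta = beta[keep],
       eta = unname(drop(X[, keep, drop = FALSE] %*% beta[keep])))
}

#' Size-specific growth curve for one group
#'
#' Expected growth as a function of initial size, standardized to the
#' fit's reference site and growing period.  The curve's nominal domain is
#' the group's sampled size range; evaluation is allowed anywhere inside
#' the pooled sampled range and errors beyond it.
#'
#' @param fit a \code{\link{fit_growth}} result.
#' @param group group code present in the fit.
#' @param size_range optional numeric length-2 domain override (mm^3).
#' @return an object of class \code{"growth_curve"}: a list with the
#'   evaluator \code{f(v)}, the \code{domain}, the pooled evaluation
#'   \code{limits} and the \code{group}.
#' @export
growth_curve <- function(fit, group, size_range = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!group %in% fit$group_levels)
    stop("group '", group, "' not present in fit")
  domain <- if (is.null(size_range)) fit$group_ranges[group, ]
            else as.numeric(size_range)
  limits <- fit$pooled_range
  f <- function(v) {
    if (any(v < limits[1L] - 1e-8 | v > limits[2L] + 1e-8))
      stop("size outside the pooled sampled range [",
           signif(limits[1L], 4), ", ", signif(limits[2L], 4), "] mm^3")
    exp(.predict_eta(fit, .reference_newdata(fit, group, v))$eta)
  }
  structure(list(group = group, f = f, domain = domain, limits = limits),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Growth curve for '%s' over [%.4g, %.4g] mm^3\n",
              x$group, x$domain[1L], x$domain[2L]))
  invisible(x)
}

#' Predicted growth at the mean-sized snail
#'
#' @param fit a \code{\link{fit_growth}} result.
#' @param group group code.
#' @param mean_size initial volume (mm^3) at which to evaluate; defaults to
#'   the mean initial volume of the fitted records.
#' @return expected growth in mm^3.
#' @export
growth_at_mean_size <- function(fit, group, mean_size = NULL) {
  if (is.null(mean_size)) mean_size <- fit$mean_initial_volume
  growth_curve(fit, group)$f(mean_size)
}

#' Default integration limits: per-group extremes averaged across groups
#'
#' @param fit a \code{\link{fit_growth}} result.
#' @return numeric c(vmin, vmax).
#' @export
default_integration_limits <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  c(mean(fit$group_ranges[, 1L]), mean(fit$group_ranges[, 2L]))
}

#' Total growth allocation: area under a growth curve
#'
#' The definite integral of the size-specific growth curve between common
#' limits (by default the minimum- and maximum-sized snail averaged across
#' groups), by adaptive quadrature.
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param vmin,vmax integration limits in mm^3; \code{vmin < vmax}.
#' @return the integral (mm^3 growth x mm^3 size range).
#' @export
total_growth_allocation <- function(curve, vmin, vmax) {
  stopifnot(inherits(curve, "growth_curve"))
  if (vmin >= vmax) stop("integration limits inverted: vmin must be < vmax")
  scale <- max(abs(curve$f(c(vmin, vmax))))
  stats::integrate(function(v) curve$f(v), vmin, vmax,
                   abs.tol = 1e-8 * max(scale, 1),
                   subdivisions = 200L)$value
}

#' All pairwise group contrasts of predicted growth
#'
#' Wald contrasts of the linear predictor (log scale) between every pair
#' of groups at a common initial size, at the standardization reference,
#' with Benjamini-Hochberg control of the false discovery rate.
#'
#' @param fit a \code{\link{fit_growth}} result.
#' @param at_size initial volume (mm^3); defaults to the mean initial
#'   volume of the fitted records.
#' @param fdr_level false discovery rate for the adjusted significance
#'   calls (default 0.05).
#' @return a data.frame with one row per unordered pair: the log-scale
#'   difference, its standard error, Wald z, raw two-tailed p, BH-adjusted
#'   p and the significance call at \code{fdr_level}.
#' @export
pairwise_contrasts <- function(fit, at_size = NULL, fdr_level = 0.05) {
  stopifnot(inherits(fit, "growth_fit"))
  groups <- fit$group_levels
  if (length(groups) < 2L) stop("need at least 2 groups for contrasts")
  if (is.null(at_size)) at_size <- fit$mean_initial_volume
  pe <- .predict_eta(fit, .reference_newdata(fit, groups, at_size))
  V <- stats::vcov(fit$glm)
  V <- V[colnames(pe$X), colnames(pe$X)]
  pairs <- utils::combn(seq_along(groups), 2L)
  est <- se <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    cvec <- pe$X[pairs[1L, k], ] - pe$X[pairs[2L, k], ]
    est[k] <- sum(cvec * pe$beta)
    se[k] <- sqrt(drop(cvec %*% V %*% cvec))
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(group1 = groups[pairs[1L, ]],
             group2 = groups[pairs[2L, ]],
             log_difference = est, se = se, z = z, p = p,
             p_bh = p_adj,
             significant_fdr = p_adj <= fdr_level,
             stringsAsFactors = FALSE)
}
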