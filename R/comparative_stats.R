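#' Randomization test for a Pearson correlation
#'
#' The observed Pearson r is compared with the null distribution obtained
#' by permuting \code{y}; the two-tailed p-value is
#' \eqn{(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(B + 1)}, so the smallest
#' attainable p is \eqn{1/(B+1)}.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no zero variance.
#' @param B number of permutations (the full analysis uses 100,000;
#'   smaller values trade resolution for time).
#' @param seed integer seed (required: every stochastic operation in this
#'   package takes an explicit seed).
#' @param permute \code{"y"} (default) permutes the raw y values;
#'   \code{"residuals"} permutes the residuals of y on x.
#' @return an object of class \code{"randomization_result"}: list with
#'   \code{statistic} (observed r), \code{p}, \code{B}, \code{seed},
#'   \code{n}.
#' @export
randomization_correlation <- function(x, y, B = 100000L, seed,
                                      permute = c("y", "residuals")) {
  permute <- match.arg(permute)
  stopifnot(length(x) == length(y), length(x) >= 3L, B >= 1L)
  if (missing(seed)) stop("an explicit seed is required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  r_obs <- stats::cor(x, y)
  set.seed(seed)
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  if (permute == "residuals") {
    res <- stats::resid(stats::lm(y ~ x))
    yhat <- stats::fitted(stats::lm(y ~ x))
    count <- 0L
    for (b in seq_len(B)) {
      yp <- yhat + res[sample.int(n)]
      if (abs(stats::cor(x, yp)) >= abs(r_obs) - 1e-12) count <- count + 1L
    }
  } else {
    ys <- (y - mean(y)) / stats::sd(y)
    denom <- n - 1
    count <- 0L
    thr <- abs(r_obs) - 1e-12
    for (b in seq_len(B)) {
      r_perm <- sum(xs * ys[sample.int(n)]) / denom
      if (abs(r_perm) >= thr) count <- count + 1L
    }
  }
  structure(list(statistic = r_obs, p = (1 + count) / (B + 1),
                 B = as.integer(B), seed = seed, n = n,
                 permute = permute),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("Randomization correlation: r = %.3f, p = %.4g (B = %d, two-tailed)\n",
              x$statistic, x$p, x$B))
  invisible(x)
}

#' Two-stage randomization of the reproduction-mortality association
#'
#' Because growth enters the denominator of relative reproductive
#' allocation (RRA), a strong growth-mortality correlation could produce a
#' spurious RRA-mortality association.  This guard permutes the growth
#' values across groups (stage 1), recomputes each pseudo-RRA from the
#' fixed gonadosomatic indices, and correlates the pseudo-RRA with the
#' (unpermuted) mortality values (stage 2).  The observed RRA-mortality
#' correlation is compared two-tailed against that compound null.  This
#' permutation scheme targets exactly the artifact of growth appearing in
#' the RRA denominator; it is this package's construction of the guard.
#'
#' @param growth per-group growth values (> 0).
#' @param mortality per-group differential mortality, aligned with
#'   \code{growth}.
#' @param gsi per-group gonadosomatic indices, aligned.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return a \code{"randomization_result"} whose statistic is the observed
#'   RRA-mortality Pearson r.
#' @export
two_stage_randomization <- function(growth, mortality, gsi, B = 100000L,
                                    seed) {
  stopifnot(length(growth) == length(mortality),
            length(growth) == length(gsi), length(growth) >= 3L)
  if (missing(seed)) stop("an explicit seed is required")
  if (any(growth <= 0)) stop("growth values must be positive")
  rra <- gsi / growth
  if (stats::sd(rra) == 0 || stats::sd(mortality) == 0)
    stop("correlation undefined: zero variance")
  r_obs <- stats::cor(rra, mortality)
  set.seed(seed)
  n <- length(growth)
  ms <- (mortality - mean(mortality)) / stats::sd(mortality)
  count <- 0L
  thr <- abs(r_obs) - 1e-12
  for (b in seq_len(B)) {
    pseudo <- gsi / growth[sample.int(n)]
    s <- stats::sd(pseudo)
    if (s == 0) next
    r_perm <- sum((pseudo - mean(pseudo)) / s * ms) / (n - 1)
    if (abs(r_perm) >= thr) count <- count + 1L
  }
  structure(list(statistic = r_obs, p = (1 + count) / (B + 1),
                 B = as.integer(B), seed = seed, n = n,
                 permute = "two-stage"),
            class = "randomization_result")
}

#' Standard major axis line
#'
#' The symmetric bivariate line fit: slope = sign(r) * sd(y)/sd(x),
#' intercept through the means.  Appropriate when both variables carry
#' error, as for the comparative species-level scatters.
#'
#' @param x,y numeric vectors (n >= 3, non-zero variances).
#' @return list of class \code{"sma_fit"}: \code{slope}, \code{intercept},
#'   \code{r}.
#' @export
sma_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("standard major axis undefined: zero variance")
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (r == 0) slope <- stats::sd(y) / stats::sd(x)  # sign convention: +
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r = r),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA: y = %.4g x + %.4g (r = %.3f)\n",
              x$slope, x$intercept, x$r))
  invisible(x)
}

#' Least-squares regression through the origin
#'
#' No-intercept regression, used to confirm relationships between
#' independent contrasts (which are defined only up to sign and have
#' expectation zero).  slope = sum(xy)/sum(x^2), df = n - 1, two-tailed t.
#'
#' @param x,y numeric vectors (n >= 2).
#' @return list with \code{slope}, \code{se}, \code{t}, \code{df},
#'   \code{p}.
#' @export
regression_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sxx <- sum(x^2)
  if (sxx == 0) stop("regression through origin undefined: sum(x^2) = 0")
  slope <- sum(x * y) / sxx
  n <- length(x)
  df <- n - 1L
  rss <- sum((y - slope * x)^2)
  se <- sqrt(rss / df / sxx)
  t <- if (se == 0) Inf * sign(slope) else slope / se
  list(slope = slope, se = se, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

#' Summarize growth and local mortality risk by site within groups
#'
#' Builds the site-level table consumed by \code{\link{plasticity_test}}:
#' mean individual growth per (group, site), together with the local
#' differential-mortality risk.  For a trematode species the local risk is
#' the site prevalence of its dominants; for uninfected snails it is the
#' overall site trematode prevalence (the risk of castration).
#'
#' @param records record table with \code{growth} (see
#'   \code{\link{prepare_growth_data}}).
#' @param h a \code{\link{dominance_hierarchy}}.
#' @return data.frame with \code{group}, \code{site}, \code{mean_growth},
#'   \code{risk}, \code{n}.
#' @export
site_growth_risk <- function(records, h) {
  if (!"growth" %in% names(records))
    records <- prepare_growth_data(records)
  rec <- records[!is.na(records$growth) & !is.na(records$group) &
                   !is.na(records$infection) &
                   records$group != "mixed", , drop = FALSE]
  tabs <- build_site_tables(records)
  risk_of <- function(group, site) {
    tab <- tabs[[site]]
    combo_sp <- .combo_species(tab)
    if (group %in% c("male", "female")) {
      sum(tab$combos) / tab$n
    } else {
      doms <- dominants_of(h, group)
      has_dom <- vapply(combo_sp, function(s) any(s %in% doms), logical(1L))
      sum(tab$combos[has_dom]) / tab$n
    }
  }
  agg <- do.call(rbind, lapply(split(rec, list(rec$group, rec$site),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1L], site = d$site[1L],
               mean_growth = mean(d$growth),
               risk = risk_of(d$group[1L], d$site[1L]),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Do species respond plastically to local mortality risk?
#'
#' Tests whether, within species, site-mean growth declines with the local
#' risk of being killed (or castrated): a general linear model of site-mean
#' growth on group and group-specific risk slopes, reporting the joint F
#' for the group x risk slopes against the group-only model.  Groups
#' observed at fewer than two sites are dropped with a warning.
#'
#' @param site_table data.frame from \code{\link{site_growth_risk}} (or
#'   with the same columns).
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{groups} tested and both fitted models.
#' @export
plasticity_test <- function(site_table) {
  stopifnot(all(c("group", "site", "mean_growth", "risk") %in%
                  names(site_table)))
  n_sites <- table(site_table$group)
  drop <- names(n_sites)[n_sites < 2L]
  if (length(drop)) {
    warning("group(s) at a single site dropped: ",
            paste(drop, collapse = ", "))
    site_table <- site_table[!site_table$group %in% drop, , drop = FALSE]
  }
  if (nrow(site_table) == 0L) stop("no testable groups")
  site_table$group <- factor(site_table$group)
  full <- stats::lm(mean_growth ~ group + group:risk, data = site_table)
  null <- stats::lm(mean_growth ~ group, data = site_table)
  an <- stats::anova(null, full)
  list(F = an$F[2L], df1 = an$Df[2L], df2 = an$Res.Df[2L],
       p = an$`Pr(>F)`[2L],
       groups = levels(site_table$group), full = full, null = null)
}
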