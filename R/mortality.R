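#' Tabulate infections per site
#'
#' Collapses a record table into per-site summaries: the count of every
#' observed infection combination (single and mixed), and uninfected counts
#' by gender.  These tables feed the differential-mortality estimator and
#' the castration-risk calculation.
#'
#' @param records record data.frame with \code{site}, \code{infection} and
#'   \code{gender} columns; rows with undetermined infection are dropped.
#' @return a list of per-site tables (class \code{"site_infection_table"}),
#'   each with \code{site}, \code{n}, \code{combos} (named counts of
#'   infection combinations, species codes joined by \code{"+"}),
#'   and \code{uninfected} (named counts by gender).
#' @export
build_site_tables <- function(records) {
  rec <- records[!is.na(records$infection), , drop = FALSE]
  lapply(split(rec, rec$site), function(d) {
    inf <- d$infection[d$infection != "none"]
    combos <- table(inf)
    un <- d[d$infection == "none", , drop = FALSE]
    structure(list(site = d$site[1L],
                   n = nrow(d),
                   combos = stats::setNames(as.integer(combos),
                                            names(combos)),
                   uninfected = table(factor(un$gender,
                                             levels = c("male", "female")))),
              class = "site_infection_table")
  })
}

# species present in each observed combo, as a list of character vectors
.combo_species <- function(tab) strsplit(names(tab$combos), "+", fixed = TRUE)

#' Differential extrinsic mortality at one site
#'
#' The estimator transfers the focal species' prevalence among
#' "dominant-free" snails (snails carrying no species that dominates the
#' focal) onto the portion of the population carrying a dominant.  That
#' expected number of doomed recruits, minus any co-infections with
#' dominants actually observed, is the estimated kill count; dividing by
#' the total estimated recruitment (observed dominant-free infections plus
#' the expected doomed recruits) gives the proportion of the species'
#' recruits killed by dominants.  Negative values indicate facilitation
#' (co-occurrence above chance).
#'
#' @param table a \code{\link{build_site_tables}} element.
#' @param h a \code{\link{dominance_hierarchy}}.
#' @param focal focal species code.
#' @return the site-level mortality proportion, or \code{NA} (with a
#'   warning) when the site is unusable (no dominant-free snails, or zero
#'   estimated recruitment).
#' @export
site_mortality <- function(table, h, focal) {
  stopifnot(inherits(table, "site_infection_table"),
            inherits(h, "dominance_hierarchy"))
  doms <- dominants_of(h, focal)
  combo_sp <- .combo_species(table)
  counts <- table$combos
  has_focal <- vapply(combo_sp, function(s) focal %in% s, logical(1L))
  has_dom <- vapply(combo_sp, function(s) any(s %in% doms), logical(1L))

  n_uninf <- sum(table$uninfected)
  n_domfree <- n_uninf + sum(counts[!has_dom])
  if (n_domfree == 0) {
    warning("site ", table$site, ": no dominant-free snails; skipped")
    return(NA_real_)
  }
  focal_domfree <- sum(counts[has_focal & !has_dom])
  p <- focal_domfree / n_domfree
  n_with_dom <- sum(counts[has_dom])
  expected_doomed <- p * n_with_dom
  observed_co <- sum(counts[has_focal & has_dom])
  killed <- expected_doomed - observed_co
  recruits <- focal_domfree + expected_doomed
  if (recruits == 0) {
    warning("site ", table$site, ": zero estimated recruitment for ",
            focal, "; skipped")
    return(NA_real_)
  }
  # a species cannot lose more than all of its recruits: proportions are
  # truncated to [-1, 1] (values below -1 can only arise from sampling
  # noise in extreme facilitation tables)
  max(min(killed / recruits, 1), -1)
}

#' Prevalence-weighted pooled differential mortality
#'
#' Site-level estimates are averaged across the sites at which the focal
#' species occurs, weighting by the species' observed prevalence at each
#' site.
#'
#' @param tables list of site tables from \code{\link{build_site_tables}}.
#' @param h a \code{\link{dominance_hierarchy}}.
#' @param focal focal species code.
#' @return an object of class \code{"mortality_estimate"}: a list with
#'   \code{species}, \code{pooled} (the weighted mean), \code{per_site}
#'   (data.frame of site, mortality, weight), and \code{n_sites}.
#' @export
pooled_mortality <- function(tables, h, focal) {
  per <- lapply(tables, function(tab) {
    combo_sp <- .combo_species(tab)
    has_focal <- vapply(combo_sp, function(s) focal %in% s, logical(1L))
    n_focal <- sum(tab$combos[has_focal])
    if (n_focal == 0) return(NULL)           # species absent at this site
    data.frame(site = tab$site,
               mortality = site_mortality(tab, h, focal),
               weight = n_focal / tab$n,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L)
    stop("species '", focal, "' occurs at no site")
  usable <- !is.na(per$mortality)
  if (!any(usable)) stop("no usable site for species '", focal, "'")
  if (sum(per$weight[usable]) == 0)
    stop("all prevalence weights zero for species '", focal, "'")
  pooled <- stats::weighted.mean(per$mortality[usable], per$weight[usable])
  structure(list(species = focal, pooled = pooled, per_site = per,
                 n_sites = sum(usable)),
            class = "mortality_estimate")
}

#' @export
print.mortality_estimate <- function(x, ...) {
  cat(sprintf("Differential mortality for '%s': %.3f over %d sites\n",
              x$species, x$pooled, x$n_sites))
  invisible(x)
}

#' Differential mortality for every species in a dataset
#'
#' @param records record table (or a list of site tables).
#' @param h a \code{\link{dominance_hierarchy}}.
#' @param species species codes to estimate; defaults to every single-
#'   species infection observed.
#' @param include_uninfected if TRUE (default), append castration risk for
#'   uninfected \code{male} and \code{female} snails as their differential
#'   mortality.
#' @return data.frame with columns \code{group}, \code{differential_mortality},
#'   \code{n_sites}.
#' @export
mortality_table <- function(records, h, species = NULL,
                            include_uninfected = TRUE) {
  is_rec <- is.data.frame(records)
  tables <- if (is_rec) build_site_tables(records) else records
  if (is.null(species)) {
    seen <- unique(unlist(lapply(tables, function(t)
      unlist(.combo_species(t)))))
    species <- intersect(h$species, seen)
  }
  rows <- lapply(species, function(s) {
    est <- pooled_mortality(tables, h, s)
    data.frame(group = s, differential_mortality = est$pooled,
               n_sites = est$n_sites, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_uninfected) {
    if (!is_rec)
      stop("include_uninfected requires the record data.frame")
    for (g in c("male", "female")) {
      risk <- tryCatch(castration_risk(records, g), error = function(e) NA)
      out <- rbind(out, data.frame(group = g, differential_mortality = risk,
                                   n_sites = length(tables),
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Castration risk for uninfected snails
#'
#' The differential "mortality" of uninfected snails is reproductive death
#' by castration: the gender-specific trematode prevalence, averaged
#' (unweighted, by default) across sites.
#'
#' @param tables list of site tables from \code{\link{build_site_tables}},
#'   built from records whose infected snails carry a gender, or a record
#'   data.frame.
#' @param gender \code{"male"} or \code{"female"}.
#' @param weighted if TRUE, weight sites by their snail count of that
#'   gender instead of averaging unweighted.
#' @return the mean castration risk (proportion).
#' @export
castration_risk <- function(tables, gender = c("male", "female"),
                            weighted = FALSE) {
  gender <- match.arg(gender)
  if (is.data.frame(tables)) {
    rec <- tables
  } else {
    stop("castration_risk requires the record data.frame ",
         "(gender of infected snails is needed)")
  }
  rec <- rec[!is.na(rec$infection) & !is.na(rec$gender) &
               rec$gender == gender, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no snails of gender '", gender, "'")
  per <- vapply(split(rec, rec$site), function(d)
    c(prev = mean(d$infection != "none"), n = nrow(d)), numeric(2L))
  if (weighted) stats::weighted.mean(per["prev", ], per["n", ])
  else mean(per["prev", ])
}

#' Gender difference in susceptibility to infection
#'
#' Logistic regression of infection status on gender, controlling for
#' site, growing time and initial size, with a likelihood-ratio chi-square
#' for the gender term.
#'
#' @param records record table; rows with undetermined gender, infection
#'   or size are dropped.  Mixed infections count as infected.
#' @return list with the fitted \code{glm}, \code{chisq}, \code{df} (1) and
#'   \code{p} for the gender term, and \code{n}.
#' @export
gender_susceptibility_test <- function(records) {
  if (!"initial_volume" %in% names(records))
    records <- prepare_growth_data(records)
  dat <- records[!is.na(records$gender) & !is.na(records$infection) &
                   !is.na(records$initial_volume), , drop = FALSE]
  dat$infected <- as.integer(dat$infection != "none")
  if (length(unique(dat$gender)) < 2L || length(unique(dat$infected)) < 2L)
    stop("need both genders and both infection states")
  dat$site <- factor(dat$site)
  dat$period <- factor(dat$period)
  rhs <- "gender"
  if (nlevels(dat$site) > 1L) rhs <- c(rhs, "site")
  if (nlevels(dat$period) > 1L) rhs <- c(rhs, "period")
  rhs <- c(rhs, "initial_volume")
  full <- stats::glm(stats::as.formula(
    paste("infected ~", paste(rhs, collapse = " + "))),
    family = stats::binomial(), data = dat)
  null <- stats::update(full, . ~ . - gender)
  chisq <- null$deviance - full$deviance
  df <- null$df.residual - full$df.residual
  list(fit = full, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       coefficient = stats::coef(full)[["gendermale"]],
       n = nrow(dat))
}
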