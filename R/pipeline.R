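#' Record-exclusion filter chain
#'
#' Applies the analysis' exclusion rules in order, each record receiving the
#' first matching disposition: (1) mixed-species infections; (2) records
#' with undetermined initial size, gender or infection status; (3) flagged
#' growth outliers; (4) infections by rare species, i.e. any trematode
#' species with \code{min_group_n} or fewer retained individuals (the
#' threshold is strict: a species needs more than \code{min_group_n}
#' individuals to stay).  Uninfected males and females are never
#' rare-filtered.
#'
#' @param records record data.frame.
#' @param min_group_n rare-species threshold (default 20; "over 20" is
#'   read strictly, so a species with exactly 20 is excluded).
#' @param outlier_rule \code{"flagged"} (default) uses the
#'   \code{is_outlier} column; \code{"deviance"} flags records with
#'   absolute Studentized deviance residual above \code{deviance_cutoff}
#'   in a preliminary quasi-Poisson fit.
#' @param deviance_cutoff cutoff for the deviance rule (default 4).
#' @return list of class \code{"filter_result"} with \code{records} (the
#'   retained rows) and \code{report} (a \code{"filter_report"}: input
#'   count, per-rule exclusion counts, retained count, per-group retained
#'   sizes, and the rule used).
#' @export
apply_filters <- function(records, min_group_n = 20L,
                          outlier_rule = c("flagged", "deviance"),
                          deviance_cutoff = 4) {
  outlier_rule <- match.arg(outlier_rule)
  n_in <- nrow(records)
  disposition <- rep("retained", n_in)

  mixed <- !is.na(records$infection) &
    grepl("+", records$infection, fixed = TRUE)
  disposition[mixed] <- "mixed"

  undet <- is.na(records$infection) | is.na(records$gender) |
    is.na(records$initial_length) | is.na(records$initial_width)
  disposition[disposition == "retained" & undet] <- "undetermined"

  if (outlier_rule == "flagged") {
    out_flag <- !is.na(records$is_outlier) & records$is_outlier
  } else {
    cand <- disposition == "retained"
    out_flag <- rep(FALSE, n_in)
    if (sum(cand) > 1L) {
      pre <- records[cand, , drop = FALSE]
      if (!"growth" %in% names(pre)) pre <- prepare_growth_data(pre)
      pre$group <- factor(pre$group)
      form <- if (nlevels(pre$group) > 1L) growth ~ group else growth ~ 1
      fit <- stats::glm(form, family = stats::quasipoisson(), data = pre)
      rs <- stats::rstudent(fit)
      out_flag[cand] <- abs(rs) > deviance_cutoff
    }
  }
  disposition[disposition == "retained" & out_flag] <- "outlier"

  # rare-species rule on what survives the earlier rules
  is_species <- !is.na(records$group) &
    !records$group %in% c("male", "female", "mixed")
  retained_sp <- table(records$group[disposition == "retained" & is_species])
  rare_sp <- names(retained_sp)[retained_sp <= min_group_n]
  disposition[disposition == "retained" & is_species &
                records$group %in% rare_sp] <- "rare"

  retained <- records[disposition == "retained", , drop = FALSE]
  report <- structure(list(
    input = n_in,
    excluded = c(mixed = sum(disposition == "mixed"),
                 undetermined = sum(disposition == "undetermined"),
                 outlier = sum(disposition == "outlier"),
                 rare = sum(disposition == "rare")),
    retained = nrow(retained),
    rare_species = rare_sp,
    group_sizes = table(retained$group),
    outlier_rule = outlier_rule,
    min_group_n = min_group_n), class = "filter_report")
  structure(list(records = retained, report = report,
                 disposition = disposition),
            class = "filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d records in, %d retained\n",
              x$input, x$retained))
  cat(sprintf("  excluded: %d mixed, %d undetermined, %d outlier, %d rare (rule: %s, threshold > %d)\n",
              x$excluded[["mixed"]], x$excluded[["undetermined"]],
              x$excluded[["outlier"]], x$excluded[["rare"]],
              x$outlier_rule, x$min_group_n))
  invisible(x)
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

# stable hash of the configuration for the run manifest
.config_hash <- function(config) {
  txt <- yaml::as.yaml(list(species = config$species,
                            edges = config$hierarchy$edges,
                            n_per_site = config$n_per_site,
                            seed = config$seed))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full comparative pipeline
#'
#' Orchestrates the analysis end to end: generate (or accept) records,
#' filter, derive shell volumes, fit the quasi-Poisson growth model,
#' integrate growth curves, estimate differential mortality, assemble the
#' allocation table, run the species-level and contrast-level
#' growth-mortality and reproduction-mortality randomization tests (with a
#' configurable group drop-list for robustness re-runs), the two-stage
#' guard, and the plasticity F-test.  Returns every intermediate table and
#' a reproducible run manifest.
#'
#' @param world a \code{\link{generate_world}} result, or a record
#'   data.frame plus \code{hierarchy} and \code{gsi}.
#' @param hierarchy dominance hierarchy (defaults to the world's).
#' @param gsi named vector of gonadosomatic indices (defaults to the
#'   world's configuration).
#' @param tree optional \code{phylo} tree over the group codes for the
#'   contrast-level analyses.
#' @param B randomization iterations (default 10,000; the full analysis
#'   standard is 100,000).
#' @param seed integer seed for the randomization tests.
#' @param drop_groups optional character vector of groups excluded from
#'   the comparative correlations (e.g. \code{c("male", "female")}).
#' @param min_group_n rare-species filter threshold.
#' @param out_dir optional directory; when given, tables and the JSON
#'   manifest are written there.
#' @return list of class \code{"pipeline_result"}: \code{filter},
#'   \code{fit}, \code{mortality}, \code{allocation},
#'   \code{tests} (tidy data.frame: test, statistic, df, p, B, seed),
#'   \code{contrasts} (when a tree is given), \code{manifest}.
#' @export
run_pipeline <- function(world, hierarchy = NULL, gsi = NULL, tree = NULL,
                         B = 10000L, seed = 1L, drop_groups = NULL,
                         min_group_n = 20L, out_dir = NULL) {
  if (inherits(world, "synthetic_world")) {
    records <- world$records
    if (is.null(hierarchy)) hierarchy <- world$config$hierarchy
    if (is.null(gsi)) gsi <- world$config$gsi
    config <- world$config
  } else {
    records <- world
    config <- NULL
    if (is.null(hierarchy) || is.null(gsi))
      stop("hierarchy and gsi are required when records are supplied directly")
  }

  records <- prepare_growth_data(records)
  filt <- apply_filters(records, min_group_n = min_group_n)
  dat <- filt$records

  fit <- fit_growth(dat)
  mort <- mortality_table(dat, hierarchy)
  alloc <- build_allocation_table(fit, mort, gsi)

  use <- if (is.null(drop_groups)) alloc
         else alloc[!alloc$group %in% drop_groups, , drop = FALSE]
  if (nrow(use) < 3L) stop("fewer than 3 groups left for correlations")

  gm <- randomization_correlation(use$total_growth_allocation,
                                  use$differential_mortality,
                                  B = B, seed = seed)
  rm_ <- randomization_correlation(use$rra, use$differential_mortality,
                                   B = B, seed = seed + 1L)
  gsim <- randomization_correlation(use$gsi, use$differential_mortality,
                                    B = B, seed = seed + 2L)
  guard <- two_stage_randomization(use$growth_at_mean,
                                   use$differential_mortality, use$gsi,
                                   B = B, seed = seed + 3L)
  sgr <- site_growth_risk(dat, hierarchy)
  plast <- tryCatch(plasticity_test(sgr), error = function(e) NULL)

  tests <- data.frame(
    test = c("growth_vs_mortality", "rra_vs_mortality", "gsi_vs_mortality",
             "two_stage_rra_vs_mortality"),
    statistic = c(gm$statistic, rm_$statistic, gsim$statistic,
                  guard$statistic),
    df = NA_real_,
    p = c(gm$p, rm_$p, gsim$p, guard$p),
    B = B, seed = c(seed, seed + 1L, seed + 2L, seed + 3L),
    stringsAsFactors = FALSE)
  if (!is.null(plast))
    tests <- rbind(tests, data.frame(
      test = "plasticity_F", statistic = plast$F, df = plast$df1,
      p = plast$p, B = NA_integer_, seed = NA_integer_))

  contrasts <- NULL
  if (!is.null(tree)) {
    tips <- tree$tip.label
    if (all(tips %in% use$group)) {
      tx <- stats::setNames(use$total_growth_allocation, use$group)[tips]
      ty <- stats::setNames(use$differential_mortality, use$group)[tips]
      tr <- stats::setNames(use$rra, use$group)[tips]
      cg <- contrast_correlation(tree, ty, tx, B = B, seed = seed + 4L)
      cr <- contrast_correlation(tree, ty, tr, B = B, seed = seed + 5L)
      contrasts <- list(growth_vs_mortality = cg, rra_vs_mortality = cr)
      tests <- rbind(tests, data.frame(
        test = c("contrast_growth_vs_mortality", "contrast_rra_vs_mortality"),
        statistic = c(cg$correlation$statistic, cr$correlation$statistic),
        df = c(cg$origin$df, cr$origin$df),
        p = c(cg$correlation$p, cr$correlation$p),
        B = B, seed = c(seed + 4L, seed + 5L)))
    } else {
      warning("tree tips not all present among analysed groups; ",
              "contrast analyses skipped")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("castguild")),
    config_hash = if (!is.null(config)) .config_hash(config) else NA,
    seeds = list(pipeline = seed,
                 world = if (inherits(world, "synthetic_world"))
                   world$seed else NA),
    counts = list(input = filt$report$input,
                  retained = filt$report$retained,
                  excluded = as.list(filt$report$excluded),
                  groups_analysed = nrow(use)),
    dispersion = fit$dispersion,
    tests = tests)

  res <- structure(list(filter = filt, fit = fit, mortality = mort,
                        allocation = alloc, tests = tests,
                        contrasts = contrasts, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$filter$report)
  cat(sprintf("Growth model dispersion: %.2f\n", x$fit$dispersion))
  cat("Comparative tests:\n")
  print(transform(x$tests, statistic = signif(statistic, 3),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Write pipeline output tables and the JSON manifest
#'
#' @param result a \code{\link{run_pipeline}} result.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$allocation,
                   file.path(out_dir, "allocation_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$mortality,
                   file.path(out_dir, "mortality_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$fit$terms,
                   file.path(out_dir, "growth_model_terms.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a per-group gonadosomatic index table
#'
#' Two delimited columns, \code{group} and \code{gsi} (fractions).  A
#' missing species may be proxied by a named relative via the optional
#' \code{proxy_for} column (proxying is explicit, never silent: proxied
#' rows are reported in a message).
#'
#' @param path delimited text file with a header.
#' @param sep separator (default comma).
#' @return named numeric vector of indices.
#' @export
read_gsi_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("group", "gsi") %in% names(tab)))
  if ("proxy_for" %in% names(tab)) {
    pr <- tab[!is.na(tab$proxy_for) & nzchar(tab$proxy_for), , drop = FALSE]
    if (nrow(pr)) {
      message("GSI proxied: ",
              paste(sprintf("%s <- %s", pr$group, pr$proxy_for),
                    collapse = ", "))
    }
  }
  if (anyDuplicated(tab$group)) stop("duplicate group codes in GSI table")
  stats::setNames(tab$gsi, tab$group)
}
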