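#' Configuration for a synthetic castrator-guild world
#'
#' Bundles everything the generator needs: the castrator species codes and
#' their within-host dominance hierarchy, the site layout (sites nested in
#' estuaries, with habitat labels), per-(site, species) recruitment
#' prevalences, per-group growth parameters on the log scale with a
#' multiplicative overdispersion factor, per-group gonadosomatic indices,
#' and the growing-time structure (days per recapture period, per estuary).
#'
#' Growth parameters are interpreted as
#' \eqn{\log E[\mathrm{growth}] = \mathrm{intercept} + \mathrm{slope}\cdot V_0
#' + \mathrm{site\ effect} + \log(\mathrm{days}/\mathrm{ref\_days})}
#' with \eqn{V_0} the initial shell volume in mm^3.
#'
#' @param species character vector of castrator species codes.
#' @param hierarchy a \code{\link{dominance_hierarchy}} over \code{species}.
#' @param sites data.frame with columns \code{site}, \code{estuary},
#'   \code{habitat}; one row per site.
#' @param prevalence numeric matrix, rows = sites (rownames = site ids),
#'   columns = species; recruitment probabilities in [0, 1].
#' @param growth_params data.frame with columns \code{group} (the species
#'   codes plus \code{"male"} and \code{"female"}), \code{intercept},
#'   \code{slope}, \code{dispersion} (>= 1).
#' @param gsi named numeric vector of reproductive-tissue mass fractions in
#'   (0, 1), one per group.
#' @param site_effects named numeric vector of fixed log-scale site effects
#'   (default all zero).
#' @param periods data.frame with columns \code{estuary}, \code{period},
#'   \code{days}, \code{prob}: the recapture periods available per estuary,
#'   their growing days, and the probability a snail belongs to each.
#' @param n_per_site snails generated per site.
#' @param length_range range of initial shell lengths (mm) sampled uniformly.
#' @param width_ratio shell width as a fraction of length.
#' @param scaling a \code{\link{scaling_relation}}.
#' @param ref_days growing days to which growth intercepts refer.
#' @param male_susceptibility odds ratio applied to every species'
#'   recruitment probability for male snails (1 = no gender difference).
#' @param seed default integer seed used by \code{\link{generate_world}}.
#' @return an object of class \code{"world_config"}.
#' @seealso \code{\link{default_world_config}}, \code{\link{generate_world}}
#' @export
world_config <- function(species, hierarchy, sites, prevalence,
                         growth_params, gsi,
                         site_effects = NULL,
                         periods = NULL,
                         n_per_site = 114L,
                         length_range = c(8, 43),
                         width_ratio = 0.364,
                         scaling = scaling_relation(),
                         ref_days = 94,
                         male_susceptibility = 1,
                         seed = 1L) {
  stopifnot(is.character(species), length(species) >= 1L,
            inherits(hierarchy, "dominance_hierarchy"),
            is.data.frame(sites),
            all(c("site", "estuary", "habitat") %in% names(sites)),
            is.matrix(prevalence),
            is.data.frame(growth_params),
            all(c("group", "intercept", "slope", "dispersion") %in%
                  names(growth_params)))
  extra <- setdiff(hierarchy$species, species)
  if (length(extra))
    stop("hierarchy names species absent from config: ",
         paste(extra, collapse = ", "))
  if (anyDuplicated(sites$site))
    stop("duplicate site ids")
  if (is.null(rownames(prevalence))) rownames(prevalence) <- sites$site
  if (is.null(colnames(prevalence))) colnames(prevalence) <- species
  if (!setequal(rownames(prevalence), sites$site) ||
      !setequal(colnames(prevalence), species))
    stop("prevalence matrix must be sites x species")
  prevalence <- prevalence[sites$site, species, drop = FALSE]
  if (any(prevalence < 0 | prevalence > 1))
    stop("recruitment prevalences must lie in [0, 1]")
  groups <- c(species, "male", "female")
  if (!setequal(growth_params$group, groups))
    stop("growth_params must cover every species plus 'male' and 'female'")
  if (any(growth_params$dispersion < 1))
    stop("overdispersion factor must be >= 1")
  if (!setequal(names(gsi), groups) || any(gsi <= 0 | gsi >= 1))
    stop("gsi must be a named vector over all groups with values in (0, 1)")
  if (is.null(site_effects))
    site_effects <- stats::setNames(rep(0, nrow(sites)), sites$site)
  if (!setequal(names(site_effects), sites$site))
    stop("site_effects must be named by site id")
  if (is.null(periods))
    periods <- data.frame(estuary = unique(sites$estuary), period = "1",
                          days = ref_days, prob = 1,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("estuary", "period", "days", "prob") %in% names(periods)))
  if (n_per_site < 1L) stop("n_per_site must be a positive integer")
  if (male_susceptibility <= 0) stop("male_susceptibility must be > 0")
  structure(list(species = species, hierarchy = hierarchy, sites = sites,
                 prevalence = prevalence, growth_params = growth_params,
                 gsi = gsi, site_effects = site_effects, periods = periods,
                 n_per_site = as.integer(n_per_site),
                 length_range = length_range, width_ratio = width_ratio,
                 scaling = scaling, ref_days = ref_days,
                 male_susceptibility = male_susceptibility,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf(
    "World config: %d castrator species, %d sites in %d estuaries, %d snails/site\n",
    length(x$species), nrow(x$sites), length(unique(x$sites$estuary)),
    x$n_per_site))
  invisible(x)
}

#' Default synthetic world mirroring the field study's structure
#'
#' Eight castrator species plus uninfected males and females; 17 sites in
#' three estuaries (creek and pan habitats); two growing periods in the two
#' southern estuaries; a strict linear dominance order with two built-in
#' exceptions: a tissue-refuge species (\code{renc}) tolerated by all but
#' the top-ranked species, and a spatially segregated species (\code{smcy})
#' recruiting mainly where dominants are rare.  Growth decreases, and the
#' gonadosomatic index increases, with a species' expected mortality, so
#' generated worlds carry a negative growth-mortality and a positive
#' reproduction-mortality coupling by construction.
#'
#' @param n_per_site snails per site (default 114).
#' @param seed default generator seed.
#' @param dispersion overdispersion factor applied to every group
#'   (default 4).
#' @param male_susceptibility odds ratio for male recruitment (default 1).
#' @return a \code{\link{world_config}}.
#' @export
default_world_config <- function(n_per_site = 114L, seed = 1L,
                                 dispersion = 4,
                                 male_susceptibility = 1) {
  species <- c("hima", "euha", "cloa", "acan", "prob", "stic", "renc", "smcy")
  rank <- c("hima", "euha", "cloa", "acan", "prob", "stic", "renc", "smcy")
  edges <- do.call(rbind, lapply(seq_along(rank)[-length(rank)], function(i) {
    data.frame(killer = rank[i], victim = rank[(i + 1):length(rank)],
               stringsAsFactors = FALSE)
  }))
  # tissue refuge: renc is killed only by the top-ranked species
  edges <- edges[!(edges$victim == "renc" & edges$killer != "hima"), ]
  h <- dominance_hierarchy(edges, species = species)

  sites <- data.frame(
    site = c(paste0("csm", 1:7), paste0("lpl", 1:6), paste0("tje", 1:4)),
    estuary = c(rep("CSM", 7), rep("LPL", 6), rep("TJE", 4)),
    habitat = c(rep("creek", 3), rep("pan", 4), rep("creek", 10)),
    stringsAsFactors = FALSE)

  base_prev <- c(hima = 0.08, euha = 0.12, cloa = 0.06, acan = 0.05,
                 prob = 0.05, stic = 0.04, renc = 0.04, smcy = 0)
  prev <- matrix(rep(base_prev, each = nrow(sites)), nrow = nrow(sites),
                 dimnames = list(sites$site, species))
  # mild deterministic site-to-site variation in prevalence
  prev <- prev * seq(0.7, 1.3, length.out = nrow(sites))
  # spatial refuge: smcy recruits at TJE, where dominants are scarce
  tje <- sites$estuary == "TJE"
  prev[tje, ] <- matrix(rep(c(hima = 0.01, euha = 0.02, cloa = 0.01,
                              acan = 0.01, prob = 0.01, stic = 0.01,
                              renc = 0.02, smcy = 0.25), each = sum(tje)),
                        nrow = sum(tje))

  groups <- c(species, "male", "female")
  growth_at_mean <- c(hima = 48, euha = 38, cloa = 24, acan = 19, prob = 15,
                      stic = 12, renc = 40, smcy = 44, male = 7, female = 9)
  slope <- -6e-4
  mean_v0 <- 705
  gp <- data.frame(group = groups,
                   intercept = log(growth_at_mean[groups]) - slope * mean_v0,
                   slope = slope,
                   dispersion = dispersion,
                   stringsAsFactors = FALSE)
  rownames(gp) <- NULL

  gsi <- c(hima = 0.10, euha = 0.13, cloa = 0.18, acan = 0.21, prob = 0.24,
           stic = 0.27, renc = 0.12, smcy = 0.11,
           male = 0.146, female = 0.149)

  site_eff <- stats::setNames(seq(-0.25, 0.25, length.out = nrow(sites)),
                              sites$site)

  periods <- rbind(
    data.frame(estuary = "CSM", period = "1", days = 94, prob = 1),
    data.frame(estuary = c("LPL", "LPL"), period = c("1", "2"),
               days = c(94, 154), prob = c(2 / 3, 1 / 3)),
    data.frame(estuary = c("TJE", "TJE"), period = c("1", "2"),
               days = c(94, 154), prob = c(2 / 3, 1 / 3)))

  world_config(species = species, hierarchy = h, sites = sites,
               prevalence = prev, growth_params = gp, gsi = gsi,
               site_effects = site_eff, periods = periods,
               n_per_site = n_per_site, seed = seed,
               male_susceptibility = male_susceptibility)
}

# draw from a gamma-mixed Poisson with mean mu and variance phi * mu
.rquasipois <- function(n, mu, phi) {
  if (length(phi) == 1L) phi <- rep(phi, n)
  lam <- mu
  over <- phi > 1 & mu > 0
  if (any(over)) {
    shape <- mu[over] / (phi[over] - 1)
    lam[over] <- stats::rgamma(sum(over), shape = shape,
                               rate = 1 / (phi[over] - 1))
  }
  stats::rpois(n, lam)
}

#' Generate a synthetic mark-recapture world
#'
#' Each snail at each site independently acquires each trematode species
#' with the site-specific recruitment prevalence; within a host, every
#' recruited species dominated by any co-recruited species is killed.  A
#' snail with two or more surviving species is a mixed-species infection;
#' snails with none are uninfected males or females.  Observed growth is
#' drawn from a gamma-mixed Poisson (variance = dispersion x mean) whose
#' mean follows the group's log-linear size relation, scaled by growing
#' time, and shell degrees/width/length are back-computed from the growth
#' volume through the shell-geometry inverses.  The latent (pre-kill)
#' recruitment of every snail is retained, so the realized per-species kill
#' fraction is known exactly.
#'
#' @param config a \code{\link{world_config}}.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return an object of class \code{"synthetic_world"}: a list with
#'   \code{records} (one row per snail; the observed dataset),
#'   \code{latent_infections} (logical snails x species matrix of pre-kill
#'   recruitment), \code{true_mortality} (named vector: realized fraction of
#'   each species' recruits killed by dominants), \code{true_growth} (the
#'   generating growth parameters) and \code{config}.
#' @export
generate_world <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "world_config"))
  set.seed(seed)
  sites <- config$sites
  n_sites <- nrow(sites)
  n <- n_sites * config$n_per_site
  site <- rep(sites$site, each = config$n_per_site)
  estuary <- rep(sites$estuary, each = config$n_per_site)
  habitat <- rep(sites$habitat, each = config$n_per_site)
  sp <- config$species
  k <- length(sp)

  gender <- sample(c("male", "female"), n, replace = TRUE)

  # independent recruitment per species at site prevalence (the estimator's
  # core assumption holds by construction)
  prev <- config$prevalence[site, , drop = FALSE]
  if (config$male_susceptibility != 1) {
    m <- gender == "male"
    adj <- stats::plogis(stats::qlogis(pmin(pmax(prev[m, , drop = FALSE],
                                                 1e-12), 1 - 1e-12)) +
                           log(config$male_susceptibility))
    adj[prev[m, , drop = FALSE] == 0] <- 0
    prev[m, ] <- adj
  }
  recruited <- matrix(stats::runif(n * k) < prev, nrow = n,
                      dimnames = list(NULL, sp))

  # within-host killing: a recruit dies if any co-recruit dominates it
  surviving <- recruited
  for (s in sp) {
    doms <- dominants_of(config$hierarchy, s)
    if (length(doms))
      surviving[, s] <- recruited[, s] &
        rowSums(recruited[, doms, drop = FALSE]) == 0
  }
  n_surv <- rowSums(surviving)
  infection <- apply(surviving, 1L, function(z) {
    if (!any(z)) "none" else paste(sp[z], collapse = "+")
  })
  group <- ifelse(n_surv == 0L, gender,
                  ifelse(n_surv == 1L, infection, "mixed"))

  # growing period and days
  period <- character(n)
  days <- numeric(n)
  for (est in unique(sites$estuary)) {
    idx <- which(estuary == est)
    pd <- config$periods[config$periods$estuary == est, , drop = FALSE]
    pick <- sample.int(nrow(pd), length(idx), replace = TRUE,
                       prob = pd$prob)
    period[idx] <- pd$period[pick]
    days[idx] <- pd$days[pick]
  }

  # shell sizes
  initial_length <- stats::runif(n, config$length_range[1],
                                 config$length_range[2])
  initial_width <- config$width_ratio * initial_length
  v0 <- initial_volume(initial_length, initial_width)

  # growth: mixed snails grow under their top surviving species' parameters
  # (they are excluded from growth analyses anyway)
  gp <- config$growth_params
  grow_group <- group
  mixed <- group == "mixed"
  if (any(mixed)) {
    first_sp <- apply(surviving[mixed, , drop = FALSE], 1L,
                      function(z) sp[which(z)[1L]])
    grow_group[mixed] <- first_sp
  }
  gidx <- match(grow_group, gp$group)
  eta <- gp$intercept[gidx] + gp$slope[gidx] * v0 +
    config$site_effects[site] + log(days / config$ref_days)
  mu <- exp(eta)
  growth <- .rquasipois(n, mu, gp$dispersion[gidx])

  # invert the shell geometry so the raw measurements reproduce the volume
  v_scaled0 <- length_to_volume(initial_length, config$scaling)
  final_length <- volume_to_length(v_scaled0 + growth, config$scaling)
  final_width <- config$width_ratio * final_length
  degrees <- ifelse(growth == 0, 0,
                    growth / (pi * (final_width / 4)^2) * 360)

  records <- data.frame(
    snail_id = sprintf("sn%05d", seq_len(n)),
    estuary = estuary, site = site, habitat = habitat,
    period = period, growing_days = days,
    gender = gender, infection = infection, group = group,
    initial_length = round(initial_length, 1),
    initial_width = round(initial_width, 1),
    final_length = round(final_length, 1),
    final_width = round(final_width, 1),
    degrees_growth = degrees,
    is_outlier = FALSE,
    stringsAsFactors = FALSE)

  recruits <- colSums(recruited)
  killed <- colSums(recruited & !surviving)
  true_mortality <- ifelse(recruits > 0, killed / recruits, NA_real_)
  names(true_mortality) <- sp

  structure(list(records = records,
                 latent_infections = recruited,
                 true_mortality = true_mortality,
                 true_growth = gp,
                 config = config,
                 seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d snails at %d sites (seed %d)\n",
              nrow(x$records), length(unique(x$records$site)), x$seed))
  tm <- round(x$true_mortality, 3)
  cat("Realized differential mortality (latent truth):\n")
  print(tm)
  invisible(x)
}

#' Fixture dataset with fixed exclusion-category counts
#'
#' Builds a record table in which every record falls into exactly one
#' filter disposition, with the requested counts: \code{mixed} (mixed-
#' species infections), \code{outlier} (flagged growth outliers),
#' \code{undetermined} (missing size, gender or infection status),
#' \code{rare} (infections by rare species, each rare species given at most
#' 16 individuals), and \code{retained}.  Retained records are spread over
#' the eight castrator species plus uninfected males and females when the
#' total allows every species more than \code{min_group_n} individuals;
#' otherwise they are assigned to the uninfected groups, which are never
#' rare-filtered.
#'
#' @param counts named numeric vector or list with any of the names
#'   \code{mixed}, \code{outlier}, \code{undetermined}, \code{rare},
#'   \code{retained}; missing names count as zero.
#' @param min_group_n the rare-species threshold the records are built to
#'   respect (default 20).
#' @param seed integer seed for the deterministic measurement noise.
#' @return a record data.frame with \code{sum(counts)} rows.
#' @export
generate_fixture_counts <- function(counts, min_group_n = 20L, seed = 1L) {
  counts <- unlist(counts)
  full <- c(mixed = 0, outlier = 0, undetermined = 0, rare = 0, retained = 0)
  bad <- setdiff(names(counts), names(full))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  full[names(counts)] <- counts
  if (any(full < 0)) stop("category counts must be non-negative")
  n <- sum(full)
  if (n == 0) {
    return(.empty_records())
  }
  set.seed(seed)
  species <- c("hima", "euha", "cloa", "acan", "prob", "stic", "renc", "smcy")

  rows <- list()
  add <- function(k, infection, gender, outlier = FALSE,
                  undet = FALSE) {
    if (k == 0) return(invisible(NULL))
    len <- stats::runif(k, 10, 40)
    wid <- 0.364 * len
    deg <- stats::runif(k, 0, 720)
    rows[[length(rows) + 1L]] <<- data.frame(
      snail_id = NA_character_,
      estuary = "CSM", site = "csm1", habitat = "creek",
      period = "1", growing_days = 94,
      gender = if (undet) NA_character_ else gender,
      infection = infection, group = NA_character_,
      initial_length = if (undet) NA_real_ else round(len, 1),
      initial_width = if (undet) NA_real_ else round(wid, 1),
      final_length = round(len + 2, 1), final_width = round(wid + 1, 1),
      degrees_growth = if (outlier) 20000 else deg,
      is_outlier = outlier,
      stringsAsFactors = FALSE)
  }

  add(full[["mixed"]], "hima+euha", "female")
  add(full[["outlier"]], "hima", "male", outlier = TRUE)
  add(full[["undetermined"]], "none", NA_character_, undet = TRUE)

  if (full[["rare"]] > 0) {
    cap <- min(16L, min_group_n)
    n_rare_sp <- ceiling(full[["rare"]] / cap)
    per <- diff(round(seq(0, full[["rare"]], length.out = n_rare_sp + 1)))
    for (i in seq_along(per))
      add(per[i], sprintf("rare%02d", i), "female")
  }

  ret <- full[["retained"]]
  if (ret > 0) {
    if (ret >= 10 * (min_group_n + 1)) {
      per <- diff(round(seq(0, ret, length.out = 11)))
      grp <- c(species, "male", "female")
      inf <- c(species, "none", "none")
      gdr <- c(rep("female", 8), "male", "female")
      for (i in 1:10) add(per[i], inf[i], gdr[i])
    } else {
      half <- floor(ret / 2)
      add(half, "none", "male")
      add(ret - half, "none", "female")
    }
  }

  out <- do.call(rbind, rows)
  out$snail_id <- sprintf("fx%05d", seq_len(nrow(out)))
  uninf <- out$infection == "none" & !is.na(out$infection)
  single <- !uninf & !grepl("+", out$infection, fixed = TRUE)
  out$group <- ifelse(uninf, out$gender,
                      ifelse(single, out$infection, "mixed"))
  out$group[is.na(out$gender) & uninf] <- NA_character_
  rownames(out) <- NULL
  out
}

.empty_records <- function() {
  data.frame(snail_id = character(), estuary = character(),
             site = character(), habitat = character(), period = character(),
             growing_days = numeric(), gender = character(),
             infection = character(), group = character(),
             initial_length = numeric(), initial_width = numeric(),
             final_length = numeric(), final_width = numeric(),
             degrees_growth = numeric(), is_outlier = logical(),
             stringsAsFactors = FALSE)
}

#' Write or read the snail record table
#'
#' Records travel as comma-delimited UTF-8 text with a header row and "."
#' as the decimal mark; one row per snail.
#'
#' @param records a record data.frame.
#' @param path file path.
#' @return \code{read_snail_records} returns the record data.frame.
#' @export
write_snail_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_snail_records
#' @export
read_snail_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c("site", "estuary", "habitat", "growing_days", "gender",
              "infection", "initial_length", "initial_width",
              "final_length", "final_width", "degrees_growth")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop("record table lacks columns: ", paste(missing, collapse = ", "))
  if (!"period" %in% names(rec)) rec$period <- "1"
  rec$period <- as.character(rec$period)
  if (!"is_outlier" %in% names(rec)) rec$is_outlier <- FALSE
  if (!"group" %in% names(rec)) {
    uninf <- rec$infection == "none" & !is.na(rec$infection)
    single <- !uninf & !is.na(rec$infection) &
      !grepl("+", rec$infection, fixed = TRUE)
    rec$group <- ifelse(uninf, rec$gender,
                        ifelse(single, rec$infection, "mixed"))
  }
  rec
}

#' Write a world's latent truth and configuration
#'
#' The observed records, the latent (pre-kill) recruitment table and the
#' realized mortality truth are written as delimited text side-car files;
#' the configuration is written as YAML.
#'
#' @param world a \code{\link{generate_world}} result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_snail_records(world$records, file.path(dir, "records.csv"))
  latent <- data.frame(snail_id = world$records$snail_id,
                       world$latent_infections * 1L)
  utils::write.csv(latent, file.path(dir, "latent_infections.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(species = names(world$true_mortality),
                              true_mortality = world$true_mortality),
                   file.path(dir, "true_mortality.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- world$config
  yaml::write_yaml(list(
    species = cfg$species,
    dominance_edges = cfg$hierarchy$edges,
    n_per_site = cfg$n_per_site,
    ref_days = cfg$ref_days,
    seed = world$seed), file.path(dir, "config.yaml"))
  invisible(dir)
}
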