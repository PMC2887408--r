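# shared fixture builders: configs are constructed in code, never stored

# minimal record table for direct growth-model tests
make_growth_records <- function(group, growth, initial_volume,
                                site = "s1", estuary = "E1",
                                habitat = "creek", period = "1") {
  n <- length(growth)
  data.frame(snail_id = sprintf("r%04d", seq_len(n)),
             estuary = rep_len(estuary, n), site = rep_len(site, n),
             habitat = rep_len(habitat, n), period = rep_len(period, n),
             growing_days = 94,
             gender = "female",
             infection = ifelse(group %in% c("male", "female"),
                                "none", group),
             group = group,
             initial_length = 20, initial_width = 8,
             final_length = 22, final_width = 9,
             degrees_growth = 90, is_outlier = FALSE,
             growth = growth, initial_volume = initial_volume,
             stringsAsFactors = FALSE)
}

# two-species world: dominant D over subordinate S, one estuary
two_species_config <- function(n_per_site = 2000L, prev_d = 0.5,
                               prev_s = 0.3, n_sites = 4L, seed = 1L) {
  species <- c("domi", "subo")
  h <- dominance_hierarchy(data.frame(killer = "domi", victim = "subo"),
                           species = species)
  sites <- data.frame(site = sprintf("s%02d", seq_len(n_sites)),
                      estuary = "E1", habitat = "creek",
                      stringsAsFactors = FALSE)
  prev <- matrix(c(rep(prev_d, n_sites), rep(prev_s, n_sites)),
                 ncol = 2, dimnames = list(sites$site, species))
  groups <- c(species, "male", "female")
  gp <- data.frame(group = groups, intercept = log(15), slope = 0,
                   dispersion = 2, stringsAsFactors = FALSE)
  gsi <- setNames(rep(0.15, 4), groups)
  world_config(species = species, hierarchy = h, sites = sites,
               prevalence = prev, growth_params = gp, gsi = gsi,
               n_per_site = n_per_site, seed = seed)
}

# single castrator plus uninfected genders at one site, known coefficients:
# the parameter-recovery configuration
recovery_config <- function(phi = 1, n_per_site = 800L, seed = 1L) {
  species <- "sp1"
  h <- dominance_hierarchy(data.frame(killer = character(),
                                      victim = character()),
                           species = species)
  sites <- data.frame(site = "s1", estuary = "E1", habitat = "creek",
                      stringsAsFactors = FALSE)
  prev <- matrix(0.5, 1, 1, dimnames = list("s1", species))
  gp <- data.frame(group = c("sp1", "male", "female"),
                   intercept = c(3.4, 2.2, 2.6),
                   slope = c(-6e-4, -4e-4, -5e-4),
                   dispersion = phi, stringsAsFactors = FALSE)
  gsi <- c(sp1 = 0.2, male = 0.146, female = 0.149)
  world_config(species = species, hierarchy = h, sites = sites,
               prevalence = prev, growth_params = gp, gsi = gsi,
               n_per_site = n_per_site, seed = seed)
}

example_tree <- function() {
  read_tree(paste0("(((hima:1,euha:1):1,((cloa:1,acan:1):1,",
                   "(prob:1,stic:1):1):1):1,((renc:1,smcy:1):1,",
                   "(male:1,female:1):1):1);"))
}

# site infection table built directly from counts (combo name -> count)
make_site_table <- function(site, combos, uninf_male = 0, uninf_female = 0) {
  n <- sum(combos) + uninf_male + uninf_female
  structure(list(site = site, n = n,
                 combos = combos,
                 uninfected = c(male = uninf_male, female = uninf_female)),
            class = "site_infection_table")
}
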