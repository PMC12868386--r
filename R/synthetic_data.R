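#' Configuration for the synthetic diet-study generator
#'
#' The generator emulates the shape of a two-group faecal metabarcoding
#' study: a social-group/individual/matriline Dirichlet hierarchy on taxon
#' proportions, triplicate PCR with multinomial read counts, sporadic
#' single-replicate contaminants, occasional replicate failures, and a
#' focal-follow observational readout of the same underlying diets with
#' optional handling-time and detectability bias.
#'
#' Group diet means differ only in how mass is split between provenance
#' classes: group `g` assigns anthropogenic (score 1) mass
#' `base_anthropogenic_mass + (g - 1) * group_anthropogenic_shift / 100`,
#' keeps `uncertain_mass` on score-0.5 taxa, and gives the rest to natural
#' taxa; the expected score-weighted anthropogenic percentage therefore
#' differs by exactly `group_anthropogenic_shift` points between adjacent
#' groups. A pool of `n_taxa_contaminant` taxa carries zero dietary mass and
#' exists only as the source of injected contaminants, making the
#' replicate-consensus filter's removal rate exactly checkable.
#'
#' @param seed Integer RNG seed used by [simulate_dataset()].
#' @param n_groups Number of social groups (default 2).
#' @param individuals_per_group Individuals per group (default 12).
#' @param n_mother_infant_pairs Mother-infant pairs per group (default 3).
#' @param n_taxa_natural,n_taxa_uncertain,n_taxa_anthropogenic,n_taxa_contaminant
#'   Taxa per provenance class (defaults 18 / 6 / 6 / 5).
#' @param base_anthropogenic_mass Score-1 diet mass in the first group
#'   (default 0.05).
#' @param uncertain_mass Score-0.5 diet mass in every group (default 0.10).
#' @param group_anthropogenic_shift Difference in expected anthropogenic
#'   share between adjacent groups, percentage points (default 10).
#' @param alpha_group Dirichlet concentration of the group base composition
#'   around its mean (default 10000; the group-level diet is treated as a
#'   near-fixed condition of the study, with only mild run-to-run
#'   variation).
#' @param tau Dirichlet concentration of individual profiles around the
#'   group base (default 150).
#' @param kappa Dirichlet concentration of infant profiles around the
#'   mother's profile (default 200).
#' @param samples_per_individual Faecal samples per individual (default 3).
#' @param replicates_per_sample PCR replicates per sample (default 3).
#' @param reads_per_replicate Sequencing depth per replicate (default 2e4).
#' @param contamination_rate Per-replicate probability of injecting one
#'   contaminant taxon into exactly that replicate (default 0.05).
#' @param replicate_failure_rate Per-replicate probability of total
#'   amplification failure (default 0.02).
#' @param seconds_total Feeding seconds observed per individual
#'   (default 7200).
#' @param handling_bias Optional named vector of per-taxon handling-time
#'   multipliers for the observational readout (default all 1).
#' @param detectability Optional named vector of per-taxon observational
#'   detectabilities in \[0, 1\] (default all 1).
#' @param window_start First collection day (default `"2023-08-15"`).
#' @param window_days Length of the collection window in days (default 130).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 20230815L,
                       n_groups = 2,
                       individuals_per_group = 12,
                       n_mother_infant_pairs = 3,
                       n_taxa_natural = 18,
                       n_taxa_uncertain = 6,
                       n_taxa_anthropogenic = 6,
                       n_taxa_contaminant = 5,
                       base_anthropogenic_mass = 0.05,
                       uncertain_mass = 0.10,
                       group_anthropogenic_shift = 10,
                       alpha_group = 10000,
                       tau = 150,
                       kappa = 200,
                       samples_per_individual = 3,
                       replicates_per_sample = 3,
                       reads_per_replicate = 2e4,
                       contamination_rate = 0.05,
                       replicate_failure_rate = 0.02,
                       seconds_total = 7200,
                       handling_bias = NULL,
                       detectability = NULL,
                       window_start = as.Date("2023-08-15"),
                       window_days = 130) {
  cfg <- list(seed = as.integer(seed), n_groups = n_groups,
              individuals_per_group = individuals_per_group,
              n_mother_infant_pairs = n_mother_infant_pairs,
              n_taxa_natural = n_taxa_natural,
              n_taxa_uncertain = n_taxa_uncertain,
              n_taxa_anthropogenic = n_taxa_anthropogenic,
              n_taxa_contaminant = n_taxa_contaminant,
              base_anthropogenic_mass = base_anthropogenic_mass,
              uncertain_mass = uncertain_mass,
              group_anthropogenic_shift = group_anthropogenic_shift,
              alpha_group = alpha_group, tau = tau, kappa = kappa,
              samples_per_individual = samples_per_individual,
              replicates_per_sample = replicates_per_sample,
              reads_per_replicate = reads_per_replicate,
              contamination_rate = contamination_rate,
              replicate_failure_rate = replicate_failure_rate,
              seconds_total = seconds_total,
              handling_bias = handling_bias,
              detectability = detectability,
              window_start = as.Date(window_start),
              window_days = window_days)
  rates <- c(cfg$contamination_rate, cfg$replicate_failure_rate)
  if (any(rates < 0 | rates > 1)) {
    fd_abort("rates must lie in [0, 1]", class = "fd_error_bad_value")
  }
  if (any(c(cfg$alpha_group, cfg$tau, cfg$kappa) <= 0)) {
    fd_abort("concentrations must be positive", class = "fd_error_bad_value")
  }
  top_anthro <- base_anthropogenic_mass +
    (n_groups - 1) * group_anthropogenic_shift / 100
  if (top_anthro + uncertain_mass >= 1) {
    fd_abort("anthropogenic + uncertain mass must leave room for natural taxa",
             class = "fd_error_bad_value")
  }
  counts <- c(cfg$individuals_per_group, cfg$samples_per_individual,
              cfg$replicates_per_sample, cfg$reads_per_replicate)
  if (any(counts < 1)) {
    fd_abort("counts must be >= 1", class = "fd_error_bad_value")
  }
  structure(cfg, class = "sim_config")
}

# Taxon table for the simulated community. Four of the natural taxa are
# species-rank (two congeneric pairs) so genus-level harmonization is
# exercised; two anthropogenic taxa sit in the vertebrate library.
sim_taxa <- function(config) {
  n_nat <- config$n_taxa_natural
  if (n_nat < 6) {
    fd_abort("need at least 6 natural taxa", class = "fd_error_bad_value")
  }
  nat_genus <- sprintf("nat_g%02d", seq_len(n_nat - 4))
  nat_species <- sprintf("nat_sp%02d", 1:4)
  nat_species_label <- c("nat_gsp01", "nat_gsp01", "nat_gsp02", "nat_gsp03")
  unc <- sprintf("unc_g%02d", seq_len(config$n_taxa_uncertain))
  ant <- sprintf("ant_g%02d", seq_len(config$n_taxa_anthropogenic))
  cont <- sprintf("cont_g%02d", seq_len(config$n_taxa_contaminant))
  ant_marker <- rep("plant", length(ant))
  if (length(ant) >= 2) ant_marker[1:2] <- "vertebrate"
  tibble(
    taxon_id = c(nat_genus, nat_species, unc, ant, cont),
    rank = c(rep("genus", length(nat_genus)), rep("species", 4),
             rep("genus", length(unc) + length(ant) + length(cont))),
    genus_or_higher_label = c(nat_genus, nat_species_label, unc, ant, cont),
    marker = c(rep("plant", length(nat_genus) + 4 + length(unc)),
               ant_marker, rep("plant", length(cont))),
    provenance_score = c(rep(0, n_nat), rep(0.5, length(unc)),
                         rep(1, length(ant)), rep(0, length(cont)))
  )
}

# Mean diet composition per group: class masses split within class by a
# geometric abundance series (a few dominant taxa, many rare ones).
sim_group_means <- function(config, taxa) {
  class_of <- ifelse(grepl("^cont", taxa$taxon_id), "contaminant",
                     ifelse(taxa$provenance_score == 0, "natural",
                            ifelse(taxa$provenance_score == 0.5, "uncertain",
                                   "anthropogenic")))
  series <- function(n) {
    w <- exp(-0.25 * (seq_len(n) - 1))
    w / sum(w)
  }
  m <- matrix(0, nrow = config$n_groups, ncol = nrow(taxa),
              dimnames = list(sprintf("group%s", LETTERS[seq_len(config$n_groups)]),
                              taxa$taxon_id))
  for (g in seq_len(config$n_groups)) {
    a_mass <- config$base_anthropogenic_mass +
      (g - 1) * config$group_anthropogenic_shift / 100
    u_mass <- config$uncertain_mass
    n_mass <- 1 - a_mass - u_mass
    m[g, class_of == "natural"] <- n_mass * series(sum(class_of == "natural"))
    m[g, class_of == "uncertain"] <- u_mass * series(sum(class_of == "uncertain"))
    m[g, class_of == "anthropogenic"] <-
      a_mass * series(sum(class_of == "anthropogenic"))
  }
  m
}

#' Simulate sample metadata for a multi-group diet study
#'
#' Builds individuals (group, sex, age class, mother links for the
#' designated infants) and their faecal samples, with collection dates
#' spread over the study window and no same-day re-collection per
#' individual. Mothers are adult females of the infant's own group.
#'
#' Uses the current RNG state; see [simulate_dataset()] for seeded
#' end-to-end generation.
#'
#' @param config A [sim_config()].
#' @return Sample metadata tibble (`sample_id`, `individual_id`, `group`,
#'   `sex`, `age_class`, `mother_id`, `date`) with an `individuals`
#'   attribute (one row per individual).
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  npg <- config$individuals_per_group
  npairs <- config$n_mother_infant_pairs
  n_adult_f <- max(npairs, min(6, npg - npairs - 1))
  n_adult_m <- if (npg - n_adult_f - npairs >= 2) 2 else
    max(0, npg - n_adult_f - npairs)
  n_juv <- npg - n_adult_f - n_adult_m
  if (n_juv < npairs) {
    fd_abort("more mother-infant pairs than juveniles",
             class = "fd_error_bad_value")
  }
  inds <- purrr::map(seq_len(config$n_groups), function(g) {
    group <- sprintf("group%s", LETTERS[g])
    id <- sprintf("%s_i%02d", group, seq_len(npg))
    sex <- c(rep("F", n_adult_f), rep("M", n_adult_m),
             sample(c("M", "F"), n_juv, replace = TRUE))
    age <- c(rep("adult", n_adult_f + n_adult_m), rep("juvenile", n_juv))
    mother <- rep(NA_character_, npg)
    infant_idx <- (n_adult_f + n_adult_m) + seq_len(npairs)
    mother[infant_idx] <- id[seq_len(npairs)]  # distinct adult females
    tibble(individual_id = id, group = group, sex = sex, age_class = age,
           mother_id = mother)
  }) |> bind_rows()

  samples <- inds |>
    tidyr::crossing(k = seq_len(config$samples_per_individual)) |>
    select(-all_of("k"))
  offsets <- purrr::map(seq_len(nrow(inds)), function(i) {
    sort(sample.int(config$window_days, config$samples_per_individual) - 1L)
  })
  samples <- samples |>
    arrange(.data$individual_id) |>
    mutate(date = config$window_start + unlist(offsets)) |>
    mutate(sample_id = sprintf("s%03d", dplyr::row_number())) |>
    select(all_of(c("sample_id", "individual_id", "group", "sex",
                    "age_class", "mother_id", "date")))
  attr(samples, "individuals") <- inds
  samples
}

#' Simulate ground-truth diet profiles
#'
#' Hierarchical Dirichlet structure: each group's base composition is drawn
#' around its class-structured mean (`alpha_group` concentration), each
#' non-infant individual's profile around the group base (`tau`), and each
#' infant's profile around its mother's realised profile (`kappa`). All
#' profiles lie on the unit simplex; contaminant-pool taxa carry exactly
#' zero mass.
#'
#' @param config A [sim_config()].
#' @param samples Sample metadata from [simulate_metadata()].
#' @return A `sim_truth` list: `taxa` (taxon table), `profiles`
#'   (individuals-by-taxa matrix), `group_means` (groups-by-taxa matrix),
#'   `expected_anthropogenic_pct` (named per-group score-weighted
#'   percentage), `config`.
#' @export
simulate_diet_profiles <- function(config, samples) {
  taxa <- sim_taxa(config)
  m <- sim_group_means(config, taxa)
  inds <- attr(samples, "individuals") %||%
    distinct(samples, .data$individual_id, .data$group, .data$sex,
             .data$age_class, .data$mother_id)
  base <- matrix(0, nrow = config$n_groups, ncol = nrow(taxa),
                 dimnames = dimnames(m))
  for (g in seq_len(nrow(m))) {
    base[g, ] <- rdirichlet(1, config$alpha_group * m[g, ])
  }
  profiles <- matrix(0, nrow = nrow(inds), ncol = nrow(taxa),
                     dimnames = list(inds$individual_id, taxa$taxon_id))
  is_infant <- !is.na(inds$mother_id)
  for (i in which(!is_infant)) {
    profiles[i, ] <- rdirichlet(1, config$tau * base[inds$group[i], ])
  }
  for (i in which(is_infant)) {
    mom <- profiles[inds$mother_id[i], ]
    profiles[i, ] <- rdirichlet(1, config$kappa * mom)
  }
  scores <- setNames(taxa$provenance_score, taxa$taxon_id)
  expected <- apply(m, 1, function(x) 100 * sum(scores * x) / sum(x))
  structure(
    list(taxa = taxa, profiles = profiles, group_means = m,
         expected_anthropogenic_pct = expected, config = config),
    class = "sim_truth")
}

#' Simulate the per-replicate read-count table
#'
#' Per (sample, replicate): with probability `replicate_failure_rate` the
#' replicate fails outright (no rows); otherwise counts are multinomial at
#' depth `reads_per_replicate` on the individual's true profile. With
#' probability `contamination_rate`, one taxon from the zero-diet
#' contaminant pool (unused so far in that sample) is injected into exactly
#' that replicate with a log-normal read count (>= 10 reads, so injected
#' rows survive the library-wide minimum-read filter and are removed only by
#' the replicate-consensus rule). Injections are recorded in the returned
#' attribute.
#'
#' @param truth A `sim_truth` from [simulate_diet_profiles()].
#' @param samples Sample metadata.
#' @return Read tibble (`sample_id`, `replicate`, `marker`, `taxon_id`,
#'   `reads`) with attributes `contaminants` (tibble of injected rows) and
#'   `failed_replicates`.
#' @export
simulate_read_table <- function(truth, samples) {
  config <- truth$config
  taxa <- truth$taxa
  marker_of <- setNames(taxa$marker, taxa$taxon_id)
  pool <- taxa$taxon_id[grepl("^cont", taxa$taxon_id)]
  rows <- vector("list", nrow(samples) * config$replicates_per_sample)
  contam <- list()
  failed <- character()
  k <- 0
  for (s in seq_len(nrow(samples))) {
    prof <- truth$profiles[samples$individual_id[s], ]
    used_pool <- character()
    for (r in seq_len(config$replicates_per_sample)) {
      k <- k + 1
      if (runif(1) < config$replicate_failure_rate) {
        failed <- c(failed, paste(samples$sample_id[s], r, sep = ":"))
        next
      }
      counts <- as.vector(rmultinom(1, config$reads_per_replicate, prof))
      names(counts) <- names(prof)
      inject <- runif(1) < config$contamination_rate
      if (inject && length(setdiff(pool, used_pool)) > 0) {
        ct <- sample(setdiff(pool, used_pool), 1)
        used_pool <- c(used_pool, ct)
        n_ct <- max(10L, as.integer(round(rlnorm(1, log(80), 0.6))))
        counts[ct] <- counts[ct] + n_ct
        contam[[length(contam) + 1]] <- tibble(
          sample_id = samples$sample_id[s], replicate = r,
          taxon_id = ct, reads = n_ct)
      }
      nz <- counts > 0
      rows[[k]] <- tibble(
        sample_id = samples$sample_id[s], replicate = r,
        marker = unname(marker_of[names(counts)[nz]]),
        taxon_id = names(counts)[nz],
        reads = as.integer(counts[nz]))
    }
  }
  out <- bind_rows(purrr::compact(rows))
  attr(out, "contaminants") <- if (length(contam) > 0) bind_rows(contam) else
    tibble(sample_id = character(), replicate = integer(),
           taxon_id = character(), reads = integer())
  attr(out, "failed_replicates") <- failed
  out
}

#' Simulate focal-follow feeding observations
#'
#' Observed feeding seconds per taxon are a biased multinomial readout of
#' the individual's true profile: expected seconds on taxon t are
#' proportional to `profile_t * handling_bias_t * detectability_t`,
#' allocated out of `seconds_total` per individual. Food classes follow the
#' provenance scores (1 -> anthropogenic, 0 -> natural, 0.5 -> unknown).
#'
#' @param truth A `sim_truth`.
#' @param samples Sample metadata (provides individuals and the window).
#' @return Focal observation tibble (`individual_id`, `date`, `taxon_id`,
#'   `seconds`, `food_class`).
#' @export
simulate_observations <- function(truth, samples) {
  config <- truth$config
  taxa <- truth$taxa
  ids <- colnames(truth$profiles)
  h <- rep(1, length(ids)); names(h) <- ids
  if (!is.null(config$handling_bias)) {
    h[names(config$handling_bias)] <- config$handling_bias
  }
  delta <- rep(1, length(ids)); names(delta) <- ids
  if (!is.null(config$detectability)) {
    delta[names(config$detectability)] <- config$detectability
  }
  score <- setNames(taxa$provenance_score, taxa$taxon_id)
  class_of <- ifelse(score == 1, "anthropogenic",
                     ifelse(score == 0, "natural", "unknown"))
  inds <- unique(samples$individual_id)
  out <- purrr::map(inds, function(ind) {
    w <- truth$profiles[ind, ] * h * delta
    if (sum(w) == 0) return(NULL)
    secs <- as.vector(rmultinom(1, config$seconds_total, w / sum(w)))
    nz <- secs > 0
    tibble(
      individual_id = ind,
      date = config$window_start +
        sample.int(config$window_days, sum(nz), replace = TRUE) - 1L,
      taxon_id = ids[nz],
      seconds = as.integer(secs[nz]),
      food_class = unname(class_of[ids[nz]]))
  })
  bind_rows(purrr::compact(out))
}

#' Generate a complete synthetic diet dataset with known ground truth
#'
#' Seeds the RNG from `config$seed` and runs metadata, diet-profile,
#' read-table and observation generation in sequence.
#'
#' @param config A [sim_config()].
#' @return List with `bundle` (a validated `diet_bundle`) and `truth`
#'   (`sim_truth` augmented with `contaminants` and `failed_replicates`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  samples <- simulate_metadata(config)
  truth <- simulate_diet_profiles(config, samples)
  reads <- simulate_read_table(truth, samples)
  obs <- simulate_observations(truth, samples)
  truth$contaminants <- attr(reads, "contaminants")
  truth$failed_replicates <- attr(reads, "failed_replicates")
  bundle <- new_bundle(reads = as_tibble(reads), taxa = truth$taxa,
                       samples = as_tibble(samples), observations = obs)
  list(bundle = bundle, truth = truth)
}
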