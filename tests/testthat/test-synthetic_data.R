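test_that("simulated metadata has the configured population structure", {
  set.seed(91)
  cfg <- sim_config(individuals_per_group = 10, n_mother_infant_pairs = 2,
                    samples_per_individual = 2)
  meta <- simulate_metadata(cfg)
  inds <- attr(meta, "individuals")
  expect_equal(nrow(inds), 20)
  expect_equal(as.integer(table(inds$group)), c(10L, 10L))
  expect_equal(nrow(meta), 40)
  # every mother is an adult female of the infant's own group
  infants <- inds[!is.na(inds$mother_id), ]
  expect_equal(nrow(infants), 4)
  moms <- inds[match(infants$mother_id, inds$individual_id), ]
  expect_true(all(moms$sex == "F"))
  expect_true(all(moms$age_class == "adult"))
  expect_equal(moms$group, infants$group)
  # no same-day re-collection
  expect_equal(anyDuplicated(meta[, c("individual_id", "date")]), 0L)
  # all dates inside the window
  expect_true(all(meta$date >= cfg$window_start &
                    meta$date < cfg$window_start + cfg$window_days))

  expect_error(
    simulate_metadata(sim_config(individuals_per_group = 4,
                                 n_mother_infant_pairs = 4)),
    class = "fd_error_bad_value")
})

test_that("diet profiles sit on the simplex with matriline correlation", {
  set.seed(92)
  cfg <- sim_config()
  meta <- simulate_metadata(cfg)
  truth <- simulate_diet_profiles(cfg, meta)
  expect_equal(unname(rowSums(truth$profiles)), rep(1, nrow(truth$profiles)),
               tolerance = 1e-12)
  # contaminant-pool taxa carry exactly zero dietary mass
  pool <- grep("^cont", colnames(truth$profiles))
  expect_true(all(truth$profiles[, pool] == 0))
  # configured shift appears exactly in the expected percentages
  expect_equal(unname(diff(truth$expected_anthropogenic_pct)), 10)

  # kappa -> infinity collapses infants onto their mothers
  set.seed(921)
  cfg_inf <- sim_config(kappa = 1e6)
  meta2 <- simulate_metadata(cfg_inf)
  truth2 <- simulate_diet_profiles(cfg_inf, meta2)
  inds <- attr(meta2, "individuals")
  infants <- inds[!is.na(inds$mother_id), ]
  for (k in seq_len(nrow(infants))) {
    expect_lt(max(abs(truth2$profiles[infants$individual_id[k], ] -
                        truth2$profiles[infants$mother_id[k], ])), 1e-3)
  }
})

test_that("realized group shift obeys the law of large numbers", {
  set.seed(93)
  cfg <- sim_config(individuals_per_group = 500, samples_per_individual = 1,
                    n_mother_infant_pairs = 0)
  meta <- simulate_metadata(cfg)
  truth <- simulate_diet_profiles(cfg, meta)
  scores <- provenance_scores(truth$taxa)[colnames(truth$profiles)]
  share <- 100 * truth$profiles %*% scores
  g <- sub("_.*", "", rownames(truth$profiles))
  expect_equal(unname(diff(tapply(share, g, mean))), 10, tolerance = 1)

  # zero shift: group means agree within Monte-Carlo error
  set.seed(931)
  cfg0 <- sim_config(individuals_per_group = 500, samples_per_individual = 1,
                     n_mother_infant_pairs = 0, group_anthropogenic_shift = 0)
  meta0 <- simulate_metadata(cfg0)
  truth0 <- simulate_diet_profiles(cfg0, meta0)
  share0 <- 100 * truth0$profiles %*%
    provenance_scores(truth0$taxa)[colnames(truth0$profiles)]
  g0 <- sub("_.*", "", rownames(truth0$profiles))
  expect_lt(abs(diff(tapply(share0, g0, mean))), 2)
})

test_that("read tables have multinomial totals and one-replicate contaminants", {
  set.seed(94)
  cfg <- small_config(seed = 941, contamination_rate = 0,
                      replicate_failure_rate = 0)
  sim <- simulate_dataset(cfg)
  totals <- tapply(sim$bundle$reads$reads,
                   paste(sim$bundle$reads$sample_id,
                         sim$bundle$reads$replicate), sum)
  expect_true(all(totals == cfg$reads_per_replicate))
  expect_equal(nrow(sim$truth$contaminants), 0)

  cfg2 <- small_config(seed = 942, contamination_rate = 0.3)
  sim2 <- simulate_dataset(cfg2)
  ct <- sim2$truth$contaminants
  expect_gt(nrow(ct), 0)
  # each injected contaminant occurs in exactly one replicate of its sample
  reads2 <- sim2$bundle$reads
  for (k in seq_len(nrow(ct))) {
    hits <- reads2[reads2$sample_id == ct$sample_id[k] &
                     reads2$taxon_id == ct$taxon_id[k] & reads2$reads > 0, ]
    expect_equal(nrow(hits), 1)
    expect_equal(hits$replicate, ct$replicate[k])
  }
  # and the consensus filter removes every one of them
  qc <- qc_pipeline(sim2$bundle$reads)
  expect_equal(nrow(dplyr::semi_join(qc$rra, ct,
                                     by = c("sample_id", "taxon_id"))), 0)
})

test_that("merged RRA converges to the true profile as depth grows", {
  mae_at <- function(depth, seed) {
    cfg <- sim_config(seed = seed, individuals_per_group = 4,
                      n_mother_infant_pairs = 1, samples_per_individual = 1,
                      reads_per_replicate = depth, contamination_rate = 0,
                      replicate_failure_rate = 0)
    sim <- simulate_dataset(cfg)
    qc <- qc_pipeline(sim$bundle$reads)
    m <- rra_matrix(qc$rra)
    meta <- sim$bundle$samples
    err <- 0
    for (s in rownames(m)) {
      ind <- meta$individual_id[meta$sample_id == s]
      prof <- sim$truth$profiles[ind, colnames(m)]
      prof <- prof / sum(prof)
      err <- err + mean(abs(m[s, ] - prof))
    }
    err / nrow(m)
  }
  expect_lt(mae_at(1e5, 951), mae_at(1e3, 951))
})

test_that("observations are an (optionally biased) readout of the profile", {
  set.seed(96)
  cfg <- sim_config(individuals_per_group = 2, n_mother_infant_pairs = 0,
                    samples_per_individual = 1, seconds_total = 100000)
  meta <- simulate_metadata(cfg)
  truth <- simulate_diet_profiles(cfg, meta)
  ind <- rownames(truth$profiles)[1]
  prof <- truth$profiles[ind, ]

  # unbiased case: mean observed share matches the profile
  reps <- replicate(300, {
    obs <- simulate_observations(truth, meta[meta$individual_id == ind, ])
    p <- tapply(obs$seconds, obs$taxon_id, sum)
    out <- setNames(rep(0, length(prof)), names(prof))
    out[names(p)] <- p / sum(p)
    out
  })
  expect_lt(max(abs(rowMeans(reps) - prof)), 0.005)

  # detectability zero removes a taxon entirely
  big <- names(sort(prof, decreasing = TRUE))[1]
  cfg_d <- sim_config(detectability = setNames(0, big),
                      seconds_total = 100000)
  truth_d <- truth; truth_d$config <- cfg_d
  obs_d <- simulate_observations(truth_d, meta[meta$individual_id == ind, ])
  expect_false(big %in% obs_d$taxon_id)

  # handling bias h = 3 inflates the observed share to 3p / (1 + 2p)
  cfg_h <- sim_config(handling_bias = setNames(3, big),
                      seconds_total = 100000)
  truth_h <- truth; truth_h$config <- cfg_h
  reps_h <- replicate(300, {
    obs <- simulate_observations(truth_h, meta[meta$individual_id == ind, ])
    sum(obs$seconds[obs$taxon_id == big]) / sum(obs$seconds)
  })
  p <- prof[[big]]
  expect_equal(mean(reps_h), 3 * p / (1 + 2 * p), tolerance = 0.01)

  # observational food classes follow the provenance scores
  obs <- simulate_observations(truth, meta)
  sc <- provenance_scores(truth$taxa)
  expect_true(all(obs$food_class[sc[obs$taxon_id] == 1] == "anthropogenic"))
  expect_true(all(obs$food_class[sc[obs$taxon_id] == 0] == "natural"))
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- small_config(seed = 971)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_equal(a$bundle$reads, b$bundle$reads)
  expect_equal(a$bundle$samples, b$bundle$samples)
  expect_equal(a$truth$profiles, b$truth$profiles)
  c <- simulate_dataset(small_config(seed = 972))
  expect_false(identical(a$bundle$reads, c$bundle$reads))
})
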