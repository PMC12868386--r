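# Hand-written minimal dataset: two samples, four taxa (one species rank,
# one vertebrate), a mother-infant pair, and a few focal records.

fixture_tables <- function() {
  taxa <- tibble::tibble(
    taxon_id = c("ficus", "bread_wheat", "melia_azedarach", "gallus_gallus"),
    rank = c("genus", "genus", "species", "species"),
    genus_or_higher_label = c("ficus", "bread_wheat", "melia", "gallus"),
    marker = c("plant", "plant", "plant", "vertebrate"),
    provenance_score = c(0, 1, 0.5, 1))
  samples <- tibble::tibble(
    sample_id = c("s01", "s02"),
    individual_id = c("mona", "kit"),
    group = c("groupA", "groupA"),
    sex = c("F", "M"),
    age_class = c("adult", "juvenile"),
    mother_id = c(NA_character_, "mona"),
    date = as.Date(c("2023-08-20", "2023-08-21")))
  reads <- tibble::tibble(
    sample_id = rep(c("s01", "s02"), each = 6),
    replicate = rep(rep(1:3, each = 2), 2),
    marker = "plant",
    taxon_id = rep(c("ficus", "bread_wheat"), 6),
    reads = as.integer(c(30, 60, 40, 50, 20, 70, 90, 10, 80, 20, 85, 15)))
  focal <- tibble::tibble(
    individual_id = c("mona", "mona", "kit"),
    date = as.Date(c("2023-08-20", "2023-08-21", "2023-08-21")),
    taxon_id = c("ficus", "bread_wheat", "ficus"),
    seconds = c(120L, 60L, 90L),
    food_class = c("natural", "anthropogenic", "natural"))
  list(reads = reads, taxa = taxa, samples = samples, focal = focal)
}

fixture_bundle <- function(with_obs = TRUE) {
  f <- fixture_tables()
  new_bundle(f$reads, f$taxa, f$samples,
             observations = if (with_obs) f$focal else NULL)
}

# Small simulation config for fast unit tests (not the documented defaults).
small_config <- function(seed = 99, ...) {
  sim_config(seed = seed, individuals_per_group = 6,
             n_mother_infant_pairs = 2, samples_per_individual = 2,
             reads_per_replicate = 4000, ...)
}
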