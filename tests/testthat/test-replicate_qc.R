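reads_of <- function(...) {
  # rows as vectors: sample, replicate, marker, taxon, reads
  rows <- list(...)
  tibble::tibble(
    sample_id = vapply(rows, `[[`, "", 1),
    replicate = as.integer(vapply(rows, `[[`, "", 2)),
    marker = vapply(rows, `[[`, "", 3),
    taxon_id = vapply(rows, `[[`, "", 4),
    reads = as.integer(vapply(rows, `[[`, "", 5)))
}

test_that("minimum-read filter is strict on 'fewer than' and per library", {
  tab <- reads_of(
    c("s1", "1", "plant", "rare", "4"), c("s1", "2", "plant", "rare", "5"),
    c("s1", "1", "plant", "edge", "10"),
    c("s1", "1", "vertebrate", "rare", "50"),
    c("s1", "1", "plant", "common", "100"))
  out <- filter_min_reads(tab, threshold = 10)
  # 9 plant reads of 'rare' go; its 50 vertebrate-library reads stay
  expect_false(any(out$taxon_id == "rare" & out$marker == "plant"))
  expect_true(any(out$taxon_id == "rare" & out$marker == "vertebrate"))
  expect_true("edge" %in% out$taxon_id)   # exactly 10 reads is retained
  expect_equal(filter_min_reads(tab, threshold = 0)$reads, tab$reads)
  excl <- qc_exclusions(out)
  expect_true(any(excl$id == "rare" & excl$marker == "plant"))
})

test_that("replicate-consensus filter drops single-replicate taxa and weak samples", {
  tab <- reads_of(
    c("s1", "1", "plant", "ficus", "50"), c("s1", "2", "plant", "ficus", "60"),
    c("s1", "3", "plant", "ficus", "55"),
    c("s1", "2", "plant", "contam", "40"),          # one replicate only
    c("s1", "1", "plant", "melia", "20"), c("s1", "3", "plant", "melia", "25"),
    c("s2", "1", "plant", "ficus", "80"))            # one successful replicate
  out <- filter_replicate_support(tab, n_replicates = 3, min_support = 2)
  expect_false("contam" %in% out$taxon_id)
  expect_true(all(c("ficus", "melia") %in% out$taxon_id[out$sample_id == "s1"]))
  expect_false("s2" %in% out$sample_id)
  excl <- qc_exclusions(out)
  expect_true(any(excl$id == "s2" & excl$reason == "insufficient replicates"))
})

test_that("day-after-event taxon exclusion removes exactly the flagged rows", {
  f <- fixture_tables()
  taxa <- dplyr::bind_rows(
    f$taxa,
    tibble::tibble(taxon_id = "arachis", rank = "genus",
                   genus_or_higher_label = "Arachis", marker = "plant",
                   provenance_score = 1))
  reads <- dplyr::bind_rows(
    f$reads,
    reads_of(c("s01", "1", "plant", "arachis", "30"),
             c("s02", "1", "plant", "arachis", "30")))
  # s01 collected 2023-08-20, s02 2023-08-21
  out <- exclude_taxon_by_date(reads, taxa, f$samples, "Arachis",
                               event_dates = as.Date("2023-08-19"))
  expect_false(any(out$taxon_id == "arachis" & out$sample_id == "s01"))
  expect_true(any(out$taxon_id == "arachis" & out$sample_id == "s02"))

  # two days after the event: kept
  out2 <- exclude_taxon_by_date(reads, taxa, f$samples, "Arachis",
                                event_dates = as.Date("2023-08-18"))
  expect_equal(nrow(out2), nrow(reads))
  # empty event list is the identity
  out3 <- exclude_taxon_by_date(reads, taxa, f$samples, "Arachis")
  expect_equal(out3, reads, ignore_attr = TRUE)
  expect_error(exclude_taxon_by_date(reads, taxa, f$samples, "Nonexistus"),
               class = "fd_error_dangling_reference")
})

test_that("per-replicate RRA normalises counts and guards zero totals", {
  tab <- reads_of(
    c("s1", "1", "plant", "a", "30"), c("s1", "1", "plant", "b", "60"),
    c("s1", "1", "plant", "c", "10"),
    c("s1", "2", "plant", "a", "0"),
    c("s2", "1", "plant", "a", "25"))
  out <- compute_rra(tab)
  r1 <- out[out$sample_id == "s1" & out$replicate == 1, ]
  expect_equal(r1$rra[match(c("a", "b", "c"), r1$taxon_id)], c(0.3, 0.6, 0.1))
  # the zero-total replicate is dropped, not divided
  expect_false(any(out$sample_id == "s1" & out$replicate == 2))
  expect_true(any(qc_exclusions(out)$id == "s1:2"))
  expect_equal(out$rra[out$sample_id == "s2"], 1.0)  # single-taxon replicate
})

test_that("mean-RRA merge averages replicates with zero imputation", {
  rra_rep <- tibble::tibble(
    sample_id = "s1", replicate = c(1L, 1L, 2L, 2L),
    taxon_id = c("a", "b", "a", "b"), rra = c(0.2, 0.8, 0.4, 0.6))
  out <- merge_replicates(rra_rep)
  expect_equal(out$rra[match(c("a", "b"), out$taxon_id)], c(0.3, 0.7))

  # identical replicates merge to themselves
  same <- dplyr::mutate(rra_rep, rra = rep(c(0.25, 0.75), 2))
  expect_equal(merge_replicates(same)$rra, c(0.25, 0.75))

  # absent taxon counts as zero: 0.3 in 2 of 3 replicates -> raw mean 0.2
  three <- tibble::tibble(
    sample_id = "s1", replicate = c(1L, 1L, 2L, 2L, 3L),
    taxon_id = c("a", "b", "a", "b", "b"),
    rra = c(0.3, 0.7, 0.3, 0.7, 1.0))
  raw <- merge_replicates(three, renormalize = FALSE)
  expect_equal(raw$rra[raw$taxon_id == "a"], 0.2)
  norm <- merge_replicates(three)
  expect_equal(sum(norm$rra), 1)
})

test_that("filters are monotone and merged profiles stay on the simplex", {
  set.seed(401)
  for (i in 1:20) {
    tab <- random_reads()
    f1 <- filter_min_reads(tab, 10)
    f2 <- filter_replicate_support(f1)
    expect_lte(sum(f1$reads), sum(tab$reads))
    expect_lte(sum(f2$reads), sum(f1$reads))
    expect_lte(dplyr::n_distinct(f2$taxon_id), dplyr::n_distinct(tab$taxon_id))
    res <- qc_pipeline(tab)
    if (nrow(res$rra) > 0) {
      sums <- tapply(res$rra$rra, res$rra$sample_id, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
      expect_true(all(res$rra$rra >= 0 & res$rra$rra <= 1))
    }
  }
})

test_that("min-reads and event-exclusion filters commute on disjoint rows", {
  f <- fixture_tables()
  taxa <- dplyr::bind_rows(
    f$taxa,
    tibble::tibble(taxon_id = "arachis", rank = "genus",
                   genus_or_higher_label = "Arachis", marker = "plant",
                   provenance_score = 1))
  reads <- dplyr::bind_rows(
    f$reads,
    reads_of(c("s01", "1", "plant", "arachis", "30"),
             c("s01", "1", "plant", "dust", "3")))
  taxa <- dplyr::bind_rows(
    taxa, tibble::tibble(taxon_id = "dust", rank = "genus",
                         genus_or_higher_label = "dust", marker = "plant",
                         provenance_score = 0))
  ed <- as.Date("2023-08-19")
  a <- exclude_taxon_by_date(filter_min_reads(reads, 10), taxa, f$samples,
                             "Arachis", ed)
  b <- filter_min_reads(
    exclude_taxon_by_date(reads, taxa, f$samples, "Arachis", ed), 10)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("QC chain matches the brute-force oracle on random tables", {
  set.seed(402)
  for (i in 1:15) {
    tab <- random_reads(n_samples = sample(2:5, 1), n_taxa = sample(4:8, 1))
    got <- qc_pipeline(tab)$rra |>
      dplyr::arrange(sample_id, taxon_id) |>
      as.data.frame()
    want <- oracle_pipeline(tab)
    expect_equal(got$sample_id, want$sample_id)
    expect_equal(got$taxon_id, want$taxon_id)
    expect_equal(got$rra, want$rra, tolerance = 1e-12)
  }
})
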