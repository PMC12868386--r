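#' Remove low-abundance taxa from a read table
#'
#' Drops every taxon whose total read count within a sequencing library
#' (marker) falls below `threshold`. "Fewer than" is strict: a taxon with
#' exactly `threshold` reads is retained.
#'
#' @param reads Per-replicate read-count tibble
#'   (`sample_id`, `replicate`, `marker`, `taxon_id`, `reads`).
#' @param threshold Minimum library-wide read total for a taxon (default 10).
#' @return The filtered read tibble (a subset of the input rows), with an
#'   `exclusions` attribute (tibble of dropped taxa and reasons) retrievable
#'   via [qc_exclusions()].
#' @export
filter_min_reads <- function(reads, threshold = 10) {
  stopifnot(threshold >= 0)
  totals <- reads |>
    group_by(.data$marker, .data$taxon_id) |>
    summarise(total = sum(.data$reads), .groups = "drop")
  drop <- filter(totals, .data$total < threshold)
  out <- reads |>
    anti_join(drop, by = c("marker", "taxon_id"))
  excl <- tibble(
    scope = "taxon", id = drop$taxon_id, marker = drop$marker,
    reason = sprintf("fewer than %d reads in the %s library (%d)",
                     threshold, drop$marker, drop$total))
  attr(out, "exclusions") <- excl
  out
}

#' Keep only taxa detected in at least `min_support` PCR replicates
#'
#' Applies the replicate-consensus rule: within each sample, a taxon detected
#' (nonzero reads) in fewer than `min_support` of the sample's successful
#' replicates is treated as an artefact and all its rows for that sample are
#' removed. A replicate is "successful" when it has any reads at all. Samples
#' with fewer than `min_support` successful replicates cannot support the
#' consensus rule and are excluded entirely (logged with reason).
#'
#' @inheritParams filter_min_reads
#' @param n_replicates Nominal replicates per sample (default 3); samples may
#'   have fewer after failures.
#' @param min_support Minimum number of replicates a taxon must appear in
#'   (default 2, i.e. taxa present in only one of three replicates drop out).
#' @return Filtered read tibble with an `exclusions` attribute.
#' @export
filter_replicate_support <- function(reads, n_replicates = 3, min_support = 2) {
  rep_totals <- reads |>
    group_by(.data$sample_id, .data$replicate) |>
    summarise(total = sum(.data$reads), .groups = "drop")
  if (any(rep_totals |> count(.data$sample_id) |> pull(.data$n) > n_replicates)) {
    fd_abort("more replicates observed than n_replicates allows",
             class = "fd_error_bad_value")
  }
  good_reps <- filter(rep_totals, .data$total > 0)
  n_good <- good_reps |> count(.data$sample_id, name = "n_reps")

  bad_samples <- n_good |> filter(.data$n_reps < min_support)
  # samples absent from good_reps entirely (all replicates empty) cannot occur
  # here because empty replicates carry no rows; samples listed in reads always
  # have >= 1 nonzero row unless all their reads are 0
  zero_only <- setdiff(unique(reads$sample_id), n_good$sample_id)
  excl_samples <- tibble(
    scope = "sample",
    id = c(bad_samples$sample_id, zero_only),
    marker = NA_character_,
    reason = "insufficient replicates")

  kept <- reads |>
    semi_join(good_reps, by = c("sample_id", "replicate")) |>
    anti_join(excl_samples, by = c(sample_id = "id"))

  support <- kept |>
    filter(.data$reads > 0) |>
    distinct(.data$sample_id, .data$taxon_id, .data$replicate) |>
    count(.data$sample_id, .data$taxon_id, name = "support")
  weak <- filter(support, .data$support < min_support)
  out <- kept |> anti_join(weak, by = c("sample_id", "taxon_id"))

  excl_taxa <- tibble(
    scope = "sample_taxon",
    id = paste(weak$sample_id, weak$taxon_id, sep = ":"),
    marker = NA_character_,
    reason = sprintf("detected in fewer than %d replicates", min_support))
  attr(out, "exclusions") <- bind_rows(excl_samples, excl_taxa)
  out
}

#' Remove a taxon's reads from samples collected the day after listed events
#'
#' Supports provisioning-experiment corrections: when a known food (e.g. a
#' peanut reward, genus *Arachis*) was handed out on given dates, reads
#' assigned to that taxon in faecal samples collected exactly one day later
#' are removed as experiment carry-over. All other rows are untouched.
#'
#' @inheritParams filter_min_reads
#' @param taxa Taxon table; `taxon_label` is matched against both `taxon_id`
#'   and `genus_or_higher_label`.
#' @param samples Sample metadata carrying collection dates.
#' @param taxon_label Label of the taxon to strip (default `"Arachis"`).
#' @param event_dates Vector of event `Date`s; samples dated
#'   `event_date + 1` are affected. Empty vector is the identity.
#' @return Filtered read tibble with an `exclusions` attribute.
#' @export
exclude_taxon_by_date <- function(reads, taxa, samples,
                                  taxon_label = "Arachis",
                                  event_dates = as.Date(character())) {
  event_dates <- as.Date(event_dates)
  hit_taxa <- taxa |>
    filter(.data$taxon_id == taxon_label |
             .data$genus_or_higher_label == taxon_label) |>
    pull(.data$taxon_id)
  if (length(hit_taxa) == 0) {
    fd_abort(sprintf("unknown taxon label '%s'", taxon_label),
             class = "fd_error_dangling_reference")
  }
  if (length(event_dates) == 0) {
    attr(reads, "exclusions") <- tibble(scope = character(), id = character(),
                                        marker = character(), reason = character())
    return(reads)
  }
  affected_samples <- samples |>
    filter(.data$date %in% (event_dates + 1)) |>
    pull(.data$sample_id)
  drop <- reads$taxon_id %in% hit_taxa & reads$sample_id %in% affected_samples
  out <- reads[!drop, , drop = FALSE]
  attr(out, "exclusions") <- tibble(
    scope = "row",
    id = paste(reads$sample_id[drop], reads$taxon_id[drop], sep = ":"),
    marker = reads$marker[drop],
    reason = sprintf("'%s' reads the day after a provisioning event", taxon_label))
  out
}

#' Compute relative read abundance per PCR replicate
#'
#' Within each (sample, replicate), a taxon's RRA is its read count divided by
#' the replicate's total reads, so each replicate's RRA vector sums to one.
#' By default read counts are pooled across markers (plant + vertebrate)
#' before normalising, so the per-sample composition spans the whole detected
#' diet; set `pool_markers = FALSE` to normalise within each marker library.
#' Replicates with zero total reads are dropped (never divided) and logged.
#'
#' @inheritParams filter_min_reads
#' @param pool_markers Pool read counts across markers before normalising
#'   (default `TRUE`).
#' @return Tibble (`sample_id`, `replicate`, `taxon_id`, `rra`) — plus
#'   `marker` when `pool_markers = FALSE` — with an `exclusions` attribute.
#' @export
compute_rra <- function(reads, pool_markers = TRUE) {
  unit <- if (pool_markers) c("sample_id", "replicate") else
    c("sample_id", "replicate", "marker")
  totals <- reads |>
    group_by(across(all_of(unit))) |>
    summarise(total = sum(.data$reads), .groups = "drop")
  empty <- filter(totals, .data$total == 0)
  out <- reads |>
    filter(.data$reads > 0) |>
    inner_join(filter(totals, .data$total > 0), by = unit) |>
    mutate(rra = .data$reads / .data$total) |>
    select(all_of(c(unit, "taxon_id", "rra")))
  attr(out, "exclusions") <- tibble(
    scope = "replicate",
    id = paste(empty$sample_id, empty$replicate, sep = ":"),
    marker = NA_character_,
    reason = "no reads")
  out
}

#' Merge per-replicate RRA vectors into per-sample diet profiles
#'
#' A sample's profile is the arithmetic mean RRA over its contributing
#' replicates, where a taxon absent from a replicate contributes 0 there.
#' Because zero-imputation pulls the mean off the unit simplex whenever
#' replicates disagree, the merged vector is renormalised to sum to one by
#' default (`renormalize = FALSE` returns the raw means).
#'
#' @param rra_rep Per-replicate RRA tibble from [compute_rra()].
#' @param renormalize Restore the unit-sum constraint after averaging
#'   (default `TRUE`).
#' @return Tibble (`sample_id`, `taxon_id`, `rra`) with an `n_replicates`
#'   attribute (tibble of contributing replicate counts per sample).
#' @export
merge_replicates <- function(rra_rep, renormalize = TRUE) {
  n_reps <- rra_rep |>
    distinct(.data$sample_id, .data$replicate) |>
    count(.data$sample_id, name = "n_replicates")
  out <- rra_rep |>
    group_by(.data$sample_id, .data$taxon_id) |>
    summarise(rra_sum = sum(.data$rra), .groups = "drop") |>
    left_join(n_reps, by = "sample_id") |>
    mutate(rra = .data$rra_sum / .data$n_replicates) |>
    select(all_of(c("sample_id", "taxon_id", "rra")))
  if (renormalize) {
    out <- out |>
      group_by(.data$sample_id) |>
      mutate(rra = .data$rra / sum(.data$rra)) |>
      ungroup()
  }
  attr(out, "n_replicates") <- n_reps
  out
}

#' Run the full read-count QC chain and return per-sample diet profiles
#'
#' Applies, in order: the library-wide minimum-read filter, the
#' replicate-consensus filter, the optional day-after-event taxon exclusion,
#' per-replicate RRA computation, and the mean-RRA replicate merge.
#'
#' @inheritParams filter_min_reads
#' @inheritParams exclude_taxon_by_date
#' @inheritParams filter_replicate_support
#' @inheritParams compute_rra
#' @inheritParams merge_replicates
#' @param min_reads Library-wide minimum read total per taxon (default 10).
#' @param exclude_taxon Optional taxon label for the day-after-event
#'   exclusion; `NULL` skips that step.
#' @return List with `rra` (long per-sample tibble `sample_id`, `taxon_id`,
#'   `rra`), `exclusions` (tibble of everything dropped, with reasons and the
#'   step that dropped it) and `n_replicates`.
#' @export
qc_pipeline <- function(reads, taxa = NULL, samples = NULL,
                        min_reads = 10, n_replicates = 3, min_support = 2,
                        exclude_taxon = NULL,
                        event_dates = as.Date(character()),
                        pool_markers = TRUE, renormalize = TRUE) {
  log_of <- function(x, step) {
    e <- attr(x, "exclusions")
    if (is.null(e) || nrow(e) == 0) return(NULL)
    mutate(e, step = step)
  }
  s1 <- filter_min_reads(reads, threshold = min_reads)
  s2 <- filter_replicate_support(s1, n_replicates = n_replicates,
                                 min_support = min_support)
  s3 <- if (!is.null(exclude_taxon)) {
    if (is.null(taxa) || is.null(samples)) {
      fd_abort("exclude_taxon requires taxa and samples tables",
               class = "fd_error_bad_value")
    }
    exclude_taxon_by_date(s2, taxa, samples, taxon_label = exclude_taxon,
                          event_dates = event_dates)
  } else {
    s2
  }
  s4 <- compute_rra(s3, pool_markers = pool_markers)
  rra <- merge_replicates(s4, renormalize = renormalize)
  logs <- purrr::compact(list(log_of(s1, "min_reads"),
                              log_of(s2, "replicate_support"),
                              log_of(s3, "event_exclusion"),
                              log_of(s4, "rra")))
  excl <- if (length(logs) > 0) bind_rows(logs) else
    tibble(scope = character(), id = character(), marker = character(),
           reason = character(), step = character())
  list(rra = rra, exclusions = excl,
       n_replicates = attr(rra, "n_replicates"))
}

#' Retrieve the exclusion log attached by a QC filter
#'
#' @param x A tibble returned by one of the QC filters.
#' @return The `exclusions` attribute (tibble), or an empty tibble.
#' @export
qc_exclusions <- function(x) {
  attr(x, "exclusions") %||%
    tibble(scope = character(), id = character(), marker = character(),
           reason = character())
}

#' Pivot a long RRA table to a samples-by-taxa matrix
#'
#' @param rra Long tibble (`sample_id`, `taxon_id`, `rra`).
#' @return Numeric matrix, rows = samples, columns = taxa, absent entries 0.
#' @export
rra_matrix <- function(rra) {
  wide <- rra |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "taxon_id",
                       values_from = "rra", values_fill = 0) |>
    arrange(.data$sample_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, order(colnames(m)), drop = FALSE]
}
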