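#' Extract a named provenance-score vector from a taxon table
#'
#' @param taxa Taxon table with `taxon_id` and `provenance_score` columns.
#' @return Named numeric vector, taxon_id -> score in \{0, 0.5, 1\}.
#' @export
provenance_scores <- function(taxa) {
  assert_columns(taxa, c("taxon_id", "provenance_score"), "taxa")
  setNames(taxa$provenance_score, taxa$taxon_id)
}

#' Score-weighted anthropogenic percentage of one diet profile
#'
#' Each taxon carries a provenance score (0 natural, 0.5 uncertain, 1
#' anthropogenic); the sample's anthropogenic percentage is 100 times the sum
#' of score times RRA, divided by the sum of RRAs. The result is invariant to
#' rescaling the profile by a positive constant and linear in the scores.
#'
#' @param rra_row Named numeric vector of RRA values for one sample (names
#'   are taxon ids); need not be normalised.
#' @param scores Named score vector covering every taxon in `rra_row`
#'   (see [provenance_scores()]).
#' @return Percentage in \[0, 100\].
#' @export
anthropogenic_percentage <- function(rra_row, scores) {
  if (length(rra_row) == 0 || sum(rra_row) <= 0) {
    fd_abort("empty diet profile", class = "fd_error_bad_value")
  }
  miss <- setdiff(names(rra_row), names(scores))
  miss <- union(miss, names(rra_row)[is.na(scores[names(rra_row)])])
  if (length(miss) > 0) {
    fd_abort(sprintf("unscored taxa: %s", paste(miss, collapse = ", ")),
             class = "fd_error_dangling_reference")
  }
  s <- scores[names(rra_row)]
  100 * sum(s * rra_row) / sum(rra_row)
}

#' Partition diet mass into natural / uncertain / anthropogenic percentages
#'
#' Per sample, the three percentages are the RRA mass carried by taxa scored
#' 0, 0.5 and 1 respectively (each normalised by the sample's total RRA, so
#' they sum to 100). Group-level partitions average samples with equal
#' weights; RRA already normalises sequencing depth, so no read weighting is
#' applied.
#'
#' @param rra Long RRA tibble (`sample_id`, `taxon_id`, `rra`).
#' @param scores Named score vector (see [provenance_scores()]).
#' @param samples Sample metadata; required when `by = "group"`.
#' @param by Unit of the partition: `"sample"` (default) or `"group"`.
#' @return Tibble (`unit`, `natural_pct`, `uncertain_pct`,
#'   `anthropogenic_pct`); rows sum to 100.
#' @export
partition_by_provenance <- function(rra, scores, samples = NULL,
                                    by = c("sample", "group")) {
  by <- match.arg(by)
  miss <- setdiff(unique(rra$taxon_id), names(scores)[!is.na(scores)])
  if (length(miss) > 0) {
    fd_abort(sprintf("unscored taxa: %s", paste(head(miss, 5), collapse = ", ")),
             class = "fd_error_dangling_reference")
  }
  per_sample <- rra |>
    mutate(score = scores[.data$taxon_id]) |>
    group_by(.data$sample_id) |>
    summarise(
      natural_pct = 100 * sum(.data$rra[.data$score == 0]) / sum(.data$rra),
      uncertain_pct = 100 * sum(.data$rra[.data$score == 0.5]) / sum(.data$rra),
      anthropogenic_pct = 100 * sum(.data$rra[.data$score == 1]) / sum(.data$rra),
      .groups = "drop") |>
    rename(unit = "sample_id")
  if (by == "sample") return(per_sample)
  if (is.null(samples)) {
    fd_abort("group partition needs the samples table",
             class = "fd_error_bad_value")
  }
  per_sample |>
    left_join(select(samples, all_of(c("sample_id", "group"))),
              by = c(unit = "sample_id")) |>
    group_by(unit = .data$group) |>
    summarise(across(all_of(c("natural_pct", "uncertain_pct",
                              "anthropogenic_pct")), mean),
              .groups = "drop")
}

#' Bound the anthropogenic share by allocating the uncertain mass
#'
#' The confidently anthropogenic percentage is a minimum: taxa of uncertain
#' origin may hide further human-derived food. Three allocation rules give an
#' upper estimate: `none` keeps the minimum, `half` adds half of the
#' uncertain mass, and `proportional` splits the uncertain mass between the
#' natural and anthropogenic categories in proportion to their observed
#' shares.
#'
#' @param partition One-row diet partition (tibble or list with
#'   `natural_pct`, `uncertain_pct`, `anthropogenic_pct`).
#' @param rule Allocation rule: `"none"`, `"half"`, or `"proportional"`.
#' @return Named numeric vector `c(min_anthropogenic, max_estimate)`.
#' @export
allocate_uncertain <- function(partition, rule = c("none", "half", "proportional")) {
  rule <- match.arg(rule)
  A <- partition$anthropogenic_pct
  U <- partition$uncertain_pct
  N <- partition$natural_pct
  stopifnot(length(A) == 1, length(U) == 1, length(N) == 1)
  if (abs(A + U + N - 100) > 1e-6) {
    fd_abort("partition percentages must sum to 100",
             class = "fd_error_bad_value")
  }
  max_est <- switch(rule,
    none = A,
    half = A + U / 2,
    proportional = {
      if (A + N == 0) {
        fd_abort("proportional allocation undefined when all mass is uncertain",
                 class = "fd_error_bad_value")
      }
      A + U * A / (A + N)
    })
  c(min_anthropogenic = A, max_estimate = max_est)
}

#' Kernel-density summary of per-sample anthropogenic percentages by group
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a grid clipped to \[0, 100\] and renormalised so the density
#' integrates to one over the grid (mass that the unbounded kernel would
#' place outside the percentage scale is folded back proportionally).
#'
#' @param anthro Tibble (`sample_id`, `anthropogenic_pct`).
#' @param samples Sample metadata providing the `group` of each sample.
#' @param n_grid Number of evaluation points (default 512).
#' @return List with `density` (tibble `group`, `x`, `y`) and `summary`
#'   (tibble `group`, `mean`, `median`, `n`).
#' @export
anthropogenic_density <- function(anthro, samples, n_grid = 512) {
  df <- anthro |>
    left_join(select(samples, all_of(c("sample_id", "group"))), by = "sample_id")
  groups <- split(df, df$group)
  if (any(vapply(groups, nrow, 1L) < 2)) {
    fd_abort("each group needs at least 2 samples for a density estimate",
             class = "fd_error_bad_value")
  }
  dens <- purrr::map(groups, function(g) {
    x <- g$anthropogenic_pct
    bw <- stats::bw.nrd0(x)
    if (!is.finite(bw) || bw <= 0) bw <- 0.5  # degenerate: all values equal
    d <- density(x, bw = bw, from = 0, to = 100, n = n_grid)
    dx <- d$x[2] - d$x[1]
    mass <- sum(d$y) * dx
    tibble(group = g$group[1], x = d$x, y = d$y / mass)
  })
  summ <- df |>
    group_by(.data$group) |>
    summarise(mean = mean(.data$anthropogenic_pct),
              median = stats::median(.data$anthropogenic_pct),
              n = n(), .groups = "drop")
  list(density = bind_rows(dens), summary = summ)
}
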