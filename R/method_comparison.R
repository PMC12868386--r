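#' Collapse taxa to the genus level or higher
#'
#' Observational records are taxonomically precise only up to genus, so
#' cross-method comparisons are done at genus level or higher: species map to
#' their genus label; genus and coarser ranks map to themselves. The mapping
#' is idempotent.
#'
#' @param taxa Taxon table (`taxon_id`, `rank`, `genus_or_higher_label`).
#' @return Named character vector, taxon_id -> harmonized label.
#' @export
harmonize_to_rank <- function(taxa) {
  assert_columns(taxa, c("taxon_id", "rank", "genus_or_higher_label"), "taxa")
  bad <- taxa$rank == "species" &
    (is.na(taxa$genus_or_higher_label) | taxa$genus_or_higher_label == "")
  if (any(bad)) {
    fd_abort(sprintf("species '%s' lacks a genus label",
                     taxa$taxon_id[which(bad)[1]]),
             class = "fd_error_bad_value")
  }
  lab <- ifelse(taxa$rank == "species", taxa$genus_or_higher_label,
                ifelse(is.na(taxa$genus_or_higher_label) |
                         taxa$genus_or_higher_label == "",
                       taxa$taxon_id, taxa$genus_or_higher_label))
  setNames(lab, taxa$taxon_id)
}

#' Feeding-time proportions from focal-follow observations
#'
#' Treats seconds of active feeding as relative abundance: each harmonized
#' taxon's proportion is its total feeding seconds divided by all feeding
#' seconds recorded in the date window.
#'
#' @param obs Focal observations (`individual_id`, `date`, `taxon_id`,
#'   `seconds`, `food_class`).
#' @param taxa Taxon table used to harmonize taxa to genus level or higher.
#' @param window Length-2 `Date` vector (inclusive start, inclusive end), or
#'   `NULL` for all records.
#' @return Tibble (`label`, `seconds`, `p_obs`); `p_obs` sums to 1.
#' @export
observation_proportions <- function(obs, taxa, window = NULL) {
  mapping <- harmonize_to_rank(taxa)
  if (!is.null(window)) {
    window <- as.Date(window)
    obs <- filter(obs, .data$date >= window[1], .data$date <= window[2])
  }
  if (nrow(obs) == 0 || sum(obs$seconds) == 0) {
    fd_abort("no feeding seconds recorded in the requested window",
             class = "fd_error_bad_value")
  }
  obs |>
    mutate(label = unname(mapping[.data$taxon_id])) |>
    group_by(.data$label) |>
    summarise(seconds = sum(.data$seconds), .groups = "drop") |>
    mutate(p_obs = .data$seconds / sum(.data$seconds)) |>
    arrange(dplyr::desc(.data$p_obs))
}

#' Diet-wide eDNA proportions at genus level or higher
#'
#' Sums RRA over all samples per harmonized taxon and normalises by the total
#' summed RRA, yielding the eDNA analogue of the observational feeding-time
#' proportions.
#'
#' @param rra Long per-sample RRA tibble (`sample_id`, `taxon_id`, `rra`).
#' @param taxa Taxon table used for harmonization.
#' @return Tibble (`label`, `rra_sum`, `p_edna`); `p_edna` sums to 1.
#' @export
edna_proportions <- function(rra, taxa) {
  mapping <- harmonize_to_rank(taxa)
  rra |>
    mutate(label = unname(mapping[.data$taxon_id])) |>
    group_by(.data$label) |>
    summarise(rra_sum = sum(.data$rra), .groups = "drop") |>
    mutate(p_edna = .data$rra_sum / sum(.data$rra_sum)) |>
    arrange(dplyr::desc(.data$p_edna))
}

#' Match observational and eDNA diet proportions taxon by taxon
#'
#' Both proportion vectors are computed over their full taxon sets (relative
#' to the whole diet each method sees) and are never renormalised after
#' matching; the matched set is the taxa with nonzero mass in both methods.
#'
#' @param rra Long per-sample RRA tibble.
#' @param obs Focal observations.
#' @param taxa Taxon table.
#' @param window Optional date window passed to [observation_proportions()].
#' @return List with `matched` (tibble `label`, `p_obs`, `p_edna`),
#'   `obs` and `edna` (the full per-method proportion tables).
#' @export
match_proportions <- function(rra, obs, taxa, window = NULL) {
  p_obs <- observation_proportions(obs, taxa, window = window)
  p_edna <- edna_proportions(rra, taxa)
  matched <- inner_join(select(p_obs, all_of(c("label", "p_obs"))),
                        select(p_edna, all_of(c("label", "p_edna"))),
                        by = "label") |>
    filter(.data$p_obs > 0, .data$p_edna > 0)
  list(matched = matched, obs = p_obs, edna = p_edna)
}

#' Venn partition of detected taxa by method and food class
#'
#' Splits the union of harmonized taxa detected by the two methods into
#' `shared`, `obs_only` and `edna_only` cells, carrying each taxon's food
#' class. The cells are disjoint and their union is the union of the inputs.
#'
#' @param obs_labels Character vector of taxa detected observationally.
#' @param edna_labels Character vector of taxa detected by eDNA.
#' @param classes Optional named vector, label -> food class
#'   (`natural` / `anthropogenic` / `uncertain`).
#' @return Tibble (`label`, `cell`, `class`).
#' @export
venn_partition <- function(obs_labels, edna_labels, classes = NULL) {
  obs_labels <- unique(obs_labels)
  edna_labels <- unique(edna_labels)
  all_labels <- sort(union(obs_labels, edna_labels))
  cell <- ifelse(all_labels %in% obs_labels & all_labels %in% edna_labels,
                 "shared",
                 ifelse(all_labels %in% obs_labels, "obs_only", "edna_only"))
  cls <- if (is.null(classes)) NA_character_ else
    unname(classes[all_labels])
  tibble(label = all_labels, cell = cell, class = cls)
}

#' Assign records to consecutive monthly periods
#'
#' The study window is cut into consecutive blocks of the given lengths
#' (alternating 33- and 32-day "months" by default), half-open on the right:
#' a date lands in period `k` when it falls in
#' `[start + sum(len[<k]), start + sum(len[<=k]))`.
#'
#' @param dates Vector of `Date`s.
#' @param window_start First day of period 1.
#' @param period_lengths Integer block lengths in days (default
#'   `c(33, 32, 33, 32)`, a 130-day window).
#' @return Integer vector of period indices (1-based).
#' @export
periodize <- function(dates, window_start, period_lengths = c(33, 32, 33, 32)) {
  dates <- as.Date(dates)
  window_start <- as.Date(window_start)
  offset <- as.integer(dates - window_start)
  total <- sum(period_lengths)
  if (any(offset < 0 | offset >= total)) {
    i <- which(offset < 0 | offset >= total)[1]
    fd_abort(sprintf("date %s is outside the covered span [%s, %s)",
                     format(dates[i]), format(window_start),
                     format(window_start + total)),
             class = "fd_error_bad_value")
  }
  findInterval(offset, cumsum(c(0, period_lengths[-length(period_lengths)])))
}

#' Logit transform of a proportion
#'
#' `log(p / (1 - p))`, with proportions of exactly 0 or 1 clamped to
#' `[eps, 1 - eps]` first so that boundary detections (a taxon seen by only
#' one method contributing zero mass) stay finite.
#'
#' @param p Numeric vector of proportions in \[0, 1\].
#' @param eps Clamping guard (default 1e-6).
#' @return Numeric vector of logits.
#' @export
logit <- function(p, eps = 1e-6) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    fd_abort("proportions must lie in [0, 1]", class = "fd_error_bad_value")
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Ordinary least-squares agreement between eDNA and observational diets
#'
#' Regresses the eDNA proportion on the observational proportion over the
#' matched taxon set, optionally on the logit scale (the package's default
#' presentation, which prevents a few dominant taxa from driving the fit).
#'
#' @param matched Matched-proportion tibble (`label`, `p_obs`, `p_edna`)
#'   from [match_proportions()].
#' @param transform `"logit"` (default) or `"none"`.
#' @param eps Clamping guard for the logit (default 1e-6).
#' @return List (`slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `transform`).
#' @export
regress_methods <- function(matched, transform = c("logit", "none"),
                            eps = 1e-6) {
  transform <- match.arg(transform)
  if (nrow(matched) < 3) {
    fd_abort("method regression needs at least 3 matched taxa",
             class = "fd_error_bad_value")
  }
  x <- matched$p_obs
  y <- matched$p_edna
  if (transform == "logit") {
    x <- logit(x, eps = eps)
    y <- logit(y, eps = eps)
  }
  if (sd(x) == 0) {
    fd_abort("zero variance in the observational proportions",
             class = "fd_error_bad_value")
  }
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # perfect fits trip a precision warning
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2, 4],
       n = nrow(matched),
       transform = transform)
}
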