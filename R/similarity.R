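#' Bray-Curtis dissimilarity between sample diet profiles
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` over taxa; 0 for identical
#' compositions, 1 for disjoint support. Computation is delegated to
#' [vegan::vegdist()].
#'
#' @param rra Samples-by-taxa RRA matrix (see [rra_matrix()]), rows on the
#'   unit simplex.
#' @return Symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(rra) {
  if (is.null(dim(rra)) || nrow(rra) == 0 || ncol(rra) == 0) {
    fd_abort("empty RRA matrix", class = "fd_error_bad_value")
  }
  d <- as.matrix(vegan::vegdist(rra, method = "bray"))
  diag(d) <- 0
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Multi-start NMDS via [vegan::metaMDS()]; returns the lowest-stress
#' embedding across random starts. Deterministic for a fixed `seed`.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param k Embedding dimension (default 2); must be below the number of
#'   samples.
#' @param n_starts Random starts (default 20).
#' @param seed Integer RNG seed.
#' @return List (`coordinates` — tibble `sample_id`, `NMDS1`, ... —,
#'   `stress` — Kruskal stress-1 as a fraction —, `k`, `converged`).
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1) {
  d <- as.matrix(d)
  if (k < 1) fd_abort("k must be >= 1", class = "fd_error_bad_value")
  if (k >= nrow(d)) {
    fd_abort("embedding dimension k must be below the number of samples",
             class = "fd_error_bad_value")
  }
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(stats::as.dist(d), k = k, try = n_starts,
                   trymax = n_starts, trace = 0, autotransform = FALSE,
                   wascores = FALSE)))
  coords <- as_tibble(fit$points, rownames = "sample_id")
  names(coords)[-1] <- paste0("NMDS", seq_len(k))
  list(coordinates = coords, stress = fit$stress, k = k,
       converged = isTRUE(fit$converged))
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances with a permutation
#' p-value using the add-one estimator
#' `p = (1 + #\{permuted F >= observed F\}) / (1 + n_permutations)`.
#' Delegates to [vegan::adonis2()].
#'
#' @param d Symmetric dissimilarity matrix.
#' @param labels Factor (or coercible) of group labels, one per sample; at
#'   least 2 levels with at least 2 samples each.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return List (`pseudo_f`, `r_squared`, `p_value`, `n_permutations`,
#'   `seed`).
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  labels <- factor(labels)
  if (length(labels) != nrow(d)) {
    fd_abort("one label per sample is required", class = "fd_error_bad_value")
  }
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    fd_abort("labels need >= 2 levels with >= 2 samples each",
             class = "fd_error_bad_value")
  }
  set.seed(seed)
  df <- data.frame(labels = labels)
  fit <- vegan::adonis2(stats::as.dist(d) ~ labels, data = df,
                        permutations = n_permutations)
  list(pseudo_f = fit$F[1], r_squared = fit$R2[1], p_value = fit$`Pr(>F)`[1],
       n_permutations = n_permutations, seed = seed)
}

#' Relationship category for a pair of faecal samples
#'
#' `"Same individual"` when both samples come from one individual,
#' `"Mother-Infant"` when one sample's individual is the recorded mother of
#' the other's, else `"Other"`. Symmetric in its arguments.
#'
#' @param sample_i,sample_j Sample ids.
#' @param samples Sample metadata table.
#' @return Character scalar category.
#' @export
relationship_category <- function(sample_i, sample_j, samples) {
  meta <- samples[match(c(sample_i, sample_j), samples$sample_id), ]
  if (any(is.na(meta$sample_id))) {
    fd_abort(sprintf("unknown sample id: %s",
                     paste(setdiff(c(sample_i, sample_j), samples$sample_id),
                           collapse = ", ")),
             class = "fd_error_dangling_reference")
  }
  relationship_vec(meta$individual_id[1], meta$individual_id[2],
                   meta$mother_id[1], meta$mother_id[2])
}

# Vectorised relationship classification on individual/mother ids.
relationship_vec <- function(ind_i, ind_j, mother_i, mother_j) {
  same <- ind_i == ind_j
  mi <- (!is.na(mother_i) & mother_i == ind_j) |
    (!is.na(mother_j) & mother_j == ind_i)
  ifelse(same, "Same individual", ifelse(mi, "Mother-Infant", "Other"))
}

#' Build the standardized pairwise dietary-similarity table
#'
#' One row per unordered sample pair: similarity is `1 - Bray-Curtis`
#' dissimilarity, z-standardized over all retained pairs (`similarity_z` has
#' mean 0, sd 1). Covariates are unordered category combinations (e.g.
#' `sex_combo` in FF/FM/MM), the relationship category, and single-factor
#' encodings of the individual pair and date pair for use as random
#' intercepts in dyadic mixed models. By default only within-group pairs are
#' retained (`group` is then the shared group); `scope = "all"` keeps
#' cross-group pairs, labelled `"cross-group"`.
#'
#' @param d Bray-Curtis dissimilarity matrix over samples.
#' @param samples Sample metadata table.
#' @param scope `"within-group"` (default) or `"all"`.
#' @return Tibble with columns `sample_i`, `sample_j`, `similarity`,
#'   `similarity_z`, `group`, `relationship`, `sex_combo`, `age_combo`,
#'   `individual_i`, `individual_j`, `individual_pair`, `date_i`, `date_j`,
#'   `date_pair`.
#' @export
build_pairwise_table <- function(d, samples, scope = c("within-group", "all")) {
  scope <- match.arg(scope)
  d <- as.matrix(d)
  ids <- rownames(d)
  meta <- samples[match(ids, samples$sample_id), ]
  if (any(is.na(meta$sample_id))) {
    fd_abort("distance matrix contains samples absent from the metadata",
             class = "fd_error_dangling_reference")
  }
  tab <- pairwise_design(meta, scope = scope)
  i <- match(tab$sample_i, ids)
  j <- match(tab$sample_j, ids)
  tab$similarity <- 1 - d[cbind(i, j)]
  if (nrow(tab) == 0) {
    fd_abort("no sample pairs retained", class = "fd_error_bad_value")
  }
  if (sd(tab$similarity) == 0) {
    fd_abort("similarity is constant across pairs; cannot standardize",
             class = "fd_error_bad_value")
  }
  tab |>
    mutate(similarity_z = (.data$similarity - mean(.data$similarity)) /
             sd(.data$similarity)) |>
    select(all_of(c("sample_i", "sample_j", "similarity", "similarity_z",
                    "group", "relationship", "sex_combo", "age_combo",
                    "individual_i", "individual_j", "individual_pair",
                    "date_i", "date_j", "date_pair")))
}

# Dyadic design over unordered sample pairs: relationship, covariate combos
# and pair-factor encodings, without any similarity values.
pairwise_design <- function(meta, scope = c("within-group", "all")) {
  scope <- match.arg(scope)
  n <- nrow(meta)
  if (n < 2) fd_abort("need at least 2 samples", class = "fd_error_bad_value")
  pairs <- combn(n, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  tab <- tibble(
    sample_i = meta$sample_id[i], sample_j = meta$sample_id[j],
    group_i = meta$group[i], group_j = meta$group[j],
    individual_i = meta$individual_id[i],
    individual_j = meta$individual_id[j],
    date_i = meta$date[i], date_j = meta$date[j],
    relationship = relationship_vec(meta$individual_id[i],
                                    meta$individual_id[j],
                                    meta$mother_id[i], meta$mother_id[j]),
    sex_combo = combo_label(meta$sex[i], meta$sex[j]),
    age_combo = combo_label(substr(meta$age_class[i], 1, 1),
                            substr(meta$age_class[j], 1, 1))
  ) |>
    mutate(
      group = ifelse(.data$group_i == .data$group_j, .data$group_i,
                     "cross-group"),
      individual_pair = combo_label(.data$individual_i, .data$individual_j,
                                    sep = ":"),
      date_pair = combo_label(format(.data$date_i), format(.data$date_j),
                              sep = ":")
    ) |>
    select(-all_of(c("group_i", "group_j")))
  if (scope == "within-group") {
    tab <- filter(tab, .data$group != "cross-group")
  }
  tab
}
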