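# Brute-force reference implementations, written as naive loops over plain
# data frames, independent of the package's vectorized code paths.

# Full QC chain: library-wide min-reads filter, replicate-consensus filter,
# per-replicate RRA, mean-RRA merge with renormalization.
oracle_pipeline <- function(reads, threshold = 10, min_support = 2) {
  df <- as.data.frame(reads)

  # 1. min reads per (marker, taxon) across the whole library
  keep <- rep(TRUE, nrow(df))
  for (m in unique(df$marker)) {
    for (t in unique(df$taxon_id[df$marker == m])) {
      sel <- df$marker == m & df$taxon_id == t
      if (sum(df$reads[sel]) < threshold) keep[sel] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]

  # 2a. successful replicates and sample exclusion
  ok_rep <- list()
  for (s in unique(df$sample_id)) {
    reps <- c()
    for (r in unique(df$replicate[df$sample_id == s])) {
      if (sum(df$reads[df$sample_id == s & df$replicate == r]) > 0) {
        reps <- c(reps, r)
      }
    }
    if (length(reps) >= min_support) ok_rep[[s]] <- reps
  }
  df <- df[df$sample_id %in% names(ok_rep), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!(df$replicate[i] %in% ok_rep[[df$sample_id[i]]])) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]

  # 2b. per-sample replicate support per taxon
  keep <- rep(TRUE, nrow(df))
  for (s in unique(df$sample_id)) {
    for (t in unique(df$taxon_id[df$sample_id == s])) {
      support <- 0
      for (r in ok_rep[[s]]) {
        sel <- df$sample_id == s & df$replicate == r & df$taxon_id == t
        if (sum(df$reads[sel]) > 0) support <- support + 1
      }
      if (support < min_support) {
        keep[df$sample_id == s & df$taxon_id == t] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]

  # 3. per-replicate RRA (markers pooled), then mean-merge + renormalize
  out <- list()
  for (s in unique(df$sample_id)) {
    reps <- c()
    for (r in unique(df$replicate[df$sample_id == s])) {
      if (sum(df$reads[df$sample_id == s & df$replicate == r]) > 0) {
        reps <- c(reps, r)
      }
    }
    if (length(reps) == 0) next
    taxa <- unique(df$taxon_id[df$sample_id == s])
    acc <- setNames(rep(0, length(taxa)), taxa)
    for (r in reps) {
      sel <- df$sample_id == s & df$replicate == r
      tot <- sum(df$reads[sel])
      for (t in taxa) {
        acc[t] <- acc[t] + sum(df$reads[sel & df$taxon_id == t]) / tot
      }
    }
    mean_rra <- acc / length(reps)
    mean_rra <- mean_rra / sum(mean_rra)
    mean_rra <- mean_rra[mean_rra > 0]
    out[[s]] <- data.frame(sample_id = s, taxon_id = names(mean_rra),
                           rra = unname(mean_rra))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$taxon_id), , drop = FALSE]
}

oracle_anthro <- function(rra_row, scores) {
  num <- 0; den <- 0
  for (t in names(rra_row)) {
    num <- num + scores[[t]] * rra_row[[t]]
    den <- den + rra_row[[t]]
  }
  100 * num / den
}

oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (k in seq_along(x)) {
    num <- num + abs(x[k] - y[k])
    den <- den + x[k] + y[k]
  }
  unname(num / den)
}

# PERMANOVA sums of squares from the distance matrix by double loop.
oracle_permanova_r2 <- function(d, labels) {
  n <- nrow(d)
  ss_total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_total <- ss_total + d[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ng <- length(idx)
    if (ng < 2) next
    ssg <- 0
    for (a in seq_len(ng - 1)) {
      for (b in (a + 1):ng) ssg <- ssg + d[idx[a], idx[b]]^2
    }
    ss_within <- ss_within + ssg / ng
  }
  (ss_total - ss_within) / ss_total
}

# Random read-count fixture: small tables with sparse counts, some zero rows
# and uneven replicate structure.
random_reads <- function(n_samples = 4, n_taxa = 6, n_reps = 3) {
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  rows <- list()
  for (s in seq_len(n_samples)) {
    for (r in seq_len(n_reps)) {
      present <- which(stats::runif(n_taxa) < 0.6)
      if (length(present) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("s%02d", s), replicate = r,
        marker = ifelse(present <= n_taxa / 2, "plant", "vertebrate"),
        taxon_id = taxa[present],
        reads = as.integer(stats::rpois(length(present), lambda = 40) *
                             stats::rbinom(length(present), 1, 0.9)))
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

random_simplex <- function(n, k) {
  m <- matrix(stats::rgamma(n * k, shape = 1), nrow = n)
  m <- m / rowSums(m)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  colnames(m) <- sprintf("t%02d", seq_len(k))
  m
}
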