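#' Read a diet dataset bundle from TSV files
#'
#' Loads and cross-validates the four tabular artefacts of a faecal
#' metabarcoding diet study: per-replicate read counts, taxon metadata with
#' provenance scores, sample metadata, and (optionally) focal-follow feeding
#' observations. All tables are UTF-8 TSV with a mandatory header; missing
#' values are the literal `NA`; dates are ISO 8601 (`YYYY-MM-DD`).
#'
#' Validation is strict and referential: every `taxon_id` in the read table
#' must exist in the taxon table, every `sample_id` must exist in the sample
#' table, enums must take their documented values, and provenance scores (when
#' present) must be exactly one of 0, 0.5, 1. Each failure raises a classed
#' condition (`fd_error_missing_column`, `fd_error_bad_enum`,
#' `fd_error_dangling_reference`, `fd_error_duplicate_key`,
#' `fd_error_bad_date`, `fd_error_bad_value`) whose message names the file,
#' row and field.
#'
#' @param dir Directory containing `reads.tsv`, `taxa.tsv`, `samples.tsv` and
#'   optionally `focal.tsv`. Ignored for any table whose path is given
#'   explicitly.
#' @param reads,taxa,samples,focal Optional explicit file paths overriding the
#'   `dir` defaults. `focal` may be `NULL` (observations are optional).
#'
#' @return A `diet_bundle`: a list with tibbles `reads`, `taxa`, `samples`
#'   and `observations` (`NULL` when absent).
#' @seealso [write_bundle()], [validate_scores()]
#' @export
read_bundle <- function(dir = NULL, reads = NULL, taxa = NULL,
                        samples = NULL, focal = NULL) {
  path_for <- function(given, name, required = TRUE) {
    if (!is.null(given)) {
      if (!file.exists(given)) {
        fd_abort(sprintf("file not found: %s", given),
                 class = "fd_error_missing_file")
      }
      return(given)
    }
    if (is.null(dir)) {
      if (required) {
        fd_abort(sprintf("no path given for %s and no directory supplied", name),
                 class = "fd_error_missing_file")
      }
      return(NULL)
    }
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      if (required) {
        fd_abort(sprintf("file not found: %s", p),
                 class = "fd_error_missing_file")
      }
      return(NULL)
    }
    p
  }

  reads_path <- path_for(reads, "reads.tsv")
  taxa_path <- path_for(taxa, "taxa.tsv")
  samples_path <- path_for(samples, "samples.tsv")
  focal_path <- path_for(focal, "focal.tsv", required = FALSE)

  read_tsv_strict <- function(path) {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    na = "NA", progress = FALSE)
  }

  reads_tbl <- validate_reads_table(read_tsv_strict(reads_path), basename(reads_path))
  taxa_tbl <- validate_taxa_table(read_tsv_strict(taxa_path), basename(taxa_path))
  samples_tbl <- validate_samples_table(read_tsv_strict(samples_path), basename(samples_path))
  obs_tbl <- if (!is.null(focal_path)) {
    validate_focal_table(read_tsv_strict(focal_path), basename(focal_path))
  } else {
    NULL
  }

  new_bundle(reads_tbl, taxa_tbl, samples_tbl, obs_tbl,
             files = c(reads = reads_path, taxa = taxa_path,
                       samples = samples_path,
                       focal = focal_path %||% NA_character_))
}

#' Assemble and validate a diet bundle from in-memory tables
#'
#' @param reads Tibble of per-replicate read counts
#'   (`sample_id`, `replicate`, `marker`, `taxon_id`, `reads`).
#' @param taxa Tibble of taxon metadata (`taxon_id`, `rank`,
#'   `genus_or_higher_label`, `marker`, `provenance_score`).
#' @param samples Tibble of sample metadata (`sample_id`, `individual_id`,
#'   `group`, `sex`, `age_class`, `mother_id`, `date`).
#' @param observations Optional tibble of focal-follow feeding records
#'   (`individual_id`, `date`, `taxon_id`, `seconds`, `food_class`).
#' @param files Internal; provenance of the tables.
#' @return A `diet_bundle` list.
#' @export
new_bundle <- function(reads, taxa, samples, observations = NULL,
                       files = NULL) {
  reads <- validate_reads_table(reads, "reads")
  taxa <- validate_taxa_table(taxa, "taxa")
  samples <- validate_samples_table(samples, "samples")
  if (!is.null(observations)) {
    observations <- validate_focal_table(observations, "focal")
  }

  check_reference(unique(reads$taxon_id), taxa$taxon_id,
                  "reads", "taxon_id", "taxa")
  check_reference(unique(reads$sample_id), samples$sample_id,
                  "reads", "sample_id", "samples")
  if (!is.null(observations)) {
    check_reference(unique(observations$taxon_id), taxa$taxon_id,
                    "focal", "taxon_id", "taxa")
    check_reference(unique(observations$individual_id),
                    samples$individual_id, "focal", "individual_id", "samples")
  }
  check_mothers(samples)

  structure(
    list(reads = reads, taxa = taxa, samples = samples,
         observations = observations, files = files),
    class = "diet_bundle"
  )
}

#' @export
print.diet_bundle <- function(x, ...) {
  cat("<diet_bundle>\n")
  cat(sprintf("  reads:        %d rows (%d samples, %d taxa)\n",
              nrow(x$reads), dplyr::n_distinct(x$reads$sample_id),
              dplyr::n_distinct(x$reads$taxon_id)))
  cat(sprintf("  taxa:         %d taxa (%d scored)\n", nrow(x$taxa),
              sum(!is.na(x$taxa$provenance_score))))
  cat(sprintf("  samples:      %d samples, %d individuals, %d group(s)\n",
              nrow(x$samples), dplyr::n_distinct(x$samples$individual_id),
              dplyr::n_distinct(x$samples$group)))
  if (is.null(x$observations)) {
    cat("  observations: none\n")
  } else {
    cat(sprintf("  observations: %d feeding records\n", nrow(x$observations)))
  }
  invisible(x)
}

#' Write a diet bundle to TSV files
#'
#' Emits the bundle's tables in the package's fixed TSV dialect with stable
#' row order (sorted by primary keys), so that writing the same bundle twice
#' produces byte-identical files. The observations file is only written when
#' observations are present.
#'
#' @param bundle A `diet_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "diet_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  fmt_date <- function(d) format(d, "%Y-%m-%d")

  reads <- bundle$reads |>
    arrange(.data$sample_id, .data$replicate, .data$marker, .data$taxon_id)
  taxa <- bundle$taxa |> arrange(.data$taxon_id)
  samples <- bundle$samples |>
    arrange(.data$sample_id) |>
    mutate(date = fmt_date(.data$date))

  paths <- c(reads = file.path(dir, "reads.tsv"),
             taxa = file.path(dir, "taxa.tsv"),
             samples = file.path(dir, "samples.tsv"))
  readr::write_tsv(reads, paths[["reads"]], na = "NA", progress = FALSE)
  readr::write_tsv(taxa, paths[["taxa"]], na = "NA", progress = FALSE)
  readr::write_tsv(samples, paths[["samples"]], na = "NA", progress = FALSE)

  if (!is.null(bundle$observations)) {
    obs <- bundle$observations |>
      arrange(.data$individual_id, .data$date, .data$taxon_id) |>
      mutate(date = fmt_date(.data$date))
    paths <- c(paths, focal = file.path(dir, "focal.tsv"))
    readr::write_tsv(obs, paths[["focal"]], na = "NA", progress = FALSE)
  }
  invisible(paths)
}

#' Report taxa lacking a provenance score
#'
#' Provenance scores (0 = natural, 0.5 = uncertain, 1 = anthropogenic) are
#' expert-assigned inputs; this reports which taxa still need one. It never
#' mutates its input; malformed scores are rejected at read time, not here.
#'
#' @param taxa A taxon table (tibble with `taxon_id` and `provenance_score`).
#' @return Tibble of the unscored taxa (zero rows when all are scored).
#' @export
validate_scores <- function(taxa) {
  assert_columns(taxa, c("taxon_id", "provenance_score"), "taxa")
  taxa |>
    filter(is.na(.data$provenance_score)) |>
    select(all_of(intersect(c("taxon_id", "rank", "genus_or_higher_label"),
                            names(taxa))))
}

# ---- internal table validators ------------------------------------------

taxon_ranks <- c("species", "genus", "tribe", "subfamily", "family",
                 "order", "subclass")

validate_reads_table <- function(df, file) {
  assert_columns(df, c("sample_id", "replicate", "marker", "taxon_id", "reads"),
                 file)
  df <- as_tibble(df) |>
    mutate(sample_id = as.character(.data$sample_id),
           replicate = as.integer(.data$replicate),
           marker = as.character(.data$marker),
           taxon_id = as.character(.data$taxon_id),
           reads = suppressWarnings(as.integer(.data$reads)))
  assert_enum(df$marker, c("plant", "vertebrate"), "marker", file)
  if (any(is.na(df$replicate)) || any(df$replicate < 1)) {
    fd_abort(sprintf("%s: field 'replicate' must be a positive integer", file),
             class = "fd_error_bad_value")
  }
  if (any(is.na(df$reads)) || any(df$reads < 0)) {
    i <- which(is.na(df$reads) | df$reads < 0)[1]
    fd_abort(sprintf("%s: row %d: field 'reads' must be a non-negative integer",
                     file, i),
             class = "fd_error_bad_value")
  }
  dup <- df |>
    count(.data$sample_id, .data$replicate, .data$marker, .data$taxon_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    fd_abort(sprintf(
      "%s: duplicate (sample, replicate, marker, taxon) key: (%s, %d, %s, %s)",
      file, dup$sample_id[1], dup$replicate[1], dup$marker[1], dup$taxon_id[1]),
      class = "fd_error_duplicate_key")
  }
  select(df, all_of(c("sample_id", "replicate", "marker", "taxon_id", "reads")))
}

validate_taxa_table <- function(df, file) {
  assert_columns(df, c("taxon_id", "rank", "genus_or_higher_label", "marker",
                       "provenance_score"), file)
  df <- as_tibble(df) |>
    mutate(taxon_id = as.character(.data$taxon_id),
           rank = as.character(.data$rank),
           genus_or_higher_label = as.character(.data$genus_or_higher_label),
           marker = as.character(.data$marker),
           provenance_score = suppressWarnings(as.numeric(.data$provenance_score)))
  if (anyDuplicated(df$taxon_id)) {
    d <- df$taxon_id[duplicated(df$taxon_id)][1]
    fd_abort(sprintf("%s: duplicate taxon_id '%s'", file, d),
             class = "fd_error_duplicate_key")
  }
  assert_enum(df$rank, taxon_ranks, "rank", file)
  assert_enum(df$marker, c("plant", "vertebrate"), "marker", file)
  bad <- !is.na(df$provenance_score) & !(df$provenance_score %in% c(0, 0.5, 1))
  if (any(bad)) {
    i <- which(bad)[1]
    fd_abort(sprintf(
      "%s: row %d: field 'provenance_score' is %s; must be one of 0, 0.5, 1",
      file, i, format(df$provenance_score[i])),
      class = "fd_error_bad_enum")
  }
  missing_label <- df$rank == "species" &
    (is.na(df$genus_or_higher_label) | df$genus_or_higher_label == "")
  if (any(missing_label)) {
    i <- which(missing_label)[1]
    fd_abort(sprintf("%s: row %d: species '%s' lacks a genus label",
                     file, i, df$taxon_id[i]),
             class = "fd_error_bad_value")
  }
  select(df, all_of(c("taxon_id", "rank", "genus_or_higher_label", "marker",
                      "provenance_score")))
}

validate_samples_table <- function(df, file) {
  assert_columns(df, c("sample_id", "individual_id", "group", "sex",
                       "age_class", "mother_id", "date"), file)
  df <- as_tibble(df) |>
    mutate(sample_id = as.character(.data$sample_id),
           individual_id = as.character(.data$individual_id),
           group = as.character(.data$group),
           sex = as.character(.data$sex),
           age_class = as.character(.data$age_class),
           mother_id = as.character(.data$mother_id))
  df$date <- as_iso_date(df$date, "date", file)
  assert_enum(df$sex, c("M", "F"), "sex", file)
  assert_enum(df$age_class, c("adult", "juvenile"), "age_class", file)
  if (anyDuplicated(df$sample_id)) {
    d <- df$sample_id[duplicated(df$sample_id)][1]
    fd_abort(sprintf("%s: duplicate sample_id '%s'", file, d),
             class = "fd_error_duplicate_key")
  }
  dup <- df |>
    count(.data$individual_id, .data$date) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    fd_abort(sprintf(
      "%s: individual '%s' re-collected on %s (same-day re-collection is not allowed)",
      file, dup$individual_id[1], format(dup$date[1])),
      class = "fd_error_duplicate_key")
  }
  select(df, all_of(c("sample_id", "individual_id", "group", "sex",
                      "age_class", "mother_id", "date")))
}

validate_focal_table <- function(df, file) {
  assert_columns(df, c("individual_id", "date", "taxon_id", "seconds",
                       "food_class"), file)
  df <- as_tibble(df) |>
    mutate(individual_id = as.character(.data$individual_id),
           taxon_id = as.character(.data$taxon_id),
           seconds = suppressWarnings(as.integer(.data$seconds)),
           food_class = as.character(.data$food_class))
  df$date <- as_iso_date(df$date, "date", file)
  assert_enum(df$food_class, c("natural", "anthropogenic", "unknown"),
              "food_class", file)
  if (any(is.na(df$seconds)) || any(df$seconds < 0)) {
    i <- which(is.na(df$seconds) | df$seconds < 0)[1]
    fd_abort(sprintf("%s: row %d: field 'seconds' must be a non-negative integer",
                     file, i),
             class = "fd_error_bad_value")
  }
  select(df, all_of(c("individual_id", "date", "taxon_id", "seconds",
                      "food_class")))
}

check_reference <- function(keys, universe, file, field, target) {
  dangling <- setdiff(keys, universe)
  if (length(dangling) > 0) {
    fd_abort(sprintf(
      "%s: field '%s' references %s absent from the %s table: %s",
      file, field, if (length(dangling) == 1) "a key" else "keys", target,
      paste(head(dangling, 5), collapse = ", ")),
      class = "fd_error_dangling_reference")
  }
  invisible(TRUE)
}

check_mothers <- function(samples) {
  ind <- samples |>
    distinct(.data$individual_id, .data$group, .data$sex)
  with_mother <- samples |>
    filter(!is.na(.data$mother_id)) |>
    distinct(.data$individual_id, .data$group, .data$mother_id)
  if (nrow(with_mother) == 0) return(invisible(TRUE))
  joined <- with_mother |>
    left_join(ind, by = c("mother_id" = "individual_id"),
              suffix = c("", "_mother"))
  bad <- is.na(joined$sex) | joined$sex != "F" |
    joined$group != joined$group_mother
  if (any(bad)) {
    b <- joined[which(bad)[1], ]
    fd_abort(sprintf(
      "samples: individual '%s' has mother_id '%s' that is not a female of the same group",
      b$individual_id, b$mother_id),
      class = "fd_error_dangling_reference")
  }
  invisible(TRUE)
}
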