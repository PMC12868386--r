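# Internal helpers shared across modules.

# Dirichlet sampler via normalised gamma draws. Coordinates with alpha = 0
# are returned as exact zeros (rgamma(shape = 0) is a point mass at 0), which
# the synthetic generator relies on for zero-diet contaminant taxa.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Unordered combination label for a pair of categorical values, e.g. sex
# combos "FF", "FM", "MM".
combo_label <- function(a, b, sep = "") {
  mapply(function(x, y) paste(sort(c(x, y)), collapse = sep), a, b,
         USE.NAMES = FALSE)
}

fd_abort <- function(message, class, ...) {
  abort(message, class = c(class, "fd_error"), ...)
}

assert_columns <- function(df, cols, file = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    fd_abort(
      sprintf("%s: missing required column(s): %s", file,
              paste(missing, collapse = ", ")),
      class = "fd_error_missing_column"
    )
  }
  invisible(df)
}

assert_enum <- function(x, allowed, field, file = "table", na_ok = FALSE) {
  bad <- !(x %in% allowed)
  if (na_ok) bad <- bad & !is.na(x)
  if (any(bad)) {
    i <- which(bad)[1]
    fd_abort(
      sprintf("%s: row %d: field '%s' has value '%s'; allowed: %s",
              file, i, field, as.character(x[i]),
              paste(allowed, collapse = ", ")),
      class = "fd_error_bad_enum"
    )
  }
  invisible(x)
}

as_iso_date <- function(x, field, file = "table") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(x)
  if (any(bad)) {
    i <- which(bad)[1]
    fd_abort(
      sprintf("%s: row %d: field '%s' value '%s' is not an ISO 8601 date",
              file, i, field, as.character(x[i])),
      class = "fd_error_bad_date"
    )
  }
  d
}
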