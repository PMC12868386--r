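#' Construct one of the two dietary-similarity model specifications
#'
#' Model 1 regresses standardized similarity on the three-way interaction of
#' group, sex combination and age combination, with random intercepts for the
#' individual pair, the date pair and the relationship category:
#' `similarity_z ~ group * sex_combo * age_combo + (1 | individual_pair) +
#' (1 | date_pair) + (1 | relationship)`.
#' Model 2 moves relationship into the fixed part:
#' `similarity_z ~ group * relationship + (1 | individual_pair) +
#' (1 | date_pair)`.
#'
#' Random intercepts on dyadic rows are encoded as single factors over the
#' unordered pair of individual ids and the unordered pair of dates (a
#' pairwise row has no single individual or date of its own).
#'
#' @param model 1 or 2.
#' @return A `similarity_model_spec`: list with `model`, `response`,
#'   `fixed_terms`, `random_terms` and the full `formula`.
#' @export
similarity_model_spec <- function(model = c(1, 2)) {
  model <- as.integer(model[1])
  stopifnot(model %in% c(1L, 2L))
  if (model == 1L) {
    fixed <- "group * sex_combo * age_combo"
    random <- c("(1 | individual_pair)", "(1 | date_pair)",
                "(1 | relationship)")
  } else {
    fixed <- "group * relationship"
    random <- c("(1 | individual_pair)", "(1 | date_pair)")
  }
  f <- as.formula(paste("similarity_z ~", fixed, "+",
                        paste(random, collapse = " + ")))
  structure(
    list(model = model, response = "similarity_z", fixed_terms = fixed,
         random_terms = random, formula = f),
    class = "similarity_model_spec")
}

#' @export
print.similarity_model_spec <- function(x, ...) {
  cat(sprintf("<similarity_model_spec %d>\n  ", x$model))
  print(x$formula, showEnv = FALSE)
  invisible(x)
}

#' Fit a Gaussian mixed model to the pairwise similarity table
#'
#' Fits the requested specification by maximum likelihood with
#' [lme4::lmer()] and tests each fixed term with a Type-II likelihood-ratio
#' test: the term's chi-square compares the model containing it (plus every
#' term not containing it) against the same model without it, so main
#' effects are tested ignoring, not conditioning on, their own interactions.
#' Model-comparison indices (AIC, BIC, RMSE, R-squared of fitted vs
#' observed) are reported alongside.
#'
#' @param table Pairwise similarity table from [build_pairwise_table()] (or
#'   [simulate_similarity_table()]).
#' @param spec A `similarity_model_spec`, or 1/2 as shorthand.
#' @param test_terms Optional character vector restricting which fixed terms
#'   are LRT-tested (default: all).
#' @return A `similarity_fit`: list with `fit` (the lmerMod), `terms`
#'   (tibble `term`, `chisq`, `df`, `p_value`), `indices`
#'   (`aic`, `bic`, `rmse`, `r_squared`), `messages` (convergence and
#'   singularity notes) and `spec`.
#' @export
fit_similarity_model <- function(table, spec = 2, test_terms = NULL) {
  if (!inherits(spec, "similarity_model_spec")) {
    spec <- similarity_model_spec(spec)
  }
  needed <- unique(c("similarity_z", all.vars(spec$formula)))
  assert_columns(table, setdiff(needed, "similarity_z"), "pairwise table")

  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  msgs <- character()
  fit_one <- function(formula) {
    withCallingHandlers(
      suppressMessages(
        lme4::lmer(formula, data = table, REML = FALSE, control = ctrl)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  full <- fit_one(spec$formula)

  fixed_formula <- as.formula(paste("~", spec$fixed_terms))
  all_terms <- attr(terms(fixed_formula), "term.labels")
  if (is.null(test_terms)) test_terms <- all_terms
  random_part <- paste(spec$random_terms, collapse = " + ")

  term_vars <- lapply(all_terms, function(t) strsplit(t, ":", fixed = TRUE)[[1]])
  names(term_vars) <- all_terms

  lrt <- purrr::map(test_terms, function(t) {
    tv <- term_vars[[t]]
    contains_t <- vapply(all_terms, function(u) {
      uv <- term_vars[[u]]
      all(tv %in% uv)
    }, logical(1))
    base_terms <- all_terms[!contains_t]
    rhs_base <- if (length(base_terms) == 0) "1" else
      paste(base_terms, collapse = " + ")
    f_base <- as.formula(paste("similarity_z ~", rhs_base, "+", random_part))
    f_full <- as.formula(paste("similarity_z ~",
                               paste(c(base_terms, t), collapse = " + "),
                               "+", random_part))
    m0 <- fit_one(f_base)
    m1 <- fit_one(f_full)
    chisq <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
    df <- attr(logLik(m1), "df") - attr(logLik(m0), "df")
    tibble(term = t, chisq = chisq, df = df,
           p_value = if (df > 0) pchisq(chisq, df, lower.tail = FALSE)
                     else NA_real_)
  }) |> bind_rows()

  res <- resid(full)
  structure(
    list(fit = full,
         terms = lrt,
         indices = list(aic = AIC(full), bic = BIC(full),
                        rmse = sqrt(mean(res^2)),
                        r_squared = cor(fitted(full), table$similarity_z)^2),
         messages = unique(msgs),
         spec = spec),
    class = "similarity_fit")
}

#' @export
print.similarity_fit <- function(x, ...) {
  cat(sprintf("<similarity_fit model %d>\n", x$spec$model))
  print(x$terms)
  cat(sprintf("AIC %.1f  BIC %.1f  RMSE %.3f  R2 %.3f\n",
              x$indices$aic, x$indices$bic, x$indices$rmse,
              x$indices$r_squared))
  if (length(x$messages) > 0) {
    cat("fitting notes:", paste(x$messages, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Simulate a pairwise similarity table from the dyadic Gaussian model
#'
#' Generates `similarity_z` directly from the mixed model the similarity
#' analysis assumes: the dyadic design (pairs, relationship categories,
#' covariate combos) is built from real or simulated sample metadata, and
#' the response is a Gaussian draw with random intercepts for the individual
#' pair and the date pair plus optional fixed effects. This isolates the
#' model-fitting machinery from the compositional pipeline, so rejection
#' rates under the null and power at a known effect size are meaningful
#' calibrations of the term tests.
#'
#' Effects are expressed on the raw response scale whose residual sd is
#' `sd_residual`; the returned `similarity_z` is the z-scored response.
#'
#' @param samples Sample metadata (e.g. from [simulate_metadata()]).
#' @param group_effect Additive shift for pairs of the last group level.
#' @param same_individual_effect,mother_infant_effect Additive shifts for
#'   the respective relationship categories (defaults 0).
#' @param sd_individual_pair,sd_date_pair Random-intercept standard
#'   deviations (defaults 0.3, 0.2).
#' @param sd_residual Residual standard deviation (default 0.9).
#' @param scope Pair scope as in [build_pairwise_table()].
#' @return A pairwise similarity table suitable for
#'   [fit_similarity_model()].
#' @export
simulate_similarity_table <- function(samples, group_effect = 0,
                                      same_individual_effect = 0,
                                      mother_infant_effect = 0,
                                      sd_individual_pair = 0.3,
                                      sd_date_pair = 0.2,
                                      sd_residual = 0.9,
                                      scope = "within-group") {
  tab <- pairwise_design(samples, scope = scope)
  ip <- unique(tab$individual_pair)
  dp <- unique(tab$date_pair)
  b_ip <- setNames(rnorm(length(ip), sd = sd_individual_pair), ip)
  b_dp <- setNames(rnorm(length(dp), sd = sd_date_pair), dp)
  groups <- sort(unique(tab$group[tab$group != "cross-group"]))
  eta <- ifelse(tab$group == groups[length(groups)], group_effect, 0) +
    ifelse(tab$relationship == "Same individual", same_individual_effect, 0) +
    ifelse(tab$relationship == "Mother-Infant", mother_infant_effect, 0)
  y <- eta + b_ip[tab$individual_pair] + b_dp[tab$date_pair] +
    rnorm(nrow(tab), sd = sd_residual)
  tab$similarity <- unname(y)
  tab$similarity_z <- (tab$similarity - mean(tab$similarity)) /
    sd(tab$similarity)
  tab
}
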