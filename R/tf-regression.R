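#' Stepwise multiple linear regression for one TF
#'
#' Both-direction stepwise least squares on the Akaike information
#' criterion, starting from the intercept-only model (AIC in the
#' least-squares form `n log(RSS/n) + 2k`, as used by [stats::step()] for
#' `lm` fits). Ties on AIC resolve by candidate order, so the procedure is
#' deterministic. The response is one TF's standardized counts across
#' samples; the candidates are the stability z-scores and spatial
#' (polynomial) terms.
#'
#' @param y numeric response vector.
#' @param candidates data frame of candidate predictors (syntactic column
#'   names; see [spatial_terms()]).
#' @param max_steps maximum number of stepwise steps (default 1000).
#' @return object of class `tf_fit`: list with `model` (the `lm`), `terms`,
#'   `r_squared`, `p_values` (per-term two-sided t-tests), `model_p`
#'   (F-test), `aic`.
#' @export
stepwise_fit <- function(y, candidates, max_steps = 1000) {
  stopifnot(length(y) == nrow(candidates))
  if (length(y) < 10L) stop("need at least 10 observations")
  dat <- data.frame(.y = y, candidates, check.names = FALSE)
  # stepwise refits are evaluated in the formula's environment, so the data
  # must live there for update()/step() to work from any calling context
  env <- list2env(list(dat = dat), parent = environment())
  base_fml <- as.formula(".y ~ 1", env = env)
  fit <- lm(base_fml, data = dat)
  if (sd(y) > 0) {
    upper <- reformulate(sprintf("`%s`", colnames(candidates)), response = ".y")
    environment(upper) <- env
    fit <- step(fit, scope = list(lower = ~1, upper = upper),
                direction = "both", steps = max_steps, trace = 0)
  }
  tf_fit(fit)
}

tf_fit <- function(fit) {
  # summary.lm warns on essentially perfect fits; degenerate responses are
  # handled explicitly upstream
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  terms <- setdiff(rownames(cf), "(Intercept)")
  pv <- if (length(terms)) setNames(cf[terms, 4], gsub("`", "", terms)) else
    setNames(numeric(0), character(0))
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(model = fit, terms = gsub("`", "", terms),
                 r_squared = if (length(terms)) sm$r.squared else 0,
                 p_values = pv, model_p = model_p,
                 aic = extractAIC(fit)[2]),
            class = "tf_fit")
}

#' @export
print.tf_fit <- function(x, ...) {
  if (length(x$terms) == 0) {
    cat("intercept-only model (R^2 = 0)\n")
  } else {
    cat(sprintf("terms: %s; R^2 = %.3f, model p = %.3g\n",
                paste(term_label(x$terms), collapse = " + "),
                x$r_squared, x$model_p))
  }
  invisible(x)
}

#' Manual pruning of low-significance terms
#'
#' Iteratively removes the term with the largest t-test p-value while any
#' term exceeds `p_max`, refitting after each removal; stops when all terms
#' are at or below `p_max` or the model is intercept-only. Idempotent.
#'
#' @param fit a `tf_fit` from [stepwise_fit()].
#' @param p_max retention threshold (default 0.1).
#' @return a pruned `tf_fit`.
#' @export
prune_terms <- function(fit, p_max = 0.1) {
  stopifnot(inherits(fit, "tf_fit"))
  model <- fit$model
  # update() re-evaluates the lm call in this frame, so the model's data
  # must be visible here under the name used in the original call
  dat <- environment(formula(model))$dat
  if (is.null(dat)) dat <- model$model
  repeat {
    cur <- tf_fit(model)
    if (length(cur$terms) == 0 || max(cur$p_values) <= p_max) return(cur)
    worst <- names(cur$p_values)[which.max(cur$p_values)]
    model <- update(model, as.formula(sprintf(". ~ . - `%s`", worst)))
  }
}

#' Screen every TF for environment/space dependence
#'
#' Runs [stepwise_fit()] followed by [prune_terms()] on each TF's
#' standardized counts and reports the TFs whose final model explains more
#' than `r2_min` of the variance with at least one retained term. Rows are
#' sorted by R^2 (ascending) within DBD / non-DBD category. Per-term
#' p-values are binned (`< 0.001`, `< 0.01`, `< 0.05`, `< 0.1`) in the
#' model text, matching how such screens are conventionally tabulated.
#'
#' @param tf_std standardized TF count matrix, models x samples.
#' @param candidates data frame of predictors (rows = samples, in matrix
#'   column order).
#' @param r2_min minimum explained-variance fraction to report (default 0.3).
#' @param categories optional named character vector (`"DBD"`/`"non-DBD"`)
#'   per model; defaults to the matrix's `category` attribute.
#' @param p_max pruning threshold passed to [prune_terms()].
#' @param max_steps passed to [stepwise_fit()].
#' @return data frame with columns `tf`, `category`, `model` (text with
#'   p-value bins), `terms` (list column), `r_squared`, `model_p`.
#' @export
screen_all <- function(tf_std, candidates, r2_min = 0.3, categories = NULL,
                       p_max = 0.1, max_steps = 1000) {
  tf_std <- as.matrix(tf_std)
  if (is.null(categories)) categories <- attr(tf_std, "category")
  if (is.null(categories))
    categories <- setNames(rep(NA_character_, nrow(tf_std)), rownames(tf_std))
  rows <- list()
  for (m in rownames(tf_std)) {
    y <- tf_std[m, ]
    if (sd(y) == 0) next
    fit <- prune_terms(stepwise_fit(y, candidates, max_steps), p_max)
    if (length(fit$terms) >= 1 && fit$r_squared > r2_min) {
      rows[[m]] <- data.frame(
        tf = m, category = unname(categories[m]),
        model = model_text(fit), r_squared = fit$r_squared,
        model_p = fit$model_p, stringsAsFactors = FALSE)
      rows[[m]]$terms <- I(list(fit$terms))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tf = character(0), category = character(0),
                      model = character(0), r_squared = numeric(0),
                      model_p = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  cat_rank <- match(out$category, c("non-DBD", "DBD"))
  out <- out[order(cat_rank, out$r_squared), , drop = FALSE]
  rownames(out) <- NULL
  out
}

p_bin <- function(p) {
  cuts <- c(0.001, 0.01, 0.05, 0.1)
  for (ct in cuts) if (p < ct) return(sprintf("p < %g", ct))
  sprintf("p = %.2g", p)
}

model_text <- function(fit) {
  paste(sprintf("%s (%s)", term_label(fit$terms),
                vapply(fit$p_values, p_bin, character(1))),
        collapse = " + ")
}
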