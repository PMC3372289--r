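#' Redundancy analysis (RDA) of a multivariate response on predictors
#'
#' RDA is the multivariate extension of linear regression: the
#' column-centred response matrix `Y` is projected onto the column space of
#' the predictors by least squares, and the canonical axes are the principal
#' components of the fitted matrix. The explained fraction is
#' `R^2 = SS(fitted) / SS(total)` and the adjusted fraction
#' `1 - (1 - R^2) (n - 1) / (n - m - 1)` with `m` predictor terms.
#' Implemented from first principles on QR decompositions; `vegan::rda`
#' agrees with it and serves as an independent cross-check in the test
#' suite.
#'
#' @param Y numeric response matrix, sites x variables (e.g. standardized TF
#'   counts); centred internally. A single response vector is allowed.
#' @param X predictor data frame or matrix, sites x terms.
#' @param scale_y centre-and-scale the response columns (correlation-based
#'   RDA) instead of centring only; default `FALSE` because SCG-standardized
#'   counts already share one scale.
#' @return object of class `rda_fit` with elements `r_squared`,
#'   `adj_r_squared`, `pseudo_F`, `eig` (canonical eigenvalues,
#'   `SS(fitted)` scaled by `n - 1`), `coefficients`, `fitted`, `residuals`,
#'   `n`, `m`, plus internals reused by [permutation_test()].
#' @export
rda_fit <- function(Y, X, scale_y = FALSE) {
  Y <- as.matrix(Y)
  Xm <- predictor_matrix(X)
  n <- nrow(Y)
  if (nrow(Xm) != n) stop("Y and X must have the same number of rows")
  if (anyNA(Y) || anyNA(Xm)) stop("missing values are not allowed")
  if (n <= ncol(Xm) + 1L)
    stop("need n > number of predictor terms + 1 (n = ", n, ", terms = ",
         ncol(Xm), ")")
  Yc <- scale(Y, center = TRUE, scale = scale_y)
  Yc[] <- Yc   # drop scale() attributes, keep matrix
  Xc <- scale(Xm, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc))
    stop("rank-deficient predictor matrix: collinear terms")
  m <- qrX$rank
  fitted <- qr.fitted(qrX, Yc)
  resid <- Yc - fitted
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("constant response matrix")
  ss_fit <- sum(fitted^2)
  r2 <- ss_fit / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  sv <- svd(fitted)
  pos <- sv$d > max(sv$d[1], 0) * 1e-9
  structure(list(
    r_squared = r2, adj_r_squared = adj,
    pseudo_F = (ss_fit / m) / ((ss_tot - ss_fit) / (n - m - 1)),
    eig = (sv$d[pos]^2) / (n - 1),
    coefficients = qr.coef(qrX, Yc),
    fitted = fitted, residuals = resid, Yc = Yc, qrX = qrX,
    u = sv$u[, pos, drop = FALSE], d = sv$d[pos],
    v = sv$v[, pos, drop = FALSE],
    n = n, m = m, ss_tot = ss_tot, ss_fit = ss_fit,
    terms = colnames(Xm)), class = "rda_fit")
}

predictor_matrix <- function(X) {
  if (is.data.frame(X)) {
    X <- as.matrix(X)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: n = %d sites, %d terms; R^2 = %.4f, adj R^2 = %.4f, pseudo-F = %.3f\n",
              x$n, x$m, x$r_squared, x$adj_r_squared, x$pseudo_F))
  cat("canonical eigenvalues:", paste(signif(head(x$eig, 6), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Ordination scores for biplots
#'
#' Site and variable (e.g. TF) scores on the canonical axes. Scaling 1
#' preserves distances among sites; scaling 2 (the default here) scales the
#' variable scores by the axis standard deviations so angles between
#' variable arrows approximate correlations.
#'
#' @param model an [rda_fit()] object.
#' @param scaling 1 or 2.
#' @param k number of axes.
#' @return list with `sites` and `variables` score matrices.
#' @export
rda_scores <- function(model, scaling = 2, k = 2) {
  k <- min(k, length(model$d))
  lam <- model$eig[seq_len(k)]
  u <- model$u[, seq_len(k), drop = FALSE]
  v <- model$v[, seq_len(k), drop = FALSE]
  if (scaling == 1) {
    sites <- u %*% diag(model$d[seq_len(k)], k)
    vars <- v
  } else {
    sites <- u * sqrt(model$n - 1)
    vars <- v %*% diag(sqrt(lam), k)
  }
  colnames(sites) <- colnames(vars) <- paste0("RDA", seq_len(k))
  list(sites = sites, variables = vars)
}

#' Permutation significance test for an RDA model
#'
#' The observed pseudo-F, `(SS(fitted)/m) / (SS(residual)/(n - m - 1))`, is
#' compared against its distribution under random row permutations of the
#' response; `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param model an [rda_fit()] object.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed (required for reproducibility).
#' @return list with `p_value`, `F_observed`, `n_perm`.
#' @export
permutation_test <- function(model, n_perm = 999, seed = 1) {
  stopifnot(inherits(model, "rda_fit"), n_perm >= 1)
  set.seed(as.integer(seed))
  n <- model$n; m <- model$m
  ss_tot <- model$ss_tot
  f_obs <- model$pseudo_F
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    Yp <- model$Yc[sample.int(n), , drop = FALSE]
    ssf <- sum(qr.fitted(model$qrX, Yp)^2)
    f_perm <- (ssf / m) / ((ss_tot - ssf) / (n - m - 1))
    if (f_perm >= f_obs) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (1 + n_perm), F_observed = f_obs,
       n_perm = n_perm)
}

# Partial RDA permutation test: significance of `Xadd` given covariables
# `Z` (NULL for none). Response and added predictors are residualized on Z;
# residuals of the reduced model are permuted (permutation under the
# reduced model). Returns F, p and the adjusted R^2 gain.
partial_permutation_test <- function(Y, Xadd, Z = NULL, n_perm = 199, seed = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xa <- scale(predictor_matrix(Xadd), center = TRUE, scale = FALSE)
  if (!is.null(Z) && NCOL(Z) > 0) {
    Zc <- scale(predictor_matrix(Z), center = TRUE, scale = FALSE)
    qrZ <- qr(Zc)
    mz <- qrZ$rank
    Yr <- qr.resid(qrZ, Yc)
    Xr <- qr.resid(qrZ, Xa)
  } else {
    mz <- 0L
    Yr <- Yc
    Xr <- Xa
  }
  qrA <- qr(Xr)
  ma <- qrA$rank
  df_res <- n - ma - mz - 1L
  if (df_res < 1L) stop("not enough residual degrees of freedom")
  ss_tot <- sum(Yr^2)
  ss_add <- sum(qr.fitted(qrA, Yr)^2)
  f_obs <- (ss_add / ma) / ((ss_tot - ss_add) / df_res)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    Yp <- Yr[sample.int(n), , drop = FALSE]
    ssf <- sum(qr.fitted(qrA, Yp)^2)
    fp <- (ssf / ma) / ((ss_tot - ssf) / df_res)
    if (fp >= f_obs) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (1 + n_perm), F_observed = f_obs,
       n_perm = n_perm)
}

#' Forward/backward selection of RDA predictor terms
#'
#' Forward steps add the candidate with the smallest permutation p-value for
#' its marginal (partial) effect, provided `p <= alpha_enter` and the
#' adjusted R^2 of the enlarged model does not exceed the adjusted R^2 of
#' the model with all candidates (the global stopping criterion that guards
#' against overfitting in forward selection). Backward steps then drop any
#' included term whose partial p-value has risen above `alpha_enter`. The
#' two phases alternate to a fixed point. Ties are broken by candidate
#' order, so the procedure is deterministic given the seed.
#'
#' @param Y response matrix, sites x variables.
#' @param candidates data frame of candidate predictor terms.
#' @param alpha_enter significance level to enter/stay (default 0.05).
#' @param n_perm permutations per partial test (default 199).
#' @param seed integer seed.
#' @return list with `terms` (selected column names, possibly empty) and
#'   `history` (data frame of steps: action, term, p_value, adj_r_squared).
#' @export
select_model <- function(Y, candidates, alpha_enter = 0.05, n_perm = 199,
                         seed = 1) {
  stopifnot(ncol(candidates) >= 1)
  cand_names <- colnames(candidates)
  global_adj <- rda_fit(Y, candidates)$adj_r_squared
  selected <- character(0)
  history <- data.frame(action = character(0), term = character(0),
                        p_value = numeric(0), adj_r_squared = numeric(0),
                        stringsAsFactors = FALSE)
  step_seed <- as.integer(seed)
  adj_of <- function(terms) {
    if (length(terms) == 0) 0 else
      rda_fit(Y, candidates[, terms, drop = FALSE])$adj_r_squared
  }
  repeat {
    changed <- FALSE
    # forward phase
    repeat {
      pool <- setdiff(cand_names, selected)
      if (length(pool) == 0) break
      pvals <- vapply(pool, function(tm) {
        step_seed <<- step_seed + 1L
        partial_permutation_test(
          Y, candidates[, tm, drop = FALSE],
          if (length(selected)) candidates[, selected, drop = FALSE] else NULL,
          n_perm = n_perm, seed = step_seed)$p_value
      }, numeric(1))
      best <- pool[which.min(pvals)]
      new_adj <- adj_of(c(selected, best))
      if (pvals[best] <= alpha_enter && new_adj <= global_adj + 1e-12) {
        selected <- c(selected, best)
        history <- rbind(history, data.frame(
          action = "add", term = best, p_value = unname(pvals[best]),
          adj_r_squared = new_adj, stringsAsFactors = FALSE))
        changed <- TRUE
      } else break
    }
    # backward phase
    repeat {
      if (length(selected) == 0) break
      pvals <- vapply(selected, function(tm) {
        step_seed <<- step_seed + 1L
        others <- setdiff(selected, tm)
        partial_permutation_test(
          Y, candidates[, tm, drop = FALSE],
          if (length(others)) candidates[, others, drop = FALSE] else NULL,
          n_perm = n_perm, seed = step_seed)$p_value
      }, numeric(1))
      if (max(pvals) > alpha_enter) {
        worst <- selected[which.max(pvals)]
        selected <- setdiff(selected, worst)
        history <- rbind(history, data.frame(
          action = "drop", term = worst, p_value = unname(max(pvals)),
          adj_r_squared = adj_of(selected), stringsAsFactors = FALSE))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  list(terms = selected, history = history, global_adj_r_squared = global_adj)
}

#' Variation partitioning between two predictor sets
#'
#' Splits the explained variation of `Y` between predictor set A
#' (environment) and set B (space) using adjusted R^2 from three RDA fits:
#' unique-to-A `[a] = adjR2(A+B) - adjR2(B)`, unique-to-B
#' `[c] = adjR2(A+B) - adjR2(A)`, shared
#' `[b] = adjR2(A) + adjR2(B) - adjR2(A+B)` (not an independently fittable
#' component, hence not testable and possibly negative), residual
#' `[d] = 1 - adjR2(A+B)`. Raw-R^2 fractions are reported alongside. The
#' testable fractions (full model, A given B, B given A) get permutation
#' p-values via (partial) RDA. With `condition` given, all models
#' additionally contain the conditioning terms and the fractions are
#' relative to them.
#'
#' @param Y response matrix, sites x variables.
#' @param set_a,set_b disjoint predictor data frames (environment / space).
#' @param n_perm permutations for the significance tests (default 999).
#' @param seed integer seed.
#' @param condition optional data frame of covariable terms included in
#'   every model.
#' @return object of class `varpart2`: list with `adjusted` and `raw`
#'   (named vectors `env_only`, `shared`, `space_only`, `residual`),
#'   `p_values` (full, env_given_space, space_given_env), `n_perm`, `n`.
#' @export
variation_partition <- function(Y, set_a, set_b, n_perm = 999, seed = 1,
                                condition = NULL) {
  a_names <- colnames(set_a)
  b_names <- if (is.null(set_b) || NCOL(set_b) == 0) character(0) else colnames(set_b)
  if (length(intersect(a_names, b_names)))
    stop("predictor sets overlap: ", paste(intersect(a_names, b_names), collapse = ", "))
  has_b <- length(b_names) > 0
  cbind_sets <- function(...) {
    parts <- Filter(function(x) !is.null(x) && NCOL(x) > 0, list(...))
    do.call(cbind, parts)
  }
  r2_of <- function(X) {
    if (is.null(X) || NCOL(X) == 0) return(c(adj = 0, raw = 0))
    f <- rda_fit(Y, X)
    c(adj = f$adj_r_squared, raw = f$r_squared)
  }
  rA <- r2_of(cbind_sets(set_a, condition))
  rB <- r2_of(cbind_sets(set_b, condition))
  rAB <- r2_of(cbind_sets(set_a, set_b, condition))
  rC <- r2_of(condition)

  frac <- function(v) {
    ab <- rAB[[v]]; a <- rA[[v]]; b <- rB[[v]]; cc <- rC[[v]]
    if (!has_b) {
      out <- c(env_only = a - cc, shared = 0, space_only = 0, residual = 1 - a)
    } else {
      out <- c(env_only = ab - b, shared = a + b - ab - cc,
               space_only = ab - a, residual = 1 - ab)
    }
    out
  }
  seeds <- as.integer(seed) + 0:2
  p_full <- partial_permutation_test(Y, cbind_sets(set_a, set_b),
                                     condition, n_perm, seeds[1])$p_value
  p_a <- partial_permutation_test(Y, set_a, cbind_sets(set_b, condition),
                                  n_perm, seeds[2])$p_value
  p_b <- if (has_b)
    partial_permutation_test(Y, set_b, cbind_sets(set_a, condition),
                             n_perm, seeds[3])$p_value else NA_real_
  structure(list(adjusted = frac("adj"), raw = frac("raw"),
                 p_values = c(full = p_full, env_given_space = p_a,
                              space_given_env = p_b),
                 n_perm = n_perm, n = nrow(as.matrix(Y)),
                 set_a = a_names, set_b = b_names,
                 condition = if (is.null(condition)) character(0) else colnames(condition)),
            class = "varpart2")
}

#' @export
print.varpart2 <- function(x, ...) {
  cat("Variation partitioning (adjusted R^2 fractions):\n")
  cat(sprintf("  environment only [a]: %6.3f (p[A|B] = %.4g)\n",
              x$adjusted["env_only"], x$p_values["env_given_space"]))
  cat(sprintf("  shared           [b]: %6.3f\n", x$adjusted["shared"]))
  cat(sprintf("  space only       [c]: %6.3f (p[B|A] = %.4g)\n",
              x$adjusted["space_only"], x$p_values["space_given_env"]))
  cat(sprintf("  residual         [d]: %6.3f\n", x$adjusted["residual"]))
  cat(sprintf("  full model p = %.4g (%d permutations, n = %d)\n",
              x$p_values["full"], x$n_perm, x$n))
  invisible(x)
}
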