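test_that("RDA agrees with the normal-equations oracle and with vegan", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(6:8, 1)
    Y <- matrix(rnorm(n * sample(2:5, 1)), n)
    X <- matrix(rnorm(n * sample(1:3, 1)), n)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    fit <- rda_fit(Y, X)
    orc <- oracle_rda(Y, X)
    expect_equal(fit$fitted, orc$fitted, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-9)
    expect_equal(fit$adj_r_squared, orc$adj_r_squared, tolerance = 1e-9)
    # canonical eigenvalue sum equals SS(fitted)/(n-1)
    expect_equal(sum(fit$eig), sum(fit$fitted^2) / (nrow(Y) - 1), tolerance = 1e-9)
  }

  # single response, single predictor: R^2 is the squared Pearson correlation
  set.seed(11)
  y <- rnorm(30); x <- 0.5 * y + rnorm(30)
  expect_equal(rda_fit(y, cbind(x = x))$r_squared, cor(x, y)^2, tolerance = 1e-12)

  # independent cross-check against vegan on one larger fit
  set.seed(12)
  Y <- matrix(rnorm(40 * 6), 40); X <- data.frame(a = rnorm(40), b = rnorm(40))
  fit <- rda_fit(Y, X)
  vg <- vegan::rda(Y ~ a + b, data = X)
  expect_equal(fit$r_squared, vegan::RsquareAdj(vg)$r.squared, tolerance = 1e-9)
  expect_equal(fit$adj_r_squared, vegan::RsquareAdj(vg)$adj.r.squared, tolerance = 1e-9)
  expect_equal(unname(fit$eig), unname(vg$CCA$eig), tolerance = 1e-8)

  # predictor orthogonal to every centred response column: R^2 = 0
  Yc <- scale(matrix(rnorm(30 * 3), 30), scale = FALSE)
  xo <- qr.resid(qr(cbind(1, Yc)), rnorm(30))
  expect_lt(rda_fit(Yc, cbind(x = xo))$r_squared, 1e-9)

  # collinear predictors are refused
  expect_error(rda_fit(Y, cbind(a = X$a, b = X$a * 2)), "rank-deficient")
  expect_error(rda_fit(matrix(rnorm(8), 4), matrix(rnorm(12), 4)), "n >")
})

test_that("permutation p-values respect their bounds and detect planted signal", {
  set.seed(20)
  Y <- matrix(rnorm(20 * 3), 20); X <- cbind(x = rnorm(20))
  p <- permutation_test(rda_fit(Y, X), n_perm = 99, seed = 1)
  expect_gte(p$p_value, 1 / 100)
  expect_lte(p$p_value, 1)

  # scaling the response by a positive constant leaves the p-value unchanged
  p2 <- permutation_test(rda_fit(Y * 7.3, X), n_perm = 99, seed = 1)
  expect_equal(p$p_value, p2$p_value)

  # strong planted effect: observed F beats every permutation
  spec <- synthetic_spec(n_sites = 44, env_fraction = 0.5, space_fraction = 0,
                         seed = 4)
  set.seed(41)
  stab <- matrix(rnorm(44 * 4), 44, 4,
                 dimnames = list(sprintf("S%02d", 1:44),
                                 c("temperature", "salinity", "phosphate", "silicate")))
  coords <- matrix(rnorm(44 * 2), 44, 2, dimnames = list(rownames(stab), c("X1", "X2")))
  cnt <- make_counts(spec, stab, coords)
  std <- standardize_counts(cnt$tf, cnt$scg)
  fit <- rda_fit(t(std), as.data.frame(scale(stab)))
  pp <- permutation_test(fit, n_perm = 1000, seed = 2)
  expect_equal(pp$p_value, 1 / 1001)
})

test_that("permutation test holds its type-I error under the null", {
  set.seed(30)
  rejections <- vapply(1:200, function(i) {
    Y <- matrix(rnorm(20 * 4), 20)
    X <- cbind(a = rnorm(20), b = rnorm(20))
    permutation_test(rda_fit(Y, X), n_perm = 199, seed = i)$p_value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("forward/backward selection recovers planted terms and rejects noise", {
  set.seed(50)
  n <- 40
  # single planted predictor among 9 decoys
  cand <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  colnames(cand) <- c("planted", paste0("decoy", 1:9))
  Y <- matrix(rnorm(n * 5, sd = 0.8), n, 5) + outer(cand$planted, rep(1, 5))
  sel <- select_model(Y, cand, alpha_enter = 0.05, n_perm = 99, seed = 1)
  expect_true("planted" %in% sel$terms)
  expect_lte(length(sel$terms), 3)

  # all-noise candidates: intercept-only selection in the large majority
  empties <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    Yn <- matrix(rnorm(20 * 3), 20)
    cn <- as.data.frame(matrix(rnorm(20 * 4), 20, 4))
    length(select_model(Yn, cn, alpha_enter = 0.05, n_perm = 99,
                        seed = i)$terms) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.75)
})

test_that("variation partitioning satisfies its identities and degenerate cases", {
  set.seed(60)
  n <- 30
  Y <- matrix(rnorm(n * 4), n)
  A <- data.frame(t1 = rnorm(n), t2 = rnorm(n))
  B <- data.frame(s1 = rnorm(n))

  vp <- variation_partition(Y, A, B, n_perm = 99, seed = 1)
  both <- rda_fit(Y, cbind(A, B))
  expect_equal(sum(vp$adjusted[c("env_only", "shared", "space_only")]),
               both$adj_r_squared, tolerance = 1e-9)
  expect_equal(unname(vp$adjusted["residual"]), 1 - both$adj_r_squared,
               tolerance = 1e-9)
  expect_equal(sum(vp$adjusted), 1, tolerance = 1e-9)
  expect_equal(sum(vp$raw), 1, tolerance = 1e-9)

  # B empty: [a] = adjR2(A), [b] = [c] = 0
  vp0 <- variation_partition(Y, A, NULL, n_perm = 49, seed = 1)
  expect_equal(unname(vp0$adjusted["env_only"]), rda_fit(Y, A)$adj_r_squared,
               tolerance = 1e-9)
  expect_equal(unname(vp0$adjusted["shared"]), 0)
  expect_equal(unname(vp0$adjusted["space_only"]), 0)

  # orthogonal-by-construction sets: projections add, so the raw shared
  # fraction vanishes identically; the adjusted one differs only by the
  # small-sample correction
  for (i in 1:20) {
    set.seed(200 + i)
    a <- rnorm(n)
    b <- qr.resid(qr(cbind(1, a)), rnorm(n))
    Yab <- outer(a, rep(1, 3)) + outer(b, rep(0.6, 3)) +
      matrix(rnorm(n * 3), n)
    vpo <- variation_partition(Yab, data.frame(a = a), data.frame(b = b),
                               n_perm = 1, seed = 1)
    expect_lt(abs(vpo$raw["shared"]), 1e-9)
    expect_lt(abs(vpo$adjusted["shared"]), 0.05)
  }

  expect_error(variation_partition(Y, A, data.frame(t1 = rnorm(n))), "overlap")

  # independent cross-check against vegan::varpart (its indfract rows are
  # [a] = A|B, [b] = B|A, [c] = shared, [d] = residuals)
  vv <- vegan::varpart(Y, ~ t1 + t2, ~ s1, data = cbind(A, B))
  ind <- vv$part$indfract$Adj.R.squared
  expect_equal(unname(vp$adjusted["env_only"]), ind[1], tolerance = 1e-9)
  expect_equal(unname(vp$adjusted["space_only"]), ind[2], tolerance = 1e-9)
  expect_equal(unname(vp$adjusted["shared"]), ind[3], tolerance = 1e-9)
  expect_equal(unname(vp$adjusted["residual"]), ind[4], tolerance = 1e-9)
})
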