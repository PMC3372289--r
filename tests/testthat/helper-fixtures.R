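# Shared fixtures, built in code at test time.

# small synthetic spec: coarse grid so interpolation-based fixtures stay fast
tiny_spec <- function(seed = 1, n_sites = 20, ...) {
  synthetic_spec(n_sites = n_sites,
                 grid_extent = list(lat = c(0, 10), lon = c(0, 10),
                                    depth = c(0, 30)),
                 resolution = 2, seed = seed, ...)
}

# a flat one-depth climatology with explicit node values, for hand-checked IDW
flat_grid <- function(lat, lon, node_values, parameter = "temperature") {
  vals <- array(rep(node_values, times = 12),
                c(length(lat), length(lon), 1, 12))
  climatology(parameter, "degC", lat, lon, 0, vals)
}

# candidate predictor table shaped like the real analysis: 4 "stability"
# z-scores plus degree-3 spatial terms of 2 random axes
fake_candidates <- function(n, seed = 1) {
  set.seed(seed)
  E <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  colnames(E) <- c("temperature", "salinity", "phosphate", "silicate")
  co <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("X1", "X2")))
  cbind(E, spatial_terms(co, 3))
}

# independent brute-force RDA oracle: explicit normal equations, no QR
oracle_rda <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  Yc <- scale(Y, scale = FALSE); Xc <- scale(X, scale = FALSE)
  B <- solve(t(Xc) %*% Xc, t(Xc) %*% Yc)
  fitted <- Xc %*% B
  r2 <- sum(fitted^2) / sum(Yc^2)
  n <- nrow(Y); m <- ncol(X)
  list(fitted = fitted, r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - m - 1))
}

# run the full synthetic generation -> partition chain once; returns the
# adjusted-R2 fractions against the spec's planted truth
recover_fractions <- function(seed, n_sites = 44,
                              params = c("temperature", "salinity",
                                         "phosphate", "silicate")) {
  spec <- synthetic_spec(seed = seed, n_sites = n_sites)
  sites <- make_sites(spec)
  grids <- lapply(setNames(nm = params), function(p) make_climatology(spec, p))
  stab <- stability_table(grids, sites)
  co <- pcoa(distance_matrix(sites), 2)
  cnt <- make_counts(spec, stab, co$coords)
  std <- standardize_counts(cnt$tf, cnt$scg)
  vp <- variation_partition(t(std), as.data.frame(zscore_stability(stab)),
                            as.data.frame(co$coords), n_perm = 1, seed = 1)
  vp$adjusted
}
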