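test_that("seasonal amplitude yields the closed-form stability and seeding is exact", {
  # amplitude 0, noise 0: constant series, zero stability
  spec0 <- tiny_spec(seasonal_amplitude = 0, noise_sd = 0)
  g0 <- make_climatology(spec0, "temperature")
  site <- list(sample_id = "s", latitude = 5, longitude = 5, depth_m = 5)
  ser0 <- monthly_series(g0, site)
  expect_equal(length(ser0$values), 12L)
  expect_equal(stability(ser0), 0)

  # amplitude A, noise 0: sample SD of A*sin(2 pi m/12) over a year is A*sqrt(6/11)
  spec <- tiny_spec(noise_sd = 0)
  for (p in c("temperature", "phosphate")) {
    g <- make_climatology(spec, p)
    A <- spec$seasonal_amplitude[[p]]
    expect_equal(stability(monthly_series(g, site)), A * sqrt(6 / 11),
                 tolerance = 1e-9)
  }

  # same spec, same seed: bit-identical grids
  sp <- tiny_spec(seed = 7)
  expect_identical(make_climatology(sp, "salinity")$values,
                   make_climatology(tiny_spec(seed = 7), "salinity")$values)
  expect_false(identical(make_climatology(sp, "salinity")$values,
                         make_climatology(tiny_spec(seed = 8), "salinity")$values))
  expect_error(make_climatology(sp, "chlorophyll"), "unknown parameter")
})

test_that("synthetic sites satisfy their contract and are seeded", {
  spec <- synthetic_spec(n_sites = 44, seed = 3)
  sites <- make_sites(spec)
  expect_equal(nrow(sites), 44L)
  expect_equal(anyDuplicated(sites$sample_id), 0L)
  expect_true(all(sites$latitude >= spec$grid_extent$lat[1] &
                  sites$latitude <= spec$grid_extent$lat[2]))
  expect_true(all(sites$longitude >= spec$grid_extent$lon[1] &
                  sites$longitude <= spec$grid_extent$lon[2]))
  expect_true(all(sites$filter_min_um >= 0.1 & sites$filter_max_um <= 0.8))
  expect_identical(sites, make_sites(synthetic_spec(n_sites = 44, seed = 3)))
  expect_error(synthetic_spec(n_sites = 10,
                              grid_extent = list(lat = c(5, 5), lon = c(0, 10),
                                                 depth = c(0, 30))),
               "positive range")
  expect_error(synthetic_spec(env_fraction = 0.7, space_fraction = 0.4),
               "env_fraction")
})

test_that("count generator plants the requested variance fractions", {
  # calibration invariant: at large n and low count noise, the realized R^2
  # of the expected (noise-free) abundances on the planted predictors is
  # within 0.02 of the requested fractions
  spec <- synthetic_spec(n_sites = 250, n_tf = 40, seed = 5,
                         mean_depth_of_coverage = 2000)
  set.seed(11)
  stab <- matrix(rnorm(250 * 4), 250, 4,
                 dimnames = list(sprintf("S%03d", 1:250),
                                 c("temperature", "salinity", "phosphate", "silicate")))
  coords <- matrix(rnorm(250 * 2), 250, 2, dimnames = list(rownames(stab), c("X1", "X2")))
  cnt <- make_counts(spec, stab, coords)
  E <- scale(stab); S <- scale(coords)
  Yexp <- t(cnt$truth$expected)
  r2 <- function(X) oracle_rda(Yexp, X)$r_squared
  expect_lt(abs((r2(cbind(E, S)) - r2(S)) - 0.35), 0.02)
  expect_lt(abs((r2(cbind(E, S)) - r2(E)) - 0.06), 0.02)

  # doubling sequencing depth leaves expected standardized abundances unchanged
  spec2 <- synthetic_spec(n_sites = 250, n_tf = 40, seed = 5,
                          mean_depth_of_coverage = 4000)
  cnt2 <- make_counts(spec2, stab, coords)
  expect_identical(cnt$truth$expected, cnt2$truth$expected)

  expect_error(make_counts(spec, stab[0, ], coords), "empty stability")
})

test_that("no planted effect means no recovered effect", {
  # env = space = 0: downstream partition fractions are near zero on average
  fr <- rowMeans(vapply(1:8, function(sd) {
    spec <- synthetic_spec(n_sites = 44, env_fraction = 0, space_fraction = 0,
                           seed = sd)
    set.seed(sd + 100)
    stab <- matrix(rnorm(44 * 4), 44, 4,
                   dimnames = list(sprintf("S%02d", 1:44),
                                   c("temperature", "salinity", "phosphate", "silicate")))
    coords <- matrix(rnorm(44 * 2), 44, 2,
                     dimnames = list(rownames(stab), c("X1", "X2")))
    cnt <- make_counts(spec, stab, coords)
    std <- standardize_counts(cnt$tf, cnt$scg)
    vp <- variation_partition(t(std), as.data.frame(scale(stab)),
                              as.data.frame(scale(coords)), n_perm = 1, seed = 1)
    vp$adjusted[c("env_only", "space_only")]
  }, numeric(2)))
  expect_lt(abs(fr[1]), 0.05)
  expect_lt(abs(fr[2]), 0.05)
})

test_that("generated domtblout round-trips through parse/filter/count", {
  spec <- tiny_spec(n_sites = 4, n_tf = 6, n_scg = 3)
  counts <- matrix(rpois(24, 3), 6, 4,
                   dimnames = list(sprintf("TF%02d", 1:6), sprintf("S%02d", 1:4)))
  lens <- setNames(sample(60:300, 6), rownames(counts))

  for (rate in c(0, 0.5)) {
    dt <- make_domtblout(counts, lens, decoy_rate = rate, seed = 9)
    hits <- do.call(rbind, lapply(names(dt), function(s)
      parse_domtblout(text = dt[[s]], sample_id = s)))
    sig <- filter_significant(hits)
    back <- build_count_matrix(sig, rownames(counts), colnames(counts))
    expect_equal(unclass(back)[, ], counts[, ],
                 ignore_attr = TRUE, label = sprintf("decoy_rate %.1f", rate))
  }

  # decoys really are present before filtering
  dt <- make_domtblout(counts, lens, decoy_rate = 0.5, seed = 9)
  hits <- do.call(rbind, lapply(names(dt), function(s)
    parse_domtblout(text = dt[[s]], sample_id = s)))
  expect_gt(nrow(hits), sum(counts))
  # every decoy with E-value 0.01-style violation is absent after filtering
  sig <- filter_significant(hits)
  expect_true(all(sig$independent_evalue < 0.001))
  expect_false(any(grepl("decoy", sig$read_id)))

  expect_error(make_domtblout(counts - 10, lens), "non-negative")
  # files round-trip through disk too
  dir <- tempfile(); paths <- write_domtblout(dt, dir)
  expect_true(all(file.exists(paths)))
  h2 <- parse_domtblout(paths[1], names(dt)[1])
  expect_equal(nrow(h2),
               nrow(parse_domtblout(text = dt[[1]], sample_id = names(dt)[1])))
})
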