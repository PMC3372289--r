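#' Specification for the synthetic study system
#'
#' Collects every knob of the synthetic-data generator: grid geometry,
#' per-parameter seasonal amplitude / spatial trend / grid noise, the target
#' fractions of TF-count variance driven by environment stability and by
#' space, table sizes, expected genome equivalents per sample, and the seed.
#' The defaults emulate an epipelagic ocean transect sampled with
#' prokaryote-targeting filters: 44 sites, 65 TF models, 53 SCG models,
#' roughly 300 genome equivalents per sample, an environment-stability
#' effect of 0.35 and a spatial effect of 0.06 on the TF table.
#'
#' @param n_sites number of samples (>= 2).
#' @param grid_extent list with numeric ranges `lat`, `lon` (degrees) and
#'   `depth` (metres).
#' @param resolution horizontal grid spacing in degrees.
#' @param seasonal_amplitude,spatial_trend,noise_sd named per-parameter
#'   vectors (parameter units; trend is per degree latitude); scalars are
#'   recycled to all eight parameters.
#' @param env_fraction,space_fraction target proportions of standardized
#'   TF-abundance variance driven by the stability table and by the spatial
#'   axes (`env_fraction + space_fraction <= 1`).
#' @param n_tf,n_scg numbers of TF and SCG models.
#' @param mean_depth_of_coverage expected genome equivalents per sample.
#' @param seed integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sites = 44,
                           grid_extent = list(lat = c(-35, 45),
                                              lon = c(-100, 20),
                                              depth = c(0, 30)),
                           resolution = 1,
                           seasonal_amplitude = c(temperature = 4, salinity = 0.5,
                                                  dissolved_oxygen = 15, AOU = 10,
                                                  oxygen_saturation = 5,
                                                  phosphate = 0.2, nitrate = 2,
                                                  silicate = 3),
                           spatial_trend = c(temperature = -0.3, salinity = 0.02,
                                             dissolved_oxygen = 1, AOU = 0.5,
                                             oxygen_saturation = -0.1,
                                             phosphate = 0.01, nitrate = 0.1,
                                             silicate = 0.15),
                           noise_sd = c(temperature = 0.5, salinity = 0.1,
                                        dissolved_oxygen = 3, AOU = 2,
                                        oxygen_saturation = 1, phosphate = 0.03,
                                        nitrate = 0.3, silicate = 0.4),
                           env_fraction = 0.35, space_fraction = 0.06,
                           n_tf = 65, n_scg = 53,
                           mean_depth_of_coverage = 300, seed = 1) {
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 8), CLIM_PARAMETERS)
    if (!all(CLIM_PARAMETERS %in% names(x)))
      stop("per-parameter vectors must name all eight parameters (or be scalar)")
    x[CLIM_PARAMETERS]
  }
  spec <- list(n_sites = as.integer(n_sites), grid_extent = grid_extent,
               resolution = resolution,
               seasonal_amplitude = expand(seasonal_amplitude),
               spatial_trend = expand(spatial_trend),
               noise_sd = expand(noise_sd),
               env_fraction = env_fraction, space_fraction = space_fraction,
               n_tf = as.integer(n_tf), n_scg = as.integer(n_scg),
               mean_depth_of_coverage = mean_depth_of_coverage,
               seed = as.integer(seed))
  validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_spec <- function(spec) {
  with(spec, {
    if (env_fraction < 0 || space_fraction < 0 ||
        env_fraction + space_fraction > 1)
      stop("env_fraction + space_fraction must lie in [0, 1]")
    if (n_sites < 1 || n_tf < 1 || n_scg < 1) stop("all counts must be >= 1")
    if (any(seasonal_amplitude < 0) || any(noise_sd < 0))
      stop("amplitudes and noise must be >= 0")
    for (ax in c("lat", "lon", "depth")) {
      r <- grid_extent[[ax]]
      if (length(r) != 2L || diff(r) <= 0)
        stop("grid extent for ", ax, " must span a positive range")
    }
    if (mean_depth_of_coverage <= 0) stop("mean_depth_of_coverage must be > 0")
  })
  invisible(spec)
}

# deterministic per-component seeds derived from the spec seed
spec_seed <- function(spec, offset) {
  as.integer((abs(spec$seed) + 7919 * offset) %% (.Machine$integer.max - 1L))
}

#' Synthetic gridded monthly climatology
#'
#' Generates one parameter's climatology on the spec's grid:
#' `value = base + trend * latitude + amplitude * sin(2 pi month / 12) +
#' N(0, noise_sd)`, identical over depth levels. With zero noise the
#' stability (sample SD of the 12 monthly values) at every node is exactly
#' `amplitude * sqrt(6/11)`, giving a closed form for testing.
#'
#' @param spec a [synthetic_spec()].
#' @param parameter one of the eight climatology parameters.
#' @return a [climatology()] object; bit-identical for identical (spec, seed).
#' @export
make_climatology <- function(spec, parameter) {
  stopifnot(inherits(spec, "synthetic_spec"))
  idx <- match(parameter, CLIM_PARAMETERS)
  if (is.na(idx)) stop("unknown parameter: ", parameter)
  base <- c(temperature = 15, salinity = 35, dissolved_oxygen = 250, AOU = 20,
            oxygen_saturation = 95, phosphate = 0.5, nitrate = 5,
            silicate = 10)[[parameter]]
  lat <- seq(spec$grid_extent$lat[1], spec$grid_extent$lat[2],
             by = spec$resolution)
  lon <- seq(spec$grid_extent$lon[1], spec$grid_extent$lon[2],
             by = spec$resolution)
  depth <- pretty_depth_levels(spec$grid_extent$depth)
  set.seed(spec_seed(spec, idx))
  dims <- c(length(lat), length(lon), length(depth), 12L)
  months <- rep(1:12, each = prod(dims[1:3]))
  lat_grid <- rep(lat, times = prod(dims[2:4]))
  vals <- base + spec$spatial_trend[[parameter]] * lat_grid +
    spec$seasonal_amplitude[[parameter]] * sin(2 * pi * months / 12) +
    rnorm(prod(dims), 0, spec$noise_sd[[parameter]])
  climatology(parameter, CLIM_UNITS[[parameter]], lat, lon, depth,
              array(vals, dims))
}

pretty_depth_levels <- function(range) {
  lv <- unique(c(seq(range[1], range[2], by = 10), range[2]))
  if (length(lv) < 2L) lv <- range
  lv
}

#' Synthetic sample sites
#'
#' Draws `n_sites` sites uniformly inside the grid extent with distinct ids,
#' sampling dates across one year, marine habitat labels,
#' prokaryote-targeting filter ranges inside 0.1-0.8 um, and empty in-situ
#' measurement columns (see [simulate_insitu()]).
#'
#' @param spec a [synthetic_spec()].
#' @return site data frame (see [read_sites()] for the columns).
#' @export
make_sites <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_sites < 2L) stop("n_sites must be >= 2")
  validate_spec(spec)
  set.seed(spec_seed(spec, 101))
  n <- spec$n_sites
  # keep sites off the exact bounding-box edge
  shrink <- function(r, f = 0.02) r + c(1, -1) * f * diff(r)
  latr <- shrink(spec$grid_extent$lat); lonr <- shrink(spec$grid_extent$lon)
  habitats <- c("open ocean", "coastal water", "coral reef", "estuary",
                "upwelling")
  data.frame(
    sample_id = sprintf("SYN%03d", seq_len(n)),
    latitude = runif(n, latr[1], latr[2]),
    longitude = runif(n, lonr[1], lonr[2]),
    depth_m = runif(n, spec$grid_extent$depth[1], spec$grid_extent$depth[2]),
    date = as.Date("2004-01-01") + sample.int(365, n, replace = TRUE) - 1L,
    habitat = sample(habitats, n, replace = TRUE,
                     prob = c(0.45, 0.3, 0.1, 0.1, 0.05)),
    filter_min_um = 0.1, filter_max_um = 0.8,
    insitu_temperature = NA_real_, insitu_salinity = NA_real_,
    stringsAsFactors = FALSE)
}

#' Simulate shipboard in-situ measurements for synthetic sites
#'
#' The measured value at a site is the climatology value interpolated at the
#' site for its sampling month plus Gaussian measurement/short-term
#' variability noise.
#'
#' @param sites site data frame with a `date` column.
#' @param grid a [climatology()] object.
#' @param noise_sd measurement noise SD in the parameter's units.
#' @param seed integer seed.
#' @return numeric vector of simulated in-situ values (NA where the series
#'   is unavailable).
#' @export
simulate_insitu <- function(sites, grid, noise_sd = 0.5, seed = 1) {
  set.seed(as.integer(seed))
  months <- as.integer(format(as.Date(sites$date), "%m"))
  vapply(seq_len(nrow(sites)), function(i) {
    ser <- monthly_series(grid, sites[i, ])
    if (!ser$available) return(NA_real_)
    ser$values[months[i]] + rnorm(1, 0, noise_sd)
  }, numeric(1))
}

#' Synthetic TF and SCG count tables with planted effect fractions
#'
#' For each TF model, a latent standardized abundance per sample is built as
#' a fixed signal plus random noise: a linear combination of the z-scored
#' stability columns (scaled to variance `env_fraction`), a combination of
#' the spatial axes residualized against the stability columns (scaled to
#' variance `space_fraction`, so the two signal parts are orthogonal), and
#' i.i.d. Gaussian noise with the remaining variance. The population
#' variance fractions of the latent abundance therefore equal the requested
#' fractions, and adjusted R-squared is an approximately unbiased estimator
#' of them. Per-sample genome equivalents `g_s` are drawn around
#' `mean_depth_of_coverage`; SCG counts are `Poisson(g_s)` per model and TF
#' counts `Poisson(abundance * g_s)`, so SCG-mean standardization is a real
#' inferential step. The planted truth (coefficients, expected abundances,
#' genome equivalents) is returned for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param stability sites x parameters stability matrix (raw or z-scored).
#' @param coords sites x 2 matrix of spatial axes (e.g. [pcoa()] coords).
#' @return list with `tf` and `scg` (integer count matrices, models x
#'   samples) and `truth` (list: `expected` standardized abundances,
#'   `mu` per-TF means, `w_env`, `w_space` coefficient matrices,
#'   `genome_equivalents`, the planted fractions, `cv`).
#' @export
make_counts <- function(spec, stability, coords) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stability <- as.matrix(stability)
  coords <- as.matrix(coords)
  if (nrow(stability) == 0L) stop("empty stability table")
  if (nrow(stability) != nrow(coords))
    stop("stability and coords must cover the same sites")
  if (spec$env_fraction + spec$space_fraction > 1)
    stop("env_fraction + space_fraction must be <= 1")
  n <- nrow(stability)
  ids <- rownames(stability)
  if (is.null(ids)) ids <- sprintf("SYN%03d", seq_len(n))

  E <- scale(stability)
  S <- scale(coords[, seq_len(min(2L, ncol(coords))), drop = FALSE])
  env <- spec$env_fraction; space <- spec$space_fraction
  resid_frac <- 1 - env - space
  cv <- 0.3   # latent coefficient of variation of standardized abundance

  qE <- qr(cbind(1, E))
  unitize <- function(v) {
    v <- v - mean(v)
    s <- sd(v)
    if (s < 1e-12) stop("degenerate predictor combination in generator")
    v / s
  }

  set.seed(spec_seed(spec, 202))
  mu <- rlnorm(spec$n_tf, meanlog = 0, sdlog = 0.5)
  w_env <- matrix(rnorm(spec$n_tf * ncol(E)), spec$n_tf, ncol(E))
  w_space <- matrix(rnorm(spec$n_tf * ncol(S)), spec$n_tf, ncol(S))
  expected <- matrix(0, spec$n_tf, n,
                     dimnames = list(sprintf("TF%03d", seq_len(spec$n_tf)), ids))
  for (j in seq_len(spec$n_tf)) {
    latent <- rep(0, n)
    if (env > 0) latent <- latent + sqrt(env) * unitize(E %*% w_env[j, ])
    if (space > 0) latent <- latent +
        sqrt(space) * unitize(qr.resid(qE, as.vector(S %*% w_space[j, ])))
    if (resid_frac > 0) latent <- latent + sqrt(resid_frac) * rnorm(n)
    expected[j, ] <- pmax(mu[j] * (1 + cv * latent), 0.02 * mu[j])
  }

  g <- rgamma(n, shape = 1 / 0.3^2, rate = 1 / (0.3^2 * spec$mean_depth_of_coverage))
  tf <- matrix(rpois(spec$n_tf * n, expected %*% diag(g, n)),
               spec$n_tf, n, dimnames = dimnames(expected))
  scg <- matrix(rpois(spec$n_scg * n, rep(g, each = spec$n_scg)),
                spec$n_scg, n,
                dimnames = list(sprintf("SCG%02d", seq_len(spec$n_scg)), ids))
  categories <- rep(c("DBD", "non-DBD"),
                    c(ceiling(spec$n_tf * 40 / 65),
                      spec$n_tf - ceiling(spec$n_tf * 40 / 65)))
  attr(tf, "category") <- setNames(categories, rownames(tf))
  list(tf = tf, scg = scg,
       truth = list(expected = expected, mu = mu, w_env = w_env,
                    w_space = w_space, genome_equivalents = g,
                    env_fraction = env, space_fraction = space, cv = cv))
}

#' Synthetic HMMER3 domtblout text with decoys
#'
#' For every counted hit in `counts`, emits one per-domain record that
#' satisfies all three significance criteria of [filter_significant()];
#' additionally emits decoy records that each fail exactly one criterion
#' (cycling E-value, model coverage, bias) at rate `decoy_rate` relative to
#' the true hits. Parsing, filtering and counting the output therefore
#' reproduces `counts` exactly for any decoy rate.
#'
#' @param counts non-negative integer matrix, models x samples.
#' @param model_lengths named integer vector of model lengths (residues)
#'   covering every model in `counts`; lengths must be >= 20.
#' @param decoy_rate decoy records per true record (default 0).
#' @param seed integer seed.
#' @return named list (one element per sample) of character vectors of
#'   domtblout lines; see [write_domtblout()].
#' @export
make_domtblout <- function(counts, model_lengths, decoy_rate = 0, seed = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!all(rownames(counts) %in% names(model_lengths)))
    stop("model_lengths must cover every model")
  if (any(model_lengths <= 0)) stop("model lengths must be positive")
  set.seed(as.integer(seed))
  out <- list()
  for (s in colnames(counts)) {
    lines <- c("#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
               "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target")
    read_n <- 0L
    true_models <- rep(rownames(counts), counts[, s])
    for (m in true_models) {
      read_n <- read_n + 1L
      lines <- c(lines, domtbl_record(
        read_id = sprintf("%s_read%05d", s, read_n), model = m,
        L = model_lengths[[m]], fail = "none"))
    }
    n_decoy <- round(decoy_rate * length(true_models))
    if (n_decoy > 0) {
      fails <- c("evalue", "coverage", "bias")[(seq_len(n_decoy) - 1L) %% 3L + 1L]
      decoy_models <- sample(rownames(counts), n_decoy, replace = TRUE)
      for (k in seq_len(n_decoy)) {
        read_n <- read_n + 1L
        lines <- c(lines, domtbl_record(
          read_id = sprintf("%s_decoy%05d", s, read_n), model = decoy_models[k],
          L = model_lengths[[decoy_models[k]]], fail = fails[k]))
      }
    }
    out[[s]] <- c(lines, "#")
  }
  out
}

# one domtblout line; `fail` picks which significance criterion to violate
domtbl_record <- function(read_id, model, L, fail = "none") {
  score <- round(runif(1, 40, 300), 1)
  bias <- round(score / (10 * runif(1, 1.1, 20)), 1)
  ieval <- signif(10^runif(1, -20, -4), 2)
  span <- ceiling(0.2 * L) + sample.int(max(1L, floor(0.7 * L)), 1L)
  span <- min(span, L - 1L)
  hmm_from <- sample.int(max(1L, L - span), 1L)
  hmm_to <- hmm_from + span
  if (fail == "evalue") ieval <- signif(10^runif(1, -2.5, -1.2), 2)
  if (fail == "coverage") { hmm_from <- 1L; hmm_to <- 1L + floor(0.1 * L) }
  if (fail == "bias") bias <- round(score / 2, 1)
  tlen <- hmm_to - hmm_from + sample.int(50, 1L)
  sprintf("%-20s -  %5d %-20s -  %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d 0.90 -",
          read_id, tlen, model, L, ieval, score, bias, 1L, 1L,
          ieval / 2, ieval, score, bias, hmm_from, hmm_to,
          1L, hmm_to - hmm_from + 1L, 1L, tlen)
}

#' @rdname make_domtblout
#' @param domtbl result of [make_domtblout()].
#' @param dir output directory (created if needed).
#' @export
write_domtblout <- function(domtbl, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(domtbl), ".domtblout"))
  for (i in seq_along(domtbl)) writeLines(domtbl[[i]], paths[i])
  invisible(paths)
}
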