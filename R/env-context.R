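#' Inverse-distance-weighted interpolation at a sampling site
#'
#' Interpolates one monthly field of a gridded climatology at a site's GPS
#' position. The `k_neighbors` nearest non-missing horizontal grid nodes at
#' the depth level closest to the site's depth contribute with weights
#' `d^-power` (great-circle node distances). A query coinciding with a grid
#' node (distance < 1 m) returns that node's value exactly.
#'
#' @param grid a [climatology()] object.
#' @param site a list or one-row data frame with `latitude`, `longitude`,
#'   `depth_m`.
#' @param month month index 1-12.
#' @param power IDW exponent (default 2).
#' @param k_neighbors number of contributing nodes (default 4).
#' @return interpolated value (scalar). Errors with class
#'   `tfstab_no_interpolation` when every candidate node is missing, and with
#'   a plain error when the site lies outside the grid bounding box.
#' @export
idw_interpolate <- function(grid, site, month, power = 2, k_neighbors = 4) {
  stopifnot(inherits(grid, "climatology"), month %in% 1:12, power > 0,
            k_neighbors >= 1)
  check_in_bbox(grid, site)
  nd <- node_distances(grid, site)
  idw_at_month(grid, nd, month, power, k_neighbors)
}

check_in_bbox <- function(grid, site) {
  if (site$latitude < min(grid$lat) || site$latitude > max(grid$lat) ||
      site$longitude < min(grid$lon) || site$longitude > max(grid$lon))
    stop("site (", site$latitude, ", ", site$longitude,
         ") outside climatology bounding box")
  invisible(TRUE)
}

# horizontal node distances (km) and the nearest depth level, reusable
# across the twelve months of one site
node_distances <- function(grid, site) {
  nodes <- expand.grid(lat = grid$lat, lon = grid$lon, KEEP.OUT.ATTRS = FALSE)
  d <- haversine_km(nodes$lat, nodes$lon, site$latitude, site$longitude)
  iz <- which.min(abs(grid$depth - site$depth_m))
  list(ilat = match(nodes$lat, grid$lat), ilon = match(nodes$lon, grid$lon),
       d = d, iz = iz)
}

idw_at_month <- function(grid, nd, month, power, k_neighbors) {
  v <- grid$values[cbind(nd$ilat, nd$ilon, nd$iz, month)]
  ok <- !is.na(v)
  if (!any(ok)) {
    stop(structure(class = c("tfstab_no_interpolation", "error", "condition"),
                   list(message = sprintf(
                     "no reliable interpolation: all nodes missing (month %d)", month),
                     call = sys.call(-1))))
  }
  d <- nd$d[ok]; v <- v[ok]
  o <- order(d)[seq_len(min(k_neighbors, sum(ok)))]
  d <- d[o]; v <- v[o]
  if (d[1] < 1e-3) return(v[1])      # query sits on a grid node
  w <- d^(-power)
  sum(w * v) / sum(w)
}

#' Twelve interpolated monthly values at a site
#'
#' Applies [idw_interpolate()] for months 1-12. If any month cannot be
#' interpolated (all candidate nodes missing) the series is flagged
#' unavailable rather than erroring, mirroring how coastal sites with no
#' reliable gridded data are handled downstream.
#'
#' @inheritParams idw_interpolate
#' @return an object of class `monthly_series`: list with `sample_id`,
#'   `parameter`, `values` (length 12) and `available` flag.
#' @export
monthly_series <- function(grid, site, power = 2, k_neighbors = 4) {
  check_in_bbox(grid, site)
  nd <- node_distances(grid, site)
  vals <- rep(NA_real_, 12)
  for (m in 1:12) {
    vals[m] <- tryCatch(idw_at_month(grid, nd, m, power, k_neighbors),
                        tfstab_no_interpolation = function(e) NA_real_)
  }
  structure(list(sample_id = if (!is.null(site$sample_id)) site$sample_id else NA_character_,
                 parameter = grid$parameter, values = vals,
                 available = all(is.finite(vals))),
            class = "monthly_series")
}

#' Environment stability of a monthly series
#'
#' Stability is the sample standard deviation of the twelve monthly values,
#' `sqrt(sum((X_i - mean)^2) / (N - 1))` with `N = 12`; a lower value means a
#' more seasonally stable environment.
#'
#' @param series a [monthly_series()] object or a numeric vector of 12 values.
#' @return the stability (standard deviation), a non-negative scalar.
#' @export
stability <- function(series) {
  x <- if (inherits(series, "monthly_series")) series$values else as.numeric(series)
  if (length(x) != 12L) stop("a monthly series has exactly 12 values")
  if (anyNA(x)) stop("missing months: series unavailable")
  sd(x)
}

#' Site x parameter table of environment-stability measures
#'
#' Convenience wrapper: for each site and each climatology, interpolates the
#' twelve monthly values and takes their standard deviation. Sites where a
#' series is unavailable get `NA`.
#'
#' @param grids named list of [climatology()] objects (names = parameters).
#' @param sites site data frame (see [read_sites()]).
#' @inheritParams idw_interpolate
#' @return numeric matrix, rows = `sample_id`, columns = parameters.
#' @export
stability_table <- function(grids, sites, power = 2, k_neighbors = 4) {
  stopifnot(length(grids) >= 1, !is.null(names(grids)))
  out <- matrix(NA_real_, nrow(sites), length(grids),
                dimnames = list(sites$sample_id, names(grids)))
  for (j in seq_along(grids)) {
    for (i in seq_len(nrow(sites))) {
      ser <- monthly_series(grids[[j]], sites[i, ], power, k_neighbors)
      if (ser$available) out[i, j] <- stability(ser)
    }
  }
  out
}

#' Z-score a stability table column-wise
#'
#' Each column (stability measure) is transformed to `(x - mu) / sigma` with
#' mean and standard deviation taken across all samples, neutralizing the
#' different scales and units of the parameters. After the transformation
#' every column has mean 0 and sample standard deviation 1.
#'
#' @param table numeric matrix, sites x parameters.
#' @return matrix of z-scores with attributes `center` and `scale` (the
#'   per-column mean and SD) and `scored = TRUE`.
#' @export
zscore_stability <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L) stop("need at least 2 rows to z-score")
  s <- apply(table, 2, sd)
  if (any(!is.finite(s)) || any(s == 0))
    stop("zero-variance (constant) stability column: ",
         paste(colnames(table)[!is.finite(s) | s == 0], collapse = ", "))
  ctr <- colMeans(table)
  z <- sweep(sweep(table, 2, ctr, "-"), 2, s, "/")
  structure(z, center = ctr, scale = s, scored = TRUE)
}

#' Prune collinear stability measures by Spearman correlation
#'
#' Computes all pairwise Spearman rank correlations; whenever `|rho|` exceeds
#' `rho_threshold` and the correlation test is significant, the
#' lower-priority member of the pair is dropped. Pairs exceeding the
#' threshold without a significant test are retained with a warning. The
#' result is independent of the column order of `table` for a fixed
#' `priority`.
#'
#' @param table sites x parameters matrix of (raw or z-scored) stabilities.
#' @param rho_threshold absolute Spearman rho above which a pair counts as
#'   collinear (default 0.6).
#' @param priority character vector ordering parameters from most to least
#'   preferred; parameters absent from it rank last in input order.
#' @param p_max two-sided significance level for the correlation test
#'   (default 0.05).
#' @return list with `retained` (character vector, in priority order) and
#'   `report` (data frame of every pair: rho, p-value, action).
#' @export
prune_collinear <- function(table, rho_threshold = 0.6,
                            priority = default_parameter_priority(),
                            p_max = 0.05) {
  table <- as.matrix(table)
  if (ncol(table) < 2L) stop("need at least 2 parameters")
  params <- colnames(table)
  rank_of <- match(params, priority)
  rank_of[is.na(rank_of)] <- length(priority) + seq_len(sum(is.na(rank_of)))
  ord <- params[order(rank_of)]

  pairs <- t(combn(params, 2))
  rho <- p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ct <- suppressWarnings(cor.test(table[, pairs[i, 1]], table[, pairs[i, 2]],
                                    method = "spearman", exact = FALSE))
    rho[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  report <- data.frame(param_a = pairs[, 1], param_b = pairs[, 2],
                       rho = rho, p_value = p,
                       collinear = abs(rho) > rho_threshold & p < p_max,
                       stringsAsFactors = FALSE)

  high_ns <- abs(rho) > rho_threshold & p >= p_max
  if (any(high_ns))
    warning("pairs exceed |rho| threshold but are not significant; retained: ",
            paste(pairs[high_ns, 1], pairs[high_ns, 2], sep = "~", collapse = ", "))

  retained <- character(0)
  for (pm in ord) {
    drop <- FALSE
    for (kept in retained) {
      hit <- (report$param_a == pm & report$param_b == kept) |
             (report$param_b == pm & report$param_a == kept)
      if (any(report$collinear[hit])) { drop <- TRUE; break }
    }
    if (!drop) retained <- c(retained, pm)
  }
  list(retained = retained, report = report)
}

#' Default priority order for correlated stability measures
#'
#' When two stability measures are collinear only one can enter the model;
#' this order prefers the parameters with the most direct, independently
#' measured oceanographic meaning over derived oxygen quantities.
#' @return character vector of parameter names.
#' @export
default_parameter_priority <- function() {
  c("temperature", "salinity", "phosphate", "silicate",
    "dissolved_oxygen", "nitrate", "AOU", "oxygen_saturation")
}

#' Validate interpolated values against in-situ measurements
#'
#' Ordinary least squares with the interpolated value as response and the
#' shipboard in-situ measurement as explanatory variable, both in the same
#' units. A good climatology interpolation yields a slope near 1 and a high
#' R-squared. The site with the largest absolute residual is flagged; a
#' gross residual typically marks a site (e.g. a hypersaline mangrove
#' forest) where the gridded product cannot represent the local water mass.
#'
#' @param insitu numeric vector of measured values.
#' @param interpolated numeric vector of interpolated values (same length).
#' @param sample_id optional sample identifiers.
#' @return object of class `interp_validation`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value` (model F-test), `n`, `residuals`,
#'   `worst_site`, `worst_residual`.
#' @export
validate_interpolation <- function(insitu, interpolated, sample_id = NULL) {
  ok <- is.finite(insitu) & is.finite(interpolated)
  insitu <- insitu[ok]; interpolated <- interpolated[ok]
  if (!is.null(sample_id)) sample_id <- sample_id[ok]
  if (length(insitu) < 3L) stop("need at least 3 complete (in-situ, interpolated) pairs")
  fit <- lm(interpolated ~ insitu)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  res <- residuals(fit)
  worst <- which.max(abs(res))
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, p_value = pval, n = length(insitu),
                 residuals = res,
                 worst_site = if (!is.null(sample_id)) sample_id[worst] else worst,
                 worst_residual = unname(res[worst])),
            class = "interp_validation")
}

#' @export
print.interp_validation <- function(x, ...) {
  cat(sprintf("interpolated ~ measured: R^2 = %.3f (p = %.3g, n = %d), slope %.3f, intercept %.3f\n",
              x$r_squared, x$p_value, x$n, x$slope, x$intercept))
  cat(sprintf("largest |residual|: %s (%.2f)\n", x$worst_site, x$worst_residual))
  invisible(x)
}
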