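#' Pairwise geographic distance matrix between sampling sites
#'
#' Distances are computed from GPS coordinates on a sphere of radius 6371 km,
#' either along the surface (`"greatcircle"`, haversine; the default) or as
#' straight-line chords through the sphere (`"chord"`). For a composite
#' sample that pools material from several stations, its distance to any
#' other sample is the mean of the constituent stations' distances to that
#' sample (and the mean over all constituent pairs for two composites).
#'
#' @param sites data frame with `sample_id`, `latitude`, `longitude`.
#' @param mode `"greatcircle"` or `"chord"`.
#' @param composites optional named list: for each composite `sample_id`, a
#'   data frame / matrix with columns `latitude`, `longitude` of its
#'   constituent stations.
#' @return symmetric matrix of distances in kilometres with zero diagonal,
#'   dimnames = sample ids.
#' @export
distance_matrix <- function(sites, mode = c("greatcircle", "chord"),
                            composites = NULL) {
  mode <- match.arg(mode)
  sites <- validate_sites_coords(sites)
  n <- nrow(sites)
  if (n < 2L) stop("need at least 2 sites")
  ids <- sites$sample_id

  pt_dist <- function(lat1, lon1, lat2, lon2) {
    if (mode == "greatcircle") {
      haversine_km(lat1, lon1, lat2, lon2)
    } else {
      to_xyz <- function(lat, lon) {
        la <- lat * pi / 180; lo <- lon * pi / 180
        EARTH_RADIUS_KM * cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
      }
      nmax <- max(length(lat1), length(lat2))
      a <- to_xyz(rep_len(lat1, nmax), rep_len(lon1, nmax))
      b <- to_xyz(rep_len(lat2, nmax), rep_len(lon2, nmax))
      sqrt(rowSums((a - b)^2))
    }
  }

  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    D[i, j] <- D[j, i] <- pt_dist(sites$latitude[j], sites$longitude[j],
                                  sites$latitude[i], sites$longitude[i])
  }

  for (cid in names(composites)) {
    if (!cid %in% ids) stop("composite sample ", cid, " not in site table")
    parts <- as.data.frame(composites[[cid]])
    for (j in seq_len(n)) {
      if (ids[j] == cid) next
      if (ids[j] %in% names(composites)) {
        other <- as.data.frame(composites[[ids[j]]])
        dd <- outer(seq_len(nrow(parts)), seq_len(nrow(other)),
                    Vectorize(function(a, b)
                      pt_dist(parts$latitude[a], parts$longitude[a],
                              other$latitude[b], other$longitude[b])))
        D[cid, ids[j]] <- D[ids[j], cid] <- mean(dd)
      } else {
        d <- pt_dist(parts$latitude, parts$longitude,
                     sites$latitude[j], sites$longitude[j])
        D[cid, ids[j]] <- D[ids[j], cid] <- mean(d)
      }
    }
  }
  D
}

validate_sites_coords <- function(sites) {
  stopifnot(all(c("sample_id", "latitude", "longitude") %in% colnames(sites)))
  if (any(!is.finite(sites$latitude)) || any(!is.finite(sites$longitude)) ||
      any(abs(sites$latitude) > 90))
    stop("invalid coordinates")
  sites
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: the squared distance matrix is double-centred
#' (`-D^2/2`), eigendecomposed, and the `k` eigenvectors with the largest
#' positive eigenvalues, scaled by the square root of their eigenvalues,
#' become the coordinates. Negative eigenvalues (possible for non-Euclidean
#' distances such as great-circle distances) are reported but their axes are
#' discarded. For reproducible axis orientation across platforms, each axis
#' is flipped so that its largest-magnitude coordinate is positive.
#'
#' @param d distance matrix (symmetric, zero diagonal) or `dist` object.
#' @param k number of coordinates to return (default 2).
#' @return object of class `pcoa_coords`: list with `coords` (n x k matrix,
#'   columns `X1..Xk`, centred at 0) and `eig` (all eigenvalues, decreasing).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) stop("need at least 3 points")
  fit <- cmdscale(d, k = min(k, n - 1L), eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- max(abs(eig)) * 1e-8
  npos <- sum(eig > tol)
  if (k > npos)
    stop("k = ", k, " exceeds the number of positive eigenvalues (", npos, ")")
  coords <- fit$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("X", seq_len(k))
  if (!is.null(attr(d, "Labels"))) rownames(coords) <- attr(d, "Labels")
  structure(list(coords = coords, eig = eig), class = "pcoa_coords")
}

#' @export
print.pcoa_coords <- function(x, ...) {
  cat(sprintf("PCoA: %d points, %d axes; first eigenvalues: %s\n",
              nrow(x$coords), ncol(x$coords),
              paste(signif(head(x$eig, 4), 4), collapse = ", ")))
  invisible(x)
}

#' Polynomial spatial predictor table
#'
#' Builds the spatial component of the ordination models: the principal
#' coordinates `X1, X2` plus element-wise powers up to `degree`, computed
#' after centring each axis (centring limits collinearity among the powers).
#' With `degree = 3` and two axes the table is `X1, X2, X1^2, X1^3, X2^2,
#' X2^3`. Column names use `_` for powers (`X1_2` = X1 squared) so they stay
#' syntactic in model formulas; [term_label()] maps them back to the
#' conventional `X1^2` notation.
#'
#' @param coords a [pcoa()] result or a numeric matrix of coordinates.
#' @param degree highest power (>= 1; default 3).
#' @return data frame of predictors, one row per site.
#' @export
spatial_terms <- function(coords, degree = 3) {
  if (inherits(coords, "pcoa_coords")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (degree < 1) stop("degree must be >= 1")
  ctr <- scale(coords, center = TRUE, scale = FALSE)
  axes <- colnames(ctr)
  if (is.null(axes)) axes <- paste0("X", seq_len(ncol(ctr)))
  out <- as.data.frame(ctr)
  colnames(out) <- axes
  if (degree >= 2) {
    for (a in axes) {
      for (p in 2:degree) out[[paste0(a, "_", p)]] <- ctr[, a]^p
    }
  }
  rownames(out) <- rownames(coords)
  out
}

#' Human-readable label for a spatial/polynomial term name
#'
#' @param term character vector of term names (e.g. `"X1_2"`).
#' @return labels such as `"X1^2"`; non-polynomial names pass through.
#' @export
term_label <- function(term) {
  gsub("^(X[0-9]+)_([0-9]+)$", "\\1^\\2", term)
}
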