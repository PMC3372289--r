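#' Gridded monthly climatology
#'
#' Container for one environmental parameter on a regular latitude x
#' longitude x depth grid with twelve monthly fields, emulating the layout of
#' standard ocean atlas products (one value per grid node per month; missing
#' values allowed, e.g. land cells).
#'
#' @param parameter parameter name (e.g. `"temperature"`).
#' @param units unit string (e.g. `"degC"`).
#' @param lat,lon,depth strictly increasing numeric grid axes (degrees,
#'   degrees, metres).
#' @param values numeric array of dimension
#'   `c(length(lat), length(lon), length(depth), 12)`; `NA` marks missing
#'   nodes.
#' @return an object of class `climatology`.
#' @seealso [read_climatology()], [write_climatology()], [idw_interpolate()]
#' @export
climatology <- function(parameter, units, lat, lon, depth, values) {
  stopifnot(is.character(parameter), length(parameter) == 1L,
            is.character(units), length(units) == 1L)
  for (ax in list(lat, lon, depth)) {
    if (length(ax) < 1L || is.unsorted(ax, strictly = TRUE))
      stop("grid axes must be strictly increasing")
  }
  values <- as.array(values)
  want <- c(length(lat), length(lon), length(depth), 12L)
  if (!identical(as.integer(dim(values)), as.integer(want)))
    stop("`values` must have dimension lat x lon x depth x 12")
  structure(list(parameter = parameter, units = units, lat = lat, lon = lon,
                 depth = depth, values = values),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("climatology: %s [%s], %d x %d x %d grid, 12 months (%.0f%% missing)\n",
              x$parameter, x$units, length(x$lat), length(x$lon),
              length(x$depth), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Write / read a climatology as a plain-text grid file
#'
#' The on-disk format is a long table with columns `latitude`, `longitude`,
#' `depth_m`, `month`, `value` preceded by a single header comment naming the
#' parameter and units, one file per parameter.
#'
#' @param clim a [climatology()] object.
#' @param path file path.
#' @return `write_climatology()` returns `path` invisibly;
#'   `read_climatology()` returns a `climatology`.
#' @export
write_climatology <- function(clim, path) {
  stopifnot(inherits(clim, "climatology"))
  grid <- expand.grid(latitude = clim$lat, longitude = clim$lon,
                      depth_m = clim$depth, month = 1:12,
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- as.vector(clim$values)
  grid <- grid[!is.na(grid$value), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# parameter=%s units=%s", clim$parameter, clim$units), con)
  writeLines(paste(colnames(grid), collapse = "\t"), con)
  write.table(grid, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_climatology
#' @export
read_climatology <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("#\\s*parameter=(\\S+)\\s+units=(\\S+)", header))[[1]]
  if (length(m) != 3L) stop("missing '# parameter=... units=...' header in ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("latitude", "longitude", "depth_m", "month", "value")
  if (!all(need %in% colnames(tab))) stop("climatology file lacks required columns")
  lat <- sort(unique(tab$latitude)); lon <- sort(unique(tab$longitude))
  depth <- sort(unique(tab$depth_m))
  vals <- array(NA_real_, c(length(lat), length(lon), length(depth), 12L))
  vals[cbind(match(tab$latitude, lat), match(tab$longitude, lon),
             match(tab$depth_m, depth), tab$month)] <- tab$value
  climatology(m[2], m[3], lat, lon, depth, vals)
}

#' Read a sample-site metadata table
#'
#' Expects the CSV layout emitted by [make_sites()] /
#' [write_sites()]: columns `sample_id`, `latitude`, `longitude`, `depth_m`,
#' `date`, `habitat`, `filter_min_um`, `filter_max_um` and optional
#' `insitu_temperature`, `insitu_salinity`.
#'
#' @param path CSV file path.
#' @return a data frame of sites with longitude normalized to (-180, 180].
#' @export
read_sites <- function(path) {
  sites <- read.csv(path, stringsAsFactors = FALSE)
  validate_sites(sites)
}

#' @rdname read_sites
#' @param sites a site data frame.
#' @export
write_sites <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

validate_sites <- function(sites) {
  need <- c("sample_id", "latitude", "longitude", "depth_m")
  if (!all(need %in% colnames(sites)))
    stop("site table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sites$sample_id)) stop("duplicate sample_id in site table")
  if (any(abs(sites$latitude) > 90)) stop("latitude outside [-90, 90]")
  # normalize longitude to (-180, 180]
  lon <- sites$longitude %% 360
  lon[lon > 180] <- lon[lon > 180] - 360
  sites$longitude <- lon
  if (any(sites$depth_m < 0)) stop("negative depth")
  if (all(c("filter_min_um", "filter_max_um") %in% colnames(sites))) {
    bad <- !is.na(sites$filter_min_um) &
      (sites$filter_min_um <= 0 | sites$filter_max_um < sites$filter_min_um)
    if (any(bad)) stop("filter bounds must be positive and ordered")
  }
  sites
}
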