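#' Configuration for a full pipeline run
#'
#' Collects inputs and thresholds for [run_full()] / [run_validation()].
#' Inputs may be in-memory objects or file paths (CSV / climatology grid
#' files); any downstream table that is supplied directly (e.g. count
#' matrices, a stability table, a distance matrix) bypasses the stages that
#' would compute it.
#'
#' @param sites site data frame or CSV path.
#' @param climatologies named list of [climatology()] objects or file paths
#'   (names = parameters). Needed unless `stability` is given.
#' @param tf_counts,scg_counts raw count matrices (models x samples) or CSV
#'   paths. Needed unless `domtblout` is given.
#' @param domtblout named list / vector of domtblout file paths (names =
#'   sample ids); used with `model_lengths` and the packaged model lists
#'   when count matrices are not supplied.
#' @param model_lengths named vector of model lengths (for `domtblout`).
#' @param tf_model_list,scg_model_list data frames with columns `model` and
#'   (for TFs) `category`; default packaged lists.
#' @param stability precomputed sites x parameters stability matrix or CSV
#'   path (rows named by sample id).
#' @param distances precomputed distance matrix or CSV path.
#' @param composites passed to [distance_matrix()].
#' @param spec optional [synthetic_spec()]: generate all inputs
#'   synthetically (the one-command demo; see [synthetic_demo_config()]).
#' @param evalue_max,coverage_fraction,bias_ratio significance thresholds
#'   for [filter_significant()].
#' @param rho_threshold,priority collinearity pruning controls.
#' @param idw_power,k_neighbors interpolation controls.
#' @param distance_mode `"greatcircle"` or `"chord"`.
#' @param alpha_enter,r2_min,p_max selection/screening thresholds.
#' @param n_perm permutations for significance tests.
#' @param seed integer seed (mandatory: permutations and simulation).
#' @param out_dir optional output directory for tables, summary JSON, log.
#' @param select_rules passed to [select_samples()].
#' @param validation_exclude sample ids excluded from the second
#'   interpolation-validation fit (e.g. known unreliable coastal sites).
#' @return a `run_config` list.
#' @export
run_config <- function(sites = NULL, climatologies = NULL, tf_counts = NULL,
                       scg_counts = NULL, domtblout = NULL,
                       model_lengths = NULL, tf_model_list = NULL,
                       scg_model_list = NULL, stability = NULL,
                       distances = NULL, composites = NULL, spec = NULL,
                       evalue_max = 0.001, coverage_fraction = 0.20,
                       bias_ratio = 10, rho_threshold = 0.6,
                       priority = default_parameter_priority(),
                       idw_power = 2, k_neighbors = 4,
                       distance_mode = "greatcircle", alpha_enter = 0.05,
                       r2_min = 0.3, p_max = 0.1, n_perm = 999, seed = 1,
                       out_dir = NULL, select_rules = list(),
                       validation_exclude = character(0)) {
  cfg <- as.list(environment())
  stopifnot(evalue_max > 0, coverage_fraction >= 0, coverage_fraction <= 1,
            bias_ratio >= 1, rho_threshold > 0, rho_threshold <= 1,
            r2_min >= 0, r2_min < 1, alpha_enter > 0, alpha_enter < 1,
            p_max > 0, p_max < 1, idw_power > 0, k_neighbors >= 1,
            n_perm >= 1)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

#' One-command synthetic demo configuration
#'
#' A [run_config()] whose inputs are generated by the synthetic-data module
#' under the default study conditions (44 sites, 65 TFs, 53 SCGs, planted
#' environment/space fractions 0.35 / 0.06). `n_perm` defaults to a smaller
#' value than a production run to keep the demo fast.
#'
#' @param seed integer seed.
#' @param n_perm permutations (default 199).
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `run_config`.
#' @export
synthetic_demo_config <- function(seed = 1, n_perm = 199, ...) {
  run_config(spec = synthetic_spec(seed = seed, ...), n_perm = n_perm,
             seed = seed)
}

load_matrix <- function(x, what = "matrix") {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    df <- read.csv(x, row.names = 1, check.names = FALSE)
    return(as.matrix(df))
  }
  as.matrix(x)
}

load_sites <- function(x) {
  if (is.character(x) && length(x) == 1L) read_sites(x) else validate_sites(x)
}

load_climatologies <- function(x) {
  if (is.null(x)) return(NULL)
  lapply(x, function(g) if (is.character(g)) read_climatology(g) else g)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: sample selection (filter size, habitat,
#' contamination, SCG depth) -> SCG-mean standardization of TF counts ->
#' monthly interpolation, stability, z-scoring, collinearity pruning ->
#' geographic distances, PCoA, polynomial spatial terms -> forward/backward
#' RDA model selection and environment/space variation partitioning ->
#' per-TF stepwise regression screen. Stages whose outputs are supplied in
#' the config are skipped. All randomness derives from `config$seed`.
#'
#' @param config a [run_config()].
#' @return a summary list (also written as JSON when `out_dir` is set) with
#'   elements `n_samples`, `excluded`, `pruned_parameters`,
#'   `selected_terms`, `partition` (adjusted and raw fractions, p-values),
#'   `tf_screen` (Table-1-style data frame), `seed`, and the intermediate
#'   tables as attributes.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  t0 <- Sys.time()

  # --- input acquisition (synthetic generation or file/object loading) ----
  if (!is.null(config$spec)) {
    spec <- config$spec
    say("stage simulate: generating synthetic inputs (n_sites = %d)", spec$n_sites)
    sites <- make_sites(spec)
    grids <- lapply(setNames(nm = CLIM_PARAMETERS),
                    function(p) make_climatology(spec, p))
    stab_raw <- stability_table(grids, sites, config$idw_power,
                                config$k_neighbors)
    D_all <- distance_matrix(sites, config$distance_mode, config$composites)
    coords_all <- pcoa(D_all, k = 2)
    cnt <- make_counts(spec, stab_raw, coords_all$coords)
    tf_raw <- cnt$tf; scg_raw <- cnt$scg
    truth <- cnt$truth
  } else {
    truth <- NULL
    sites <- load_sites(config$sites)
    grids <- load_climatologies(config$climatologies)
    tf_raw <- load_matrix(config$tf_counts)
    scg_raw <- load_matrix(config$scg_counts)
    if (is.null(tf_raw) && !is.null(config$domtblout)) {
      say("stage counts: parsing %d domtblout files", length(config$domtblout))
      tf_list <- if (is.null(config$tf_model_list)) tf_models() else config$tf_model_list
      scg_list <- if (is.null(config$scg_model_list)) scg_models() else config$scg_model_list
      hits <- do.call(rbind, lapply(names(config$domtblout), function(s)
        parse_domtblout(config$domtblout[[s]], s)))
      if (anyNA(hits$model_length) && !is.null(config$model_lengths))
        hits$model_length <- config$model_lengths[hits$model_name]
      sig <- filter_significant(hits, config$coverage_fraction,
                                config$evalue_max, config$bias_ratio)
      say("stage filter: %d of %d hits significant", nrow(sig), nrow(hits))
      tf_raw <- build_count_matrix(sig, tf_list$model, sites$sample_id)
      attr(tf_raw, "category") <- setNames(tf_list$category, tf_list$model)
      scg_raw <- build_count_matrix(sig, scg_list$model, sites$sample_id)
    }
    if (is.null(tf_raw) || is.null(scg_raw))
      stop("stage counts: need tf_counts and scg_counts (or domtblout input)")
    stab_raw <- load_matrix(config$stability)
    D_all <- load_matrix(config$distances)
  }

  # --- sample selection --------------------------------------------------
  sel <- select_samples(sites, scg_raw, config$select_rules)
  say("stage select_samples: retained %d of %d samples (%d excluded)",
      length(sel$retained), ncol(scg_raw), nrow(sel$exclusion_log))

  # --- stability ---------------------------------------------------------
  if (is.null(stab_raw)) {
    if (is.null(grids)) stop("stage stability: need climatologies or a stability table")
    say("stage stability: interpolating %d parameters at %d sites",
        length(grids), nrow(sites))
    stab_raw <- stability_table(grids, sites, config$idw_power, config$k_neighbors)
  }
  keep <- intersect(sel$retained, rownames(stab_raw))
  complete <- keep[rowSums(is.na(stab_raw[keep, , drop = FALSE])) == 0]
  if (length(complete) < length(keep))
    say("stage stability: %d sample(s) dropped (no reliable interpolation)",
        length(keep) - length(complete))
  keep <- complete
  if (length(keep) < 10L)
    stop("stage stability: too few samples with complete stability data")
  tf_raw2 <- tf_raw[, keep, drop = FALSE]
  scg2 <- scg_raw[, keep, drop = FALSE]
  stab <- stab_raw[keep, , drop = FALSE]

  # --- standardization ---------------------------------------------------
  tf_std <- standardize_counts(tf_raw2, scg2)
  attr(tf_std, "category") <- attr(tf_raw, "category")
  say("stage standardize: divisor = mean SCG count (median %.1f)",
      median(attr(tf_std, "divisors")))

  stab_z <- zscore_stability(stab)
  pruned <- prune_collinear(stab_z, config$rho_threshold, config$priority)
  say("stage prune_collinear: retained {%s}", paste(pruned$retained, collapse = ", "))

  # --- space -------------------------------------------------------------
  if (is.null(D_all)) {
    D_all <- distance_matrix(sites, config$distance_mode, config$composites)
  }
  D <- D_all[keep, keep]
  coords <- pcoa(D, k = 2)
  sp_terms <- spatial_terms(coords, degree = 3)
  say("stage spatial: PCoA eigenvalues %s", paste(signif(head(coords$eig, 2), 4),
                                                  collapse = ", "))

  # --- ordination --------------------------------------------------------
  Y <- t(tf_std)
  Y <- Y[, apply(Y, 2, sd) > 0, drop = FALSE]
  env_cand <- as.data.frame(stab_z[, pruned$retained, drop = FALSE])
  candidates <- cbind(env_cand, sp_terms)
  selres <- select_model(Y, candidates, config$alpha_enter,
                         n_perm = min(config$n_perm, 199), seed = config$seed)
  env_sel <- intersect(selres$terms, colnames(env_cand))
  space_sel <- setdiff(selres$terms, env_sel)
  say("stage select_model: environment {%s}, space {%s}",
      paste(env_sel, collapse = ", "), paste(space_sel, collapse = ", "))

  partition <- NULL
  if (length(env_sel) > 0) {
    partition <- variation_partition(
      Y, candidates[, env_sel, drop = FALSE],
      if (length(space_sel)) candidates[, space_sel, drop = FALSE] else NULL,
      n_perm = config$n_perm, seed = config$seed)
    say("stage varpart: env %.3f, space %.3f, shared %.3f, residual %.3f (adjusted)",
        partition$adjusted["env_only"], partition$adjusted["space_only"],
        partition$adjusted["shared"], partition$adjusted["residual"])
  } else {
    say("stage varpart: skipped (no environment term selected)")
  }

  # --- per-TF regression -------------------------------------------------
  screen <- screen_all(tf_std, candidates, r2_min = config$r2_min,
                       p_max = config$p_max)
  say("stage screen_all: %d TFs with R^2 > %.2f", nrow(screen), config$r2_min)
  say("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  summary <- list(
    n_samples = length(keep),
    samples = keep,
    excluded = sel$exclusion_log,
    pruned_parameters = setdiff(colnames(stab_z), pruned$retained),
    retained_parameters = pruned$retained,
    selected_terms = list(environment = env_sel, space = space_sel),
    partition = if (!is.null(partition)) list(
      adjusted = as.list(partition$adjusted), raw = as.list(partition$raw),
      p_values = as.list(partition$p_values), n_perm = partition$n_perm),
    tf_screen = screen[, c("tf", "category", "model", "r_squared", "model_p")],
    seed = config$seed)
  attr(summary, "tables") <- list(stability = stab, stability_z = stab_z,
                                  tf_std = tf_std, distances = D,
                                  coords = coords, spatial_terms = sp_terms,
                                  truth = truth)
  attr(summary, "log") <- log_lines

  if (!is.null(config$out_dir)) write_outputs(summary, config)
  summary
}

write_outputs <- function(summary, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- attr(summary, "tables")
  wcsv <- function(x, name) write.csv(as.data.frame(x),
                                      file.path(config$out_dir, name))
  wcsv(tabs$stability, "stability_measures.csv")
  wcsv(tabs$tf_std, "tf_counts_standardized.csv")
  wcsv(tabs$distances, "sample_distances_km.csv")
  wcsv(cbind(tabs$coords$coords, tabs$spatial_terms[, -(1:2), drop = FALSE]),
       "spatial_terms.csv")
  write.csv(summary$tf_screen, file.path(config$out_dir, "tf_regression_table.csv"),
            row.names = FALSE)
  clean <- summary
  attributes(clean) <- list(names = names(summary))
  jsonlite::write_json(clean, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(attr(summary, "log"), file.path(config$out_dir, "run.log"))
  invisible(config$out_dir)
}

#' Validate interpolated against in-situ values for a site table
#'
#' For temperature and salinity (where climatologies and in-situ columns are
#' available), interpolates the monthly value at each site for its sampling
#' month and regresses it on the shipboard measurement, once with all sites
#' and once with the configured exclusions removed.
#'
#' @param config a [run_config()] with `sites` (including `date`,
#'   `insitu_temperature` / `insitu_salinity`) and `climatologies` for
#'   `temperature` / `salinity`; `validation_exclude` lists sample ids for
#'   the second fit.
#' @return named list per parameter: list with `all` and `excluded`
#'   [validate_interpolation()] reports (the latter `NULL` when nothing is
#'   excluded) and `pairs` (the per-site value table).
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sites <- load_sites(config$sites)
  grids <- load_climatologies(config$climatologies)
  if (is.null(grids)) stop("run_validation needs climatologies")
  if (!"date" %in% colnames(sites)) stop("site table needs a date column")
  months <- as.integer(format(as.Date(sites$date), "%m"))
  out <- list()
  for (p in intersect(c("temperature", "salinity"), names(grids))) {
    col <- paste0("insitu_", p)
    if (!col %in% colnames(sites)) stop("missing in-situ column: ", col)
    interp <- vapply(seq_len(nrow(sites)), function(i) {
      ser <- monthly_series(grids[[p]], sites[i, ], config$idw_power,
                            config$k_neighbors)
      if (ser$available) ser$values[months[i]] else NA_real_
    }, numeric(1))
    pairs <- data.frame(sample_id = sites$sample_id, insitu = sites[[col]],
                        interpolated = interp, stringsAsFactors = FALSE)
    all_fit <- validate_interpolation(pairs$insitu, pairs$interpolated,
                                      pairs$sample_id)
    exc_fit <- NULL
    if (length(config$validation_exclude)) {
      kp <- !pairs$sample_id %in% config$validation_exclude
      exc_fit <- validate_interpolation(pairs$insitu[kp], pairs$interpolated[kp],
                                        pairs$sample_id[kp])
    }
    out[[p]] <- list(all = all_fit, excluded = exc_fit, pairs = pairs)
  }
  out
}
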