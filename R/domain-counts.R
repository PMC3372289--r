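#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' Reads the 23-column per-domain table written by `hmmsearch --domtblout`
#' when translated reads are searched against profile HMMs (target = read,
#' query = model). Comment lines (`#`) are ignored. One `DomainHit` row is
#' returned per record with the fields the significance filter needs: model
#' name and length, hmm coordinates, domain independent E-value (`i-Evalue`),
#' domain bit score and bias.
#'
#' @param path path to a domtblout file, or `NULL` when `text` is given.
#' @param sample_id sample identifier attached to every hit.
#' @param text optional character vector of lines (instead of `path`).
#' @return data frame with columns `sample_id`, `read_id`, `model_name`,
#'   `model_length`, `hmm_from`, `hmm_to`, `independent_evalue`, `score`,
#'   `bias`.
#' @export
parse_domtblout <- function(path = NULL, sample_id, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(sample_id = character(0), read_id = character(0),
                      model_name = character(0), model_length = integer(0),
                      hmm_from = integer(0), hmm_to = integer(0),
                      independent_evalue = numeric(0), score = numeric(0),
                      bias = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    if (length(f) < 22L)
      stop("malformed domtblout record at line ", idx[i],
           ": expected >= 22 fields, got ", length(f))
    num <- suppressWarnings(as.numeric(f[c(6, 13, 14, 15, 16, 17)]))
    if (anyNA(num))
      stop("malformed domtblout record at line ", idx[i],
           ": non-numeric value in a numeric column")
    out[[i]] <- data.frame(sample_id = sample_id, read_id = f[1],
                           model_name = f[4], model_length = as.integer(num[1]),
                           hmm_from = as.integer(num[5]), hmm_to = as.integer(num[6]),
                           independent_evalue = num[2], score = num[3],
                           bias = num[4], stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  bad <- hits$hmm_from < 1 | hits$hmm_to < hits$hmm_from |
    hits$hmm_to > hits$model_length | hits$independent_evalue < 0
  if (any(bad))
    stop("invalid hmm coordinates or E-value at line ", idx[which(bad)[1]])
  hits
}

#' Keep only significant domain hits
#'
#' A hit is significant when all three criteria hold: (1) the domain
#' independent E-value is below `evalue_max`; (2) the aligned model span
#' `hmm_to - hmm_from` covers at least `coverage_fraction` of the model
#' length; (3) the composition bias is at least `bias_ratio` times smaller
#' than the bit score (ties pass). All thresholds are configurable.
#'
#' @param hits data frame from [parse_domtblout()].
#' @param coverage_fraction minimum model coverage (default 0.20).
#' @param evalue_max maximum independent E-value (default 0.001).
#' @param bias_ratio required score/bias ratio (default 10).
#' @return the subset of `hits` passing all three criteria.
#' @export
filter_significant <- function(hits, coverage_fraction = 0.20,
                               evalue_max = 0.001, bias_ratio = 10) {
  if (nrow(hits) == 0L) return(hits)
  if (anyNA(hits$model_length)) stop("missing model length")
  keep <- hits$independent_evalue < evalue_max &
    (hits$hmm_to - hits$hmm_from) >= coverage_fraction * hits$model_length &
    hits$bias * bias_ratio <= hits$score
  hits[keep, , drop = FALSE]
}

#' Assemble a model x sample count matrix from domain hits
#'
#' Each significant domain record counts once (per-domain counting; multiple
#' domains of one model on one read all count). Hits to models outside
#' `model_list` are ignored; their number is recorded in the `ignored_hits`
#' attribute.
#'
#' @param hits data frame of (filtered) hits.
#' @param model_list character vector of model names (rows).
#' @param sample_list character vector of sample ids (columns).
#' @return integer matrix `length(model_list)` x `length(sample_list)` with
#'   attribute `ignored_hits`.
#' @export
build_count_matrix <- function(hits, model_list, sample_list) {
  if (length(model_list) == 0L) stop("model_list must be non-empty")
  if (anyDuplicated(model_list)) stop("duplicate model names in model_list")
  mat <- matrix(0L, length(model_list), length(sample_list),
                dimnames = list(model_list, sample_list))
  ignored <- 0L
  if (nrow(hits) > 0L) {
    inlist <- hits$model_name %in% model_list & hits$sample_id %in% sample_list
    ignored <- sum(hits$model_name %in% model_list == FALSE)
    use <- hits[inlist, , drop = FALSE]
    if (nrow(use) > 0L) {
      tab <- table(factor(use$model_name, levels = model_list),
                   factor(use$sample_id, levels = sample_list))
      mat[] <- as.integer(tab)
    }
  }
  attr(mat, "ignored_hits") <- ignored
  mat
}

#' Single-copy-gene count diagnostics
#'
#' Within each sample, an SCG count is an outlier when it falls outside
#' `median +/- 1.5 * IQR` of that sample's SCG counts. A model is flagged
#' over-represented (under-represented) when it is a high (low) outlier in
#' more than half of the samples. Per-sample summary statistics (mean,
#' median, IQR, coefficient of variation) are returned alongside; systematic
#' outliers indicate cloning/sequencing bias or genuinely multi-copy genes.
#'
#' @param scg integer matrix of SCG counts, models x samples.
#' @return object of class `scg_diagnostics`: list with `per_model` (data
#'   frame: model, high/low outlier fractions, flags) and `per_sample`
#'   (data frame: mean, median, IQR, CV).
#' @export
scg_diagnostics <- function(scg) {
  scg <- as.matrix(scg)
  if (nrow(scg) < 2L || ncol(scg) < 2L)
    stop("need at least 2 SCG models and 2 samples")
  high <- low <- matrix(FALSE, nrow(scg), ncol(scg), dimnames = dimnames(scg))
  per_sample <- data.frame(sample_id = colnames(scg),
                           mean = colMeans(scg),
                           median = apply(scg, 2, median),
                           iqr = apply(scg, 2, function(x) diff(quantile(x, c(.25, .75)))),
                           cv = apply(scg, 2, function(x)
                             if (mean(x) > 0) sd(x) / mean(x) else 0),
                           row.names = NULL, stringsAsFactors = FALSE)
  for (s in seq_len(ncol(scg))) {
    med <- per_sample$median[s]; iqr <- per_sample$iqr[s]
    high[, s] <- scg[, s] > med + 1.5 * iqr
    low[, s] <- scg[, s] < med - 1.5 * iqr
  }
  per_model <- data.frame(model = rownames(scg),
                          frac_high = rowMeans(high), frac_low = rowMeans(low),
                          row.names = NULL, stringsAsFactors = FALSE)
  per_model$overrepresented <- per_model$frac_high > 0.5
  per_model$underrepresented <- per_model$frac_low > 0.5
  structure(list(per_model = per_model, per_sample = per_sample),
            class = "scg_diagnostics")
}

#' @export
print.scg_diagnostics <- function(x, ...) {
  cat(sprintf("SCG diagnostics: %d models x %d samples; %d overrepresented, %d underrepresented\n",
              nrow(x$per_model), nrow(x$per_sample),
              sum(x$per_model$overrepresented), sum(x$per_model$underrepresented)))
  invisible(x)
}

#' Select samples suitable for the TF analysis
#'
#' Applies the sample-exclusion rules in order and records the first reason
#' that fires: (1) the filter-size range must target prokaryotes (within
#' `rules$filter_range` micrometres); (2) freshwater habitats are excluded;
#' (3) samples on the named contamination list are excluded; (4) samples
#' whose mean SCG count is at or below `rules$min_mean_scg` carry too few
#' sequences to quantify gene content.
#'
#' @param sites site data frame (must include `habitat`, `filter_min_um`,
#'   `filter_max_um` for the corresponding rules to apply).
#' @param scg SCG count matrix (models x samples) covering the sites.
#' @param rules list overriding any of `filter_range` (default
#'   `c(0.1, 0.8)`), `exclude_habitat_pattern` (default `"fresh"`),
#'   `contaminated` (default `"GS000a"`), `min_mean_scg` (default 1).
#' @return list with `retained` (character vector of sample ids) and
#'   `exclusion_log` (data frame: sample_id, reason).
#' @export
select_samples <- function(sites, scg, rules = list()) {
  def <- list(filter_range = c(0.1, 0.8), exclude_habitat_pattern = "fresh",
              contaminated = "GS000a", min_mean_scg = 1)
  rules <- modifyList(def, rules)
  ids <- colnames(scg)
  missing <- setdiff(ids, sites$sample_id)
  if (length(missing))
    stop("samples in counts but absent from metadata: ",
         paste(missing, collapse = ", "))
  sites <- sites[match(ids, sites$sample_id), , drop = FALSE]
  reason <- rep(NA_character_, length(ids))

  if (all(c("filter_min_um", "filter_max_um") %in% colnames(sites))) {
    bad <- sites$filter_min_um < rules$filter_range[1] - 1e-9 |
      sites$filter_max_um > rules$filter_range[2] + 1e-9
    reason[is.na(reason) & bad] <- "filter size"
  }
  if ("habitat" %in% colnames(sites)) {
    bad <- grepl(rules$exclude_habitat_pattern, sites$habitat, ignore.case = TRUE)
    reason[is.na(reason) & bad] <- "freshwater habitat"
  }
  reason[is.na(reason) & ids %in% rules$contaminated] <- "suspected contamination"
  mean_scg <- colMeans(scg)
  reason[is.na(reason) & mean_scg <= rules$min_mean_scg] <- "low SCG counts"

  list(retained = ids[is.na(reason)],
       exclusion_log = data.frame(sample_id = ids[!is.na(reason)],
                                  reason = reason[!is.na(reason)],
                                  stringsAsFactors = FALSE))
}

#' Standardize TF counts to genome equivalents
#'
#' Divides each sample's raw TF counts by a per-sample statistic of its SCG
#' counts: the mean (default, the per-sample genome-equivalent estimate), or
#' the mean plus/minus `k` standard deviations (sensitivity variants;
#' comparing results under `mean_plus_ksd` and `mean_minus_ksd` brackets the
#' uncertainty of the genome-equivalent estimate).
#'
#' @param tf raw TF count matrix, models x samples.
#' @param scg raw SCG count matrix, models x samples (same samples).
#' @param divisor `"mean"`, `"mean_plus_ksd"` or `"mean_minus_ksd"`.
#' @param k number of standard deviations for the ksd variants (default 2).
#' @return numeric matrix of standardized abundances with attributes
#'   `divisor_type` and `divisors` (the per-sample divisor).
#' @export
standardize_counts <- function(tf, scg,
                               divisor = c("mean", "mean_plus_ksd", "mean_minus_ksd"),
                               k = 2) {
  divisor <- match.arg(divisor)
  if (!identical(colnames(tf), colnames(scg)))
    stop("tf and scg matrices must share the same sample columns")
  mu <- colMeans(scg)
  s <- apply(scg, 2, sd)
  div <- switch(divisor, mean = mu, mean_plus_ksd = mu + k * s,
                mean_minus_ksd = mu - k * s)
  if (any(div <= 0))
    stop("non-positive standardization divisor for sample(s): ",
         paste(colnames(scg)[div <= 0], collapse = ", "))
  out <- sweep(tf, 2, div, "/")
  attr(out, "divisor_type") <- divisor
  attr(out, "divisors") <- div
  out
}

#' Packaged default TF / SCG model lists
#'
#' Editable plain-text defaults shipped with the package: 65 prokaryotic
#' transcription-factor Pfam domain models (40 DNA-binding-domain, 25
#' effector/receiver "non-DBD" models) and 53 universal single-copy-gene
#' models. The lists contain the families named in the source analyses
#' plus representative members of the same curated collections; both are
#' reconstructions intended as sensible defaults, not authoritative copies,
#' and real studies should supply their own lists.
#'
#' @return data frame with columns `model`, `pfam`, `category` (TF list) or
#'   `model`, `pfam` (SCG list).
#' @export
tf_models <- function() {
  read.table(system.file("extdata", "tf_models_synthetic_default.tsv",
                         package = "tfstab"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname tf_models
#' @export
scg_models <- function() {
  read.table(system.file("extdata", "scg_models_synthetic_default.tsv",
                         package = "tfstab"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
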