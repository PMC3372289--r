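fixture_path <- function() {
  system.file("extdata", "example.domtblout", package = "tfstab")
}

test_that("domtblout parsing extracts the documented fields and rejects bad records", {
  # comments-only input: empty hit list
  expect_equal(nrow(parse_domtblout(text = c("# a comment", "#"), "s1")), 0L)

  hits <- parse_domtblout(fixture_path(), "s1")
  expect_equal(nrow(hits), 10L)
  first <- hits[1, ]
  expect_equal(first$read_id, "read00001")
  expect_equal(first$model_name, "TF_A")
  expect_equal(first$model_length, 100L)
  expect_equal(first$hmm_from, 1L)
  expect_equal(first$hmm_to, 51L)
  expect_equal(first$independent_evalue, 1e-5)
  expect_equal(first$score, 50)
  expect_equal(first$bias, 2)

  bad <- "read1 - 120 TF_A - 100 1e-5 50 2 1 1 5e-6 oops 50 2 1 51 1 51 1 60 0.9 -"
  expect_error(parse_domtblout(text = bad, "s1"), "non-numeric")
  expect_error(parse_domtblout(text = "read1 - 120 TF_A", "s1"), "fields")
})

test_that("the three significance criteria act independently and monotonically", {
  hits <- parse_domtblout(fixture_path(), "s1")
  sig <- filter_significant(hits)
  expect_equal(nrow(sig), 6L)

  # boundary: coverage exactly 20% of the model length passes (>= rule)
  boundary <- hits[hits$read_id == "read00002", ]
  expect_equal(boundary$hmm_to - boundary$hmm_from, 20L)
  expect_equal(nrow(filter_significant(boundary)), 1L)
  shrunk <- boundary; shrunk$hmm_to <- 20L; shrunk$hmm_from <- 1L
  expect_equal(nrow(filter_significant(shrunk)), 0L)  # 19 < 20

  # bias tie (bias * ratio == score) passes
  tie <- boundary; tie$bias <- tie$score / 10
  expect_equal(nrow(filter_significant(tie)), 1L)

  # monotone: tightening any threshold yields a subset
  base <- filter_significant(hits)
  for (args in list(list(coverage_fraction = 0.5), list(evalue_max = 1e-6),
                    list(bias_ratio = 40))) {
    tight <- do.call(filter_significant, c(list(hits), args))
    expect_true(all(tight$read_id %in% base$read_id))
  }
})

test_that("count matrices tally surviving hits and ignore unlisted models", {
  hits <- filter_significant(parse_domtblout(fixture_path(), "s1"))
  m <- build_count_matrix(hits, c("TF_A", "TF_B"), "s1")
  expect_equal(m["TF_A", "s1"], 3L)
  expect_equal(m["TF_B", "s1"], 3L)
  expect_equal(sum(m), nrow(hits))

  m2 <- build_count_matrix(hits, c("TF_A", "OTHER"), "s1")
  expect_equal(m2["TF_A", "s1"], 3L)
  expect_equal(m2["OTHER", "s1"], 0L)
  expect_equal(attr(m2, "ignored_hits"), 3L)

  empty <- build_count_matrix(hits[0, ], c("a", "b"), c("s1", "s2"))
  expect_true(all(empty == 0L))
  expect_equal(dim(empty), c(2L, 2L))
  expect_error(build_count_matrix(hits, c("a", "a"), "s1"), "duplicate")
})

test_that("SCG diagnostics flag systematic outliers under the IQR rule", {
  even <- matrix(5L, 6, 4, dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  d <- scg_diagnostics(even)
  expect_true(all(!d$per_model$overrepresented & !d$per_model$underrepresented))
  expect_equal(d$per_sample$cv, rep(0, 4))
  expect_equal(d$per_sample$mean, rep(5, 4))

  spiked <- even; spiked["g1", ] <- 50L
  d2 <- scg_diagnostics(spiked)
  expect_true(d2$per_model$overrepresented[d2$per_model$model == "g1"])
  expect_equal(d2$per_model$frac_high[d2$per_model$model == "g1"], 1)

  one <- matrix(c(2, 4, 6), 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(scg_diagnostics(one)$per_sample$mean, c(4, 4))
  expect_error(scg_diagnostics(even[1, , drop = FALSE]), "at least 2")
})

test_that("sample selection applies each exclusion rule with a logged reason", {
  sites <- data.frame(
    sample_id = paste0("s", 1:5),
    latitude = 0, longitude = 0, depth_m = 1,
    habitat = c("open ocean", "fresh water estuary", "open ocean",
                "coastal water", "open ocean"),
    filter_min_um = c(0.1, 0.1, 0.1, 0.1, 0.1),
    filter_max_um = c(0.8, 0.8, 3.0, 0.8, 0.8),
    stringsAsFactors = FALSE)
  scg <- matrix(10L, 4, 5, dimnames = list(paste0("g", 1:4), sites$sample_id))
  scg[, "s5"] <- 0:3 %/% 3   # mean 0.25 <= 1: too shallow
  sel <- select_samples(sites, scg, rules = list(contaminated = "s4"))
  expect_equal(sel$retained, "s1")
  log <- sel$exclusion_log
  expect_equal(log$reason[log$sample_id == "s2"], "freshwater habitat")
  expect_equal(log$reason[log$sample_id == "s3"], "filter size")
  expect_equal(log$reason[log$sample_id == "s4"], "suspected contamination")
  expect_equal(log$reason[log$sample_id == "s5"], "low SCG counts")

  expect_error(select_samples(sites[1:3, ], scg), "absent from metadata")
})

test_that("SCG standardization divides by the chosen per-sample statistic", {
  scg <- matrix(c(2, 4, 6), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  tf <- matrix(8, 1, 1, dimnames = list("TF_A", "s1"))
  expect_equal(unname(standardize_counts(tf, scg)["TF_A", "s1"]), 2)
  # sample SD of {2,4,6} is 2: mean + 2 SD = 8
  expect_equal(unname(standardize_counts(tf, scg, "mean_plus_ksd", k = 2)["TF_A", "s1"]), 1)
  expect_error(standardize_counts(tf, scg, "mean_minus_ksd", k = 2), "non-positive")

  # uniform per-sample scaling of raw counts cancels (genome equivalents)
  set.seed(3)
  tf2 <- matrix(rpois(20, 5), 4, 5, dimnames = list(paste0("t", 1:4), paste0("s", 1:5)))
  scg2 <- matrix(rpois(15, 8) + 1L, 3, 5, dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  s1 <- standardize_counts(tf2, scg2)
  s2 <- standardize_counts(sweep(tf2, 2, c(2, 3, 1, 5, 4), "*"),
                           sweep(scg2, 2, c(2, 3, 1, 5, 4), "*"))
  expect_equal(unclass(s1)[, ], unclass(s2)[, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("packaged model lists have the documented sizes and categories", {
  tf <- tf_models()
  expect_equal(nrow(tf), 65L)
  expect_equal(sum(tf$category == "DBD"), 40L)
  expect_equal(sum(tf$category == "non-DBD"), 25L)
  expect_equal(anyDuplicated(tf$model), 0L)
  scg <- scg_models()
  expect_equal(nrow(scg), 53L)
  expect_equal(anyDuplicated(scg$model), 0L)
})
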