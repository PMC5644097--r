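make_scan_fixture <- function(g = 30, m = 60, B = 400, seed = 2,
                              tail = 0.05) {
  mat <- transform_matrix(noise_matrix(g, m, seed = seed))
  ref <- build_reference_distribution(mat, B, seed = seed + 1)
  cfg <- scan_config(tail_quantile = tail, n_permutations = B,
                     seed = seed, leader_min_linkages = 1)
  list(mat = mat, ref = ref, cfg = cfg)
}

test_that("scan_all enumerates pair-by-conditioner combinations", {
  fx <- make_scan_fixture(g = 4, m = 30, B = 100, tail = 0.4)
  res <- suppressMessages(scan_all(fx$mat, fx$ref, fx$cfg))
  expect_identical(attr(res, "n_evaluated"), 12L)   # C(4,2) * 2
  expect_identical(attr(res, "n_pairs"), 6L)
  # no triplet uses a pair member as its own conditioner
  expect_true(all(res$z_id != res$x_id & res$z_id != res$y_id))
})

test_that("scan_all rejects an untransformed matrix unless overridden", {
  fx <- make_scan_fixture(g = 5, m = 30, B = 50, tail = 0.3)
  raw <- noise_matrix(5, 30, seed = 77) + 5
  expect_error(suppressMessages(scan_all(raw, fx$ref, fx$cfg)),
               "transform")
  expect_silent(suppressMessages(scan_all(raw, fx$ref, fx$cfg,
                                          override_transform_check = TRUE)))
})

test_that("scan hits agree with direct la_score and the reference p-values", {
  fx <- make_scan_fixture(g = 20, m = 50, B = 300, tail = 0.1)
  res <- suppressMessages(scan_all(fx$mat, fx$ref, fx$cfg))
  expect_gt(nrow(res), 0)
  thr <- la_threshold(fx$ref, 0.1)
  for (k in seq_len(min(nrow(res), 25L))) {
    s <- la_score(fx$mat[res$x_id[k], ], fx$mat[res$y_id[k], ],
                  fx$mat[res$z_id[k], ])
    expect_equal(res$la[k], s, tolerance = 1e-12)
    expect_true(s >= thr[["pos"]] || s <= thr[["neg"]])
    expect_identical(res$p_value[k], permutation_p_value(res$la[k], fx$ref))
    expect_true(res$scout_id[k] %in%
                  c(res$x_id[k], res$y_id[k], res$z_id[k]))
  }
})

test_that("scan results are deterministic and files byte-identical", {
  fx <- make_scan_fixture(g = 15, m = 40, B = 200, tail = 0.1)
  r1 <- suppressMessages(scan_all(fx$mat, fx$ref, fx$cfg))
  r2 <- suppressMessages(scan_all(fx$mat, fx$ref, fx$cfg))
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_triplet_results(r1, f1)
  write_triplet_results(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("conditional-LAP filter applies magnitude thresholds and conserves", {
  res <- data.frame(x_id = letters[1:4], y_id = letters[5:8],
                    z_id = letters[9:12],
                    r_xy = c(0.05, 0.30, 0.05, -0.10),
                    la = c(0.70, 0.70, -0.65, 0.20))
  kept <- classify_conditional_laps(res, 0.17, 0.60)
  expect_identical(kept$x_id, c("a", "c"))   # negative LA retained by |.|
  expect_identical(nrow(kept) + nrow(res[setdiff(rownames(res),
                                                 rownames(kept)), ]),
                   nrow(res))
})

test_that("linkage counting tallies by scout and sign, conserving totals", {
  res <- data.frame(scout_id = c("A", "A", "A", "B"),
                    la = c(0.5, 0.2, -0.3, -0.8))
  cnt <- count_linkages_per_scout(res)
  expect_identical(cnt$n_positive[cnt$scout_id == "A"], 2L)
  expect_identical(cnt$n_negative[cnt$scout_id == "A"], 1L)
  expect_identical(sum(cnt$n_positive) + sum(cnt$n_negative), nrow(res))
  expect_identical(nrow(count_linkages_per_scout(res[0, ])), 0L)
  # brute-force group-by oracle on a random result set
  set.seed(9)
  big <- data.frame(scout_id = sample(LETTERS[1:6], 200, replace = TRUE),
                    la = rnorm(200))
  cb <- count_linkages_per_scout(big)
  for (s in cb$scout_id) {
    expect_identical(cb$n_positive[cb$scout_id == s],
                     sum(big$scout_id == s & big$la >= 0))
    expect_identical(cb$n_negative[cb$scout_id == s],
                     sum(big$scout_id == s & big$la < 0))
  }
})

test_that("leader selection is sign-specific and inclusive at the cutoff", {
  cnt <- data.frame(scout_id = c("A", "B", "C"),
                    n_positive = c(6L, 2L, 5L),
                    n_negative = c(0L, 9L, 1L))
  expect_identical(select_leaders(cnt, 5, "positive")$scout_id, c("A", "C"))
  expect_identical(select_leaders(cnt, 5, "negative")$scout_id, "B")
  # boundary: exactly min_linkages qualifies
  expect_true("C" %in% select_leaders(cnt, 5, "positive")$scout_id)
  expect_identical(nrow(select_leaders(cnt, 10, "positive")), 0L)
  expect_error(select_leaders(cnt, 0, "positive"), "min_linkages")
})

test_that("network export deduplicates edges keeping the largest |LA|", {
  res <- data.frame(x_id = c("f1", "f1", "f2", "o1"),
                    z_id = c("m1", "m1", "m2", "m1"),
                    la = c(0.25, 0.30, -0.4, 0.9),
                    p_value = c(0.01, 0.02, 0.001, 0.5))
  net <- export_network(res, focus_genes = c("f1", "f2"))
  expect_identical(nrow(net), 2L)
  expect_identical(net$la[net$x_id == "f1"], 0.30)
  expect_identical(attr(net, "n_nodes"), 4L)
  empty <- export_network(res, focus_genes = "nope")
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "n_nodes"), 0L)
  # join oracle: edge count equals distinct (focus, conditioner) pairs
  set.seed(10)
  big <- data.frame(x_id = sample(c("f1", "f2", "f3"), 100, replace = TRUE),
                    z_id = sample(paste0("m", 1:10), 100, replace = TRUE),
                    la = rnorm(100), p_value = runif(100))
  nb <- export_network(big, c("f1", "f2", "f3"))
  expect_identical(nrow(nb), nrow(unique(big[c("x_id", "z_id")])))
})

test_that("noise-matrix pass rate matches the tail expectation", {
  fx <- make_scan_fixture(g = 40, m = 80, B = 2000, seed = 6, tail = 1e-3)
  res <- suppressMessages(scan_all(fx$mat, fx$ref, fx$cfg))
  # threshold is on per-pair extremes: expected passing pairs ~ n_pairs * q per sign
  n_pairs <- attr(res, "n_pairs")
  expected <- 2 * n_pairs * 1e-3
  n_pass_pairs <- nrow(unique(res[c("x_id", "y_id")]))
  expect_lte(n_pass_pairs, expected + 3 * sqrt(expected) + 1)
})
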