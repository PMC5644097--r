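test_that("la_score is the mean triple product", {
  expect_identical(la_score(c(2, 0, -2), c(1, -1, 0), c(0.5, 1, -1)), 1 / 3)
  expect_identical(la_score(rnorm(5), rnorm(5), rep(0, 5)), 0)
  expect_error(la_score(1:4, 1:3, 1:4), "equal length")
  expect_error(la_score(1:2, 1:2, 1:2), "at least 3")
})

test_that("la_score is symmetric in its three arguments", {
  set.seed(3)
  for (rep in 1:25) {
    x <- rnorm(12); y <- rnorm(12); z <- rnorm(12)
    s <- la_score(x, y, z)
    perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (p in perms) {
      args <- list(x, y, z)[p]
      expect_equal(la_score(args[[1]], args[[2]], args[[3]]), s,
                   tolerance = 1e-12)
    }
  }
})

test_that("la_scan_for_pair equals the scalar loop over conditioners", {
  mat <- noise_matrix(10, 20, seed = 5)
  out <- la_scan_for_pair(mat, 2, 7)
  expect_length(out, 8L)
  brute <- sapply(setdiff(1:10, c(2, 7)),
                  function(j) la_score(mat[2, ], mat[7, ], mat[j, ]))
  expect_identical(unname(out), brute)
  # name-based lookup agrees with index-based
  expect_identical(la_scan_for_pair(mat, "g002", "g007"), out)
  expect_error(la_scan_for_pair(mat, 1, 1), "distinct")
  expect_error(la_scan_for_pair(mat, 0, 2), "out of range")
  # identical rows: every score is mean(r^3)
  r <- rnorm(20)
  same <- matrix(rep(r, each = 4), nrow = 4)
  expect_equal(unname(la_scan_for_pair(same, 1, 2)),
               rep(mean(r^3), 2), tolerance = 1e-12)
})

test_that("conditional correlations recover planted group structure", {
  z <- 1:9
  x <- rnorm(9)
  y <- x                      # perfect correlation everywhere
  y[1:3] <- -x[1:3]           # except anticorrelated in the low tercile
  cc <- conditional_correlations(x, y, z)
  expect_equal(unname(cc$correlations[["high"]]), 1)
  expect_equal(unname(cc$correlations[["low"]]), -1)
  expect_identical(cc$groups, rep(1:3, each = 3))
})

test_that("conditional correlations match explicit slicing", {
  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    cc <- conditional_correlations(x, y, z, 3)
    ord <- order(z)
    slices <- list(ord[1:10], ord[11:20], ord[21:30])
    for (i in 1:3)
      expect_identical(unname(cc$correlations[i]),
                       cor(x[slices[[i]]], y[slices[[i]]]))
  }
  # a group of 2 is reported absent with a warning, not an error
  expect_warning(cc <- conditional_correlations(rnorm(5), rnorm(5), rnorm(5),
                                                n_groups = 2),
                 "fewer than 3")
  expect_true(anyNA(cc$correlations))
})

test_that("mla reproduces the plug-in estimator on constructed bins", {
  # three bins with x3 means (-1, 0, 1) and exact within-bin
  # correlations (-0.6, 0, 0.6)
  u <- c(-1, 0, 1)            # within-bin carrier, sd-free correlation design
  w <- c(1, -2, 1)            # orthogonal to u
  x1 <- rep(u, 3)
  x2 <- c(-0.6 * u + (0.8 / sqrt(3)) * w,     # cor = -0.6
          w,                                   # cor = 0
          0.6 * u + (0.8 / sqrt(3)) * w)      # cor = +0.6
  x3 <- c(-1.1, -1.0, -0.9, -0.1, 0.0, 0.1, 0.9, 1.0, 1.1)
  expect_equal(mla(x1, x2, x3, 3), 0.4, tolerance = 1e-12)
})

test_that("mla cancels when bin correlations are constant and means sum to 0", {
  u <- c(-1, 0, 1); w <- c(1, -2, 1)
  x1 <- rep(u, 3)
  x2 <- rep(0.5 * u + (sqrt(0.75) / sqrt(3)) * w, 3)   # cor = 0.5 in every bin
  x3 <- c(-3, -2.8, -2.6, -0.2, 0, 0.2, 2.6, 2.8, 3)   # bin means -2.8, 0, 2.8
  expect_equal(mla(x1, x2, x3, 3), 0, tolerance = 1e-12)
})

test_that("mla equals the brute-force binned oracle on random instances", {
  set.seed(13)
  for (rep in 1:100) {
    m <- sample(12:60, 1)
    x1 <- rnorm(m); x2 <- rnorm(m); x3 <- rnorm(m)
    expect_equal(mla(x1, x2, x3, 3), oracle_mla(x1, x2, x3, 3),
                 tolerance = 1e-12)
  }
  expect_error(mla(rep(1, 12), rnorm(12), rnorm(12)), "bin 1")
  expect_error(mla(rnorm(6), rnorm(6), rnorm(6), 3), "at least 9")
})

test_that("scouting designation finds a correlation-flipping conditioner", {
  set.seed(21)
  m <- 300
  trip <- draw_planted_triplet(theta = 1.2, m = m)
  sc <- assign_scouting_gene(trip$x, trip$y, trip$z,
                             ids = c("gx", "gy", "gz"))
  expect_identical(sc$scout_id, "gz")
  expect_identical(names(sc$mla_values), c("gx", "gy", "gz"))
  # brute-force check of all three conditioner roles
  expect_equal(unname(sc$mla_values),
               c(oracle_mla(trip$y, trip$z, trip$x),
                 oracle_mla(trip$x, trip$z, trip$y),
                 oracle_mla(trip$x, trip$y, trip$z)),
               tolerance = 1e-12)
})

test_that("scouting designation is total and order-invariant away from ties", {
  set.seed(22)
  # independent noise: still returns a well-defined scout
  sc <- assign_scouting_gene(rnorm(60), rnorm(60), rnorm(60))
  expect_true(sc$scout_id %in% c("x", "y", "z"))
  # permuting the input order of a strict-maximum triplet keeps the scout
  trip <- draw_planted_triplet(theta = 1.5, m = 400)
  ids <- c("a", "b", "c")
  s1 <- assign_scouting_gene(trip$x, trip$y, trip$z, ids = ids)
  s2 <- assign_scouting_gene(trip$z, trip$x, trip$y, ids = ids[c(3, 1, 2)])
  expect_identical(s1$scout_id, s2$scout_id)
})

test_that("null la_score has mean 0 and sd near 1/sqrt(m)", {
  set.seed(31)
  m <- 368L
  reps <- 2000L
  s <- replicate(reps, la_score(rnorm(m), rnorm(m), rnorm(m)))
  expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(reps))
  expect_equal(sd(s), 1 / sqrt(m), tolerance = 0.10)
})

test_that("trivariate-normal data with constant correlation gives null LA", {
  set.seed(32)
  # fixed correlation structure: all third moments vanish
  S <- matrix(c(1, .5, .3, .5, 1, .4, .3, .4, 1), 3)
  L <- chol(S)
  m <- 100L
  s <- replicate(2000, {
    d <- matrix(rnorm(3 * m), ncol = 3) %*% L
    la_score(d[, 1], d[, 2], d[, 3])
  })
  expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(length(s)))
})

test_that("planted positive scouts give positive LA and rising terciles", {
  set.seed(33)
  m <- 368L
  ok_sign <- ok_cc <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    trip <- draw_planted_triplet(0.5, m)
    ok_sign <- ok_sign + (la_score(trip$x, trip$y, trip$z) > 0)
    cc <- conditional_correlations(trip$x, trip$y, trip$z)$correlations
    ok_cc <- ok_cc + (cc[["high"]] > cc[["low"]])
  }
  expect_gte(ok_sign / reps, 0.99)
  expect_gte(ok_cc / reps, 0.99)
})
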