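#' Build a permutation reference distribution of extreme LA scores
#'
#' Under the assumption of no linkage, each permutation constructs two null
#' profiles X and Y, scores LA against every gene of the matrix in the Z
#' role, and records the most positive and most negative score. The sorted
#' extremes over all permutations form the reference distributions used for
#' tail thresholds and empirical P values.
#'
#' Two null constructions are available. \code{"cells"} (the default)
#' resamples m cells uniformly with replacement from the whole matrix for
#' each null profile and then normal-score transforms it: gene identity is
#' destroyed while the global expression-value distribution is preserved.
#' \code{"rows"} draws two distinct real gene rows as X and Y and scores
#' them against all other genes; this is the genome-wide score distribution
#' used for quantile-quantile comparison against the null, not a null
#' itself. A custom \code{null_profile_fn(mat, b)} returning
#' \code{list(x =, y =)} (used as-is, no further transform) can be injected,
#' e.g. to make the sampler deterministic in tests.
#'
#' Each permutation b draws from its own sub-stream
#' \code{derive_seed(seed, b)}, so results are independent of execution
#' order.
#'
#' @param mat transformed gene x sample matrix with >= 3 genes.
#' @param n_permutations number of permutations B >= 1.
#' @param seed master integer seed.
#' @param sampler \code{"cells"} or \code{"rows"}; ignored when
#'   \code{null_profile_fn} is given.
#' @param null_profile_fn optional injectable profile source (see Details).
#' @return an object of class \code{la_reference}: list with sorted
#'   \code{pos_extremes}, \code{neg_extremes}, \code{n_permutations},
#'   \code{seed}, \code{sampler}.
#' @export
build_reference_distribution <- function(mat, n_permutations, seed = 1L,
                                         sampler = c("cells", "rows"),
                                         null_profile_fn = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3L)
  B <- as.integer(n_permutations)
  if (is.na(B) || B < 1L) stop("'n_permutations' must be >= 1")
  sampler <- if (is.null(null_profile_fn)) match.arg(sampler) else "injected"
  m <- ncol(mat)
  g <- nrow(mat)
  pool <- as.vector(mat[!is.na(mat)])
  pos <- numeric(B)
  neg <- numeric(B)
  for (b in seq_len(B)) {
    if (!is.null(null_profile_fn)) {
      prof <- null_profile_fn(mat, b)
      x <- prof$x; y <- prof$y
      z_rows <- seq_len(g)
    } else if (sampler == "cells") {
      set.seed(derive_seed(seed, b))
      x <- nqt_resample(pool, m)
      y <- nqt_resample(pool, m)
      z_rows <- seq_len(g)
    } else {  # rows
      set.seed(derive_seed(seed, b))
      ij <- sample.int(g, 2L)
      x <- mat[ij[1L], ]
      y <- mat[ij[2L], ]
      z_rows <- setdiff(seq_len(g), ij)
    }
    s <- as.vector(mat[z_rows, , drop = FALSE] %*% (x * y)) / m
    pos[b] <- max(s)
    neg[b] <- min(s)
  }
  structure(list(pos_extremes = sort(pos), neg_extremes = sort(neg),
                 n_permutations = B, seed = as.integer(seed),
                 sampler = sampler),
            class = "la_reference")
}

# resample m cells and normal-score transform; retries the (practically
# impossible) all-identical draw
nqt_resample <- function(pool, m) {
  for (try in 1:100) {
    v <- pool[sample.int(length(pool), m, replace = TRUE)]
    if (v[1L] != v[2L] || length(unique(v)) > 1L)
      return(normal_quantile_transform(v))
  }
  stop("could not draw a non-degenerate null profile")
}

#' @export
print.la_reference <- function(x, ...) {
  cat("LA permutation reference distribution\n")
  cat("  permutations:", x$n_permutations, " sampler:", x$sampler,
      " seed:", x$seed, "\n")
  cat("  pos extremes: [", format(min(x$pos_extremes), digits = 4), ", ",
      format(max(x$pos_extremes), digits = 4), "]\n", sep = "")
  cat("  neg extremes: [", format(min(x$neg_extremes), digits = 4), ", ",
      format(max(x$neg_extremes), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Tail-quantile LA thresholds from a reference distribution
#'
#' The positive threshold is the ceiling(B * q)-th largest recorded
#' positive extreme, so that exactly a fraction q of the reference
#' extremes are at or above it (inverse empirical CDF, no interpolation;
#' thresholds are bit-reproducible). The negative threshold is the
#' mirrored order statistic of the negative extremes.
#'
#' @param ref an \code{la_reference}.
#' @param tail_quantile tail mass q in (0, 1); the genome-wide screening
#'   convention is 1e-5 at full scale.
#' @return named numeric vector \code{c(pos =, neg =)}.
#' @export
la_threshold <- function(ref, tail_quantile) {
  stopifnot(inherits(ref, "la_reference"))
  q <- tail_quantile
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'tail_quantile' must be in (0, 1)")
  B <- ref$n_permutations
  if (B < 1L || length(ref$pos_extremes) == 0L) stop("empty reference")
  if (B < 1 / q)
    warning("only ", B, " permutations for a ", format(q),
            " tail; threshold is the sample extreme (degenerate estimate)")
  k <- max(1L, min(B, as.integer(ceiling(B * q))))
  pos <- sort(ref$pos_extremes, decreasing = TRUE)[k]
  neg <- sort(ref$neg_extremes)[k]
  c(pos = pos, neg = neg)
}

#' Empirical permutation P value of an LA score
#'
#' How often the reference extremes are at least as extreme as the score,
#' matching the score's sign: for positive scores the positive extremes at
#' or above it, for negative scores the negative extremes at or below it.
#' Uses the add-one convention p = (1 + count) / (B + 1), so p is never 0.
#'
#' @param score numeric vector of LA scores (finite).
#' @param ref an \code{la_reference}.
#' @return numeric vector of P values in (0, 1].
#' @export
permutation_p_value <- function(score, ref) {
  stopifnot(inherits(ref, "la_reference"))
  if (any(!is.finite(score))) stop("scores must be finite")
  B <- ref$n_permutations
  vapply(score, function(s) {
    cnt <- if (s >= 0) sum(ref$pos_extremes >= s) else sum(ref$neg_extremes <= s)
    (1 + cnt) / (B + 1)
  }, numeric(1))
}

#' Plug-in false discovery rate FDR = N p / D
#'
#' Assumes the proportion of null cases is 100 percent: with N candidate
#' pairs tested at permutation P-value cutoff p and D discoveries, the
#' expected number of false discoveries is N p, giving FDR = N p / D,
#' capped at 1.
#'
#' @param n_pairs number of candidate pairs N (>= 1).
#' @param p_cutoff permutation P-value cutoff p in (0, 1].
#' @param n_discoveries number of discoveries D (>= 0).
#' @return estimated FDR in [0, 1], or \code{NA} when D = 0.
#' @export
estimate_fdr <- function(n_pairs, p_cutoff, n_discoveries) {
  if (n_pairs < 1) stop("'n_pairs' must be >= 1")
  if (p_cutoff <= 0 || p_cutoff > 1) stop("'p_cutoff' must be in (0, 1]")
  if (n_discoveries < 0) stop("'n_discoveries' must be >= 0")
  if (n_discoveries == 0) return(NA_real_)
  min(1, n_pairs * p_cutoff / n_discoveries)
}

#' Local permutation P value for one triplet
#'
#' Permutes the sample pairing between the conditioner Z and the pair
#' (X, Y) \code{n_perm} times, recomputes the LA score each time, and
#' returns the add-one empirical P value: how often the permuted scores
#' are at least as extreme as the observed score, i.e.
#' |score_perm| >= |score_obs|. Counting by magnitude keeps the P value
#' calibrated (uniform under the null); counting only the observed score's
#' side after looking at its sign would reject at twice the nominal rate.
#' This is the significance assessment used for within-pathway and
#' gene-trait LA, where the genome-wide reference is too strict.
#'
#' @param x,y,z transformed numeric vectors of equal length.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param early_stop optional exceedance count at which to stop early and
#'   return the P value based on permutations done so far (sequential
#'   Monte Carlo; default \code{Inf} runs all \code{n_perm}). Useful when
#'   screening many triplets for a small cutoff.
#' @return P value in (0, 1].
#' @export
local_permutation_p <- function(x, y, z, n_perm, seed = 1L, early_stop = Inf) {
  m <- length(z)
  if (length(x) != m || length(y) != m) stop("profiles must have equal length")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("'n_perm' must be >= 1")
  obs <- abs(la_score(x, y, z))
  xy <- x * y
  set.seed(derive_seed(seed, 0L))
  cnt <- 0L
  done <- 0L
  for (b in seq_len(n_perm)) {
    s <- sum(xy[sample.int(m)] * z) / m
    cnt <- cnt + (abs(s) >= obs)
    done <- b
    if (cnt >= early_stop) break
  }
  (1 + cnt) / (done + 1)
}
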