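#' Liquid association score of a gene triplet
#'
#' The LA score of (X, Y | Z) is the average triple product
#' \eqn{\sum_i x_i y_i z_i / m} over the m samples. On normal-score
#' transformed profiles this estimates E(XYZ), which by Stein's lemma equals
#' the expected derivative of corr(X, Y) with respect to the level of Z: a
#' positive score means the pair becomes more correlated as Z increases
#' (Z is a positive scouting gene), a negative score the reverse.
#'
#' The score is symmetric in its three arguments (exactly, in exact
#' arithmetic; to the last ulp in floating point). Profiles are expected to
#' be normal-score transformed already; this is a documented contract and
#' is not re-checked here.
#'
#' @param x,y,z numeric vectors of equal length m >= 3.
#' @return the LA score, a single number.
#' @export
la_score <- function(x, y, z) {
  m <- length(x)
  if (length(y) != m || length(z) != m)
    stop("profiles must have equal length")
  if (m < 3L)
    stop("need at least 3 samples")
  sum((x * y) * z) / m
}

#' LA scores of one pair against every other gene as conditioner
#'
#' For a fixed pair (X, Y), computes \code{la_score(x, y, z)} with every
#' other gene of the matrix in the Z role. Implemented as a literal loop
#' over \code{\link{la_score}}, so results are bit-identical to calling it
#' gene by gene.
#'
#' @param mat transformed gene x sample matrix.
#' @param x_index,y_index distinct row indices or rownames of the pair.
#' @return named numeric vector of LA scores over all genes except the pair.
#' @export
la_scan_for_pair <- function(mat, x_index, y_index) {
  stopifnot(is.matrix(mat))
  xi <- resolve_gene(mat, x_index)
  yi <- resolve_gene(mat, y_index)
  if (xi == yi) stop("x and y must be distinct genes")
  zi <- setdiff(seq_len(nrow(mat)), c(xi, yi))
  x <- mat[xi, ]
  y <- mat[yi, ]
  out <- vapply(zi, function(j) la_score(x, y, mat[j, ]), numeric(1))
  names(out) <- rownames(mat)[zi] %||% as.character(zi)
  out
}

resolve_gene <- function(mat, idx) {
  if (is.character(idx)) {
    i <- match(idx, rownames(mat))
    if (is.na(i)) stop("gene '", idx, "' not found in matrix")
    return(i)
  }
  i <- as.integer(idx)
  if (is.na(i) || i < 1L || i > nrow(mat))
    stop("gene index ", idx, " out of range [1, ", nrow(mat), "]")
  i
}

#' Pair correlation within conditioner-expression groups
#'
#' Partitions the samples into \code{n_groups} equal-size (+/- 1) groups by
#' ascending conditioner expression z and returns the Pearson correlation
#' of (x, y) within each group, ordered low to high. With the default three
#' groups these are the Corr_low / Corr_mid / Corr_high statistics used to
#' display how a scouting gene modulates a pair's co-expression.
#'
#' A group with fewer than 3 samples gets \code{NA} with a warning rather
#' than an error.
#'
#' @param x,y,z numeric vectors of equal length, m >= 2 * n_groups.
#' @param n_groups number of expression groups, default 3 (terciles).
#' @return list with \code{correlations} (named numeric, low to high) and
#'   \code{groups} (integer group label per sample, 1 = lowest z).
#' @export
conditional_correlations <- function(x, y, z, n_groups = 3L) {
  m <- length(z)
  if (length(x) != m || length(y) != m)
    stop("profiles must have equal length")
  n_groups <- as.integer(n_groups)
  if (n_groups < 2L) stop("'n_groups' must be >= 2")
  if (m < 2L * n_groups)
    stop("need at least ", 2L * n_groups, " samples for ", n_groups, " groups")
  g <- partition_by_rank(z, n_groups)
  cors <- rep(NA_real_, n_groups)
  for (i in seq_len(n_groups)) {
    idx <- which(g == i)
    if (length(idx) < 3L) {
      warning("group ", i, " has fewer than 3 samples; correlation undefined")
      next
    }
    cors[i] <- stats::cor(x[idx], y[idx])
  }
  names(cors) <- if (n_groups == 3L) c("low", "mid", "high")
                 else paste0("group", seq_len(n_groups))
  list(correlations = cors, groups = g)
}

#' Modified liquid association (binned Stein's-lemma estimator)
#'
#' MLA(X1, X2 | X3) = E{h'(X3)} = E{h(X3) X3}, where h(z) is the conditional
#' correlation of (X1, X2) given X3 = z. The direct estimate bins the
#' samples into \code{n_bins} equal-size bins by ascending X3 and averages
#' the within-bin Pearson correlation weighted by the bin mean of X3:
#' \deqn{\widehat{MLA} = \frac{1}{M}\sum_{i=1}^{M} \hat\rho_i \bar X_{3i}.}
#' M = 3 bins is the convention used throughout genome-wide screening.
#'
#' @param x1,x2,x3 numeric vectors of equal length; x3 is the conditioner.
#' @param n_bins number of bins M, default 3; every bin must receive at
#'   least 3 samples.
#' @return the MLA estimate, a single number.
#' @export
mla <- function(x1, x2, x3, n_bins = 3L) {
  m <- length(x3)
  if (length(x1) != m || length(x2) != m)
    stop("profiles must have equal length")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  if (m < 3L * n_bins)
    stop("need at least ", 3L * n_bins, " samples so every bin has >= 3")
  g <- partition_by_rank(x3, n_bins)
  acc <- 0
  for (i in seq_len(n_bins)) {
    idx <- which(g == i)
    if (stats::sd(x1[idx]) == 0 || stats::sd(x2[idx]) == 0)
      stop("correlation undefined in bin ", i, ": constant profile subvector")
    acc <- acc + stats::cor(x1[idx], x2[idx]) * mean(x3[idx])
  }
  acc / n_bins
}

#' Designate the LA-scouting gene of a triplet by MLA
#'
#' Evaluates the MLA estimator with each member of the triplet in the
#' conditioner role (the other two as the pair) and designates as scouting
#' gene the member whose conditioner-role MLA is largest in absolute value;
#' both polarities are biologically meaningful (positive scouts increase
#' the pair correlation as they increase, negative scouts decrease it).
#' Ties are broken by input order (first wins) with a note.
#'
#' @param x,y,z the three transformed profiles.
#' @param ids identifiers for the three profiles, in input order.
#' @param n_bins bins for \code{\link{mla}}, default 3.
#' @return list with \code{scout_id} and \code{mla_values} (named by
#'   \code{ids}; entry k is the MLA with profile k as conditioner).
#' @export
assign_scouting_gene <- function(x, y, z, ids = c("x", "y", "z"), n_bins = 3L) {
  stopifnot(length(ids) == 3L, !anyDuplicated(ids))
  vals <- c(mla(y, z, x, n_bins), # x as conditioner
            mla(x, z, y, n_bins), # y as conditioner
            mla(x, y, z, n_bins)) # z as conditioner
  names(vals) <- ids
  av <- abs(vals)
  k <- which.max(av)              # first maximum wins on ties
  if (sum(av == av[k]) > 1L)
    message("assign_scouting_gene: |MLA| tie, keeping first ('", ids[k], "')")
  list(scout_id = ids[k], mla_values = vals)
}
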