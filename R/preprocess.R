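#' Filter genes by missing rate
#'
#' Retains exactly the genes whose fraction of missing entries is strictly
#' below \code{max_missing_fraction}, the convention used for genome-wide
#' screening (a gene with e.g. 20 percent missing at a 0.20 cutoff is
#' dropped). Gene order and samples are unchanged.
#'
#' @param mat numeric gene x sample matrix with \code{NA} for missing values;
#'   rownames are gene identifiers, colnames sample identifiers.
#' @param max_missing_fraction retention cutoff in [0, 1]; default 0.20.
#' @return the filtered matrix.
#' @export
filter_by_missing_rate <- function(mat, max_missing_fraction = 0.20) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 1L)
  if (!is.numeric(max_missing_fraction) || length(max_missing_fraction) != 1L ||
      max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("'max_missing_fraction' must be a single value in [0, 1]")
  frac <- rowMeans(is.na(mat))
  keep <- frac < max_missing_fraction
  if (!any(keep))
    stop("no genes retained: every gene has a missing rate >= ",
         format(max_missing_fraction))
  mat[keep, , drop = FALSE]
}

#' Impute missing expression values with the gene's mean
#'
#' Each missing entry is replaced by the mean of the gene's observed values;
#' observed entries are untouched.
#'
#' @param mat numeric gene x sample matrix with \code{NA} for missing values.
#' @return a matrix with no missing values.
#' @export
impute_missing <- function(mat) {
  stopifnot(is.matrix(mat))
  n_obs <- rowSums(!is.na(mat))
  if (any(n_obs == 0L)) {
    bad <- rownames(mat)[n_obs == 0L] %||% which(n_obs == 0L)
    stop("gene(s) with no observed values cannot be imputed: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!anyNA(mat)) return(mat)
  mu <- rowMeans(mat, na.rm = TRUE)
  idx <- which(is.na(mat), arr.ind = TRUE)
  mat[idx] <- mu[idx[, 1L]]
  mat
}

#' Normal score (quantile) transformation of a profile
#'
#' Rank-based inverse normal transform: value i maps to
#' \eqn{\Phi^{-1}((r_i - a) / (n + 1 - 2a))} where \eqn{r_i} is the
#' tie-averaged rank and \eqn{a} the plotting-position offset. With the
#' default offset this reproduces \code{qqnorm()}'s theoretical quantiles
#' (Blom's a = 3/8 for n <= 10, a = 1/2 otherwise) for untied input. The
#' transform depends on the data only through ranks, so any strictly
#' increasing rescaling of the input gives identical output; ties map to
#' equal scores.
#'
#' Standardizing every profile this way is the prerequisite for reading the
#' mean triple product as E(XYZ): with Z standard normal the triple-product
#' expectation measures how corr(X, Y) changes along Z.
#'
#' @param v numeric vector, length >= 2, no missing values.
#' @param offset plotting-position offset a; \code{NULL} (default) selects
#'   3/8 for n <= 10 and 1/2 otherwise.
#' @return numeric vector of normal scores, same length and order as \code{v}.
#' @export
normal_quantile_transform <- function(v, offset = NULL) {
  n <- length(v)
  if (n < 2L)
    stop("need at least 2 values to rank")
  if (anyNA(v))
    stop("profile contains missing values; impute first")
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("degenerate profile: all values identical, ranks carry no information")
  a <- if (is.null(offset)) (if (n <= 10L) 3 / 8 else 1 / 2) else offset
  r <- rank(v, ties.method = "average")
  stats::qnorm((r - a) / (n + 1 - 2 * a))
}

#' Normal-score transform every row of an expression matrix
#'
#' @param mat numeric gene x sample matrix, no missing values
#'   (run \code{\link{impute_missing}} first).
#' @param offset passed to \code{\link{normal_quantile_transform}}.
#' @return matrix of the same shape and dimnames.
#' @export
transform_matrix <- function(mat, offset = NULL) {
  stopifnot(is.matrix(mat))
  out <- mat
  for (i in seq_len(nrow(mat)))
    out[i, ] <- normal_quantile_transform(mat[i, ], offset = offset)
  out
}

#' Filter, impute and transform in one step
#'
#' The standard preprocessing chain for LA analysis: drop genes with too
#' many missing values, mean-impute the rest, normal-score transform each
#' gene profile. Never changes the number of samples.
#'
#' @inheritParams filter_by_missing_rate
#' @inheritParams normal_quantile_transform
#' @return transformed matrix ready for \code{\link{la_score}} and friends.
#' @export
preprocess_matrix <- function(mat, max_missing_fraction = 0.20, offset = NULL) {
  transform_matrix(impute_missing(
    filter_by_missing_rate(mat, max_missing_fraction)), offset = offset)
}

#' Align an expression matrix and a trait vector on shared samples
#'
#' Keeps the intersection of sample identifiers, in matrix column order,
#' and reports how many samples were dropped from each side.
#'
#' @param mat gene x sample matrix with sample identifiers as colnames.
#' @param trait named numeric vector (names are sample identifiers).
#' @return list with elements \code{matrix}, \code{trait}, and
#'   \code{n_shared}.
#' @export
align_samples <- function(mat, trait) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)), !is.null(names(trait)))
  shared <- intersect(colnames(mat), names(trait))
  n <- length(shared)
  if (n == 0L) stop("no shared sample identifiers between matrix and trait")
  dropped_mat <- ncol(mat) - n
  dropped_tr <- length(trait) - n
  if (dropped_mat > 0L || dropped_tr > 0L)
    message("align_samples: ", n, " shared samples (dropped ", dropped_mat,
            " matrix, ", dropped_tr, " trait samples)")
  list(matrix = mat[, shared, drop = FALSE], trait = trait[shared],
       n_shared = n)
}
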