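#' Partition samples into equal-size groups by ascending value
#'
#' Shared partition routine used both for conditional-correlation groups
#' (low/mid/high conditioner expression) and for the bins of the MLA
#' estimator, so the two views of a triplet are always consistent.
#'
#' Samples are ordered by ascending \code{z} (ties broken by stable input
#' order) and split into \code{n_groups} contiguous groups of equal size;
#' when the sample count is not divisible, the remainder samples go to the
#' lower groups first.
#'
#' @param z numeric vector ranking the samples (e.g. conditioner expression).
#' @param n_groups number of groups (>= 2).
#' @return integer vector of group labels in \code{1:n_groups}, 1 = lowest.
#' @export
partition_by_rank <- function(z, n_groups = 3L) {
  n_groups <- as.integer(n_groups)
  if (is.na(n_groups) || n_groups < 2L)
    stop("'n_groups' must be an integer >= 2")
  m <- length(z)
  if (m < n_groups)
    stop("cannot split ", m, " samples into ", n_groups, " groups")
  if (anyNA(z))
    stop("'z' contains missing values")
  ord <- order(z)                      # stable: ties keep input order
  base <- m %/% n_groups
  rem <- m %% n_groups
  sizes <- rep.int(base, n_groups)
  if (rem > 0L)
    sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  labels <- rep.int(seq_len(n_groups), sizes)
  out <- integer(m)
  out[ord] <- labels
  out
}

#' Derive a reproducible sub-seed from a master seed and a counter
#'
#' Counter-based stream derivation: each permutation (or replicate) b uses
#' \code{derive_seed(seed, b)}, so results do not depend on the order in
#' which permutations are executed. Plain multiplicative mixing modulo the
#' Mersenne prime 2^31 - 1; all intermediates stay exact in double
#' precision.
#'
#' @param seed master integer seed.
#' @param counter nonnegative integer counter (permutation index).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, counter) {
  p <- 2147483647
  s <- (abs(as.numeric(seed)) %% p) * 48271 %% p
  s <- (s %% p + ((as.numeric(counter) %% p) * 69621) %% p) %% p
  s <- (s * 16807 + 12345) %% p
  if (s == 0) s <- 1
  as.integer(s)
}

#' Check that profiles look normal-score transformed
#'
#' LA theory requires standardized (normal-score) profiles; the score
#' E(XYZ) is meaningless on raw expression. Rows of a transformed matrix
#' have empirical mean ~0 (exactly for untied rows; ties from imputation
#' shift it negligibly).
#'
#' @param mat numeric matrix, genes in rows.
#' @param tol tolerance on |row mean|.
#' @param override skip the check (for expert use on pre-standardized data).
#' @keywords internal
assert_transformed <- function(mat, tol = 1e-6, override = FALSE) {
  if (override) return(invisible(TRUE))
  mu <- rowMeans(mat)
  bad <- which(abs(mu) > tol)
  if (length(bad))
    stop("matrix does not look normal-score transformed (row mean exceeds ",
         format(tol), " for ", length(bad), " gene(s), e.g. '",
         rownames(mat)[bad[1]] %||% bad[1],
         "'); run transform_matrix() first or set override")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tiny stable content hash (FNV-1a over a deparsed object)
#' @keywords internal
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
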