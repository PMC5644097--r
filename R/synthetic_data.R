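#' Theoretical LA of the tanh-link planted triplet
#'
#' For the generator's planted model corr(X, Y | Z = z) = tanh(theta z)
#' with standard-normal Z, the population LA score is
#' E[tanh(theta Z) Z], evaluated by adaptive quadrature against the
#' standard-normal density. It has the sign of theta and magnitude at most
#' E|Z| = sqrt(2/pi).
#'
#' @param theta link strength.
#' @return the population LA value.
#' @export
theoretical_la <- function(theta) {
  if (theta == 0) return(0)
  stats::integrate(function(z) tanh(theta * z) * z * stats::dnorm(z),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

#' Expected value of the binned MLA estimator under the tanh link
#'
#' Population counterpart of \code{\link{mla}} for the planted model with
#' the conditioner in its true role: bins are equal-probability slices of
#' the standard normal, and each contributes
#' E[tanh(theta Z) | bin] * E[Z | bin] / M.
#'
#' @param theta link strength.
#' @param n_bins number of bins M (default 3).
#' @return the expected binned MLA.
#' @export
theoretical_mla_binned <- function(theta, n_bins = 3L) {
  probs <- seq(0, 1, length.out = n_bins + 1L)
  cuts <- stats::qnorm(probs)
  acc <- 0
  for (i in seq_len(n_bins)) {
    w <- 1 / n_bins
    eh <- stats::integrate(function(z) tanh(theta * z) * stats::dnorm(z),
                           cuts[i], cuts[i + 1L], rel.tol = 1e-10)$value / w
    ez <- stats::integrate(function(z) z * stats::dnorm(z),
                           cuts[i], cuts[i + 1L], rel.tol = 1e-10)$value / w
    acc <- acc + eh * ez
  }
  acc / n_bins
}

#' Describe planted triplets
#'
#' Builds the ground-truth table for \code{\link{generate_la_dataset}}:
#' \code{n} planted triplets occupying the first 3n gene slots (x, y, z
#' interleaved per triplet), all with link strength \code{theta}.
#'
#' @param n number of triplets.
#' @param theta link strength(s), recycled to length n.
#' @return data.frame with x_index, y_index, z_index, theta,
#'   theoretical_la, kind.
#' @export
planted_triplets <- function(n, theta) {
  theta <- rep_len(theta, n)
  base <- (seq_len(n) - 1L) * 3L
  data.frame(x_index = base + 1L, y_index = base + 2L, z_index = base + 3L,
             theta = theta,
             theoretical_la = vapply(theta, theoretical_la, numeric(1)),
             kind = rep("gene-gene", n), stringsAsFactors = FALSE)
}

#' Generate a synthetic expression matrix with planted LA triplets
#'
#' Background genes are i.i.d. standard normal across samples. Each planted
#' triplet (X, Y, Z) is drawn as: Z ~ N(0,1), W ~ N(0,1), E ~ N(0,1),
#' X = W, Y = tanh(theta Z) W + sqrt(1 - tanh^2(theta Z)) E, so that
#' corr(X, Y | Z = z) = tanh(theta z) exactly while all marginals are
#' standard normal. The tanh link is bounded in (-1, 1) (a valid
#' correlation for every z), odd (so the overall corr(X, Y) is ~0: the
#' pair is correlated only conditioning on Z), and monotone (matching the
#' positive/negative scouting-gene semantics). Missing entries are set
#' completely at random at \code{missing_rate}.
#'
#' @param n_genes total genes (>= 3 * number of planted triplets).
#' @param n_samples samples m; 368 matches the maize-panel regime the
#'   analysis was designed for.
#' @param planted data.frame from \code{\link{planted_triplets}} (or any
#'   data.frame with x_index, y_index, z_index, theta), or an integer
#'   count combined with \code{theta}.
#' @param theta link strength used when \code{planted} is a count.
#' @param missing_rate fraction of entries set missing, in [0, 0.5).
#' @param seed integer seed governing all draws.
#' @return list with \code{matrix} (gene x sample, NAs for missing,
#'   rownames \code{g0001}... and colnames \code{s0001}...) and
#'   \code{truth} (the planted table with identifiers added).
#' @export
generate_la_dataset <- function(n_genes, n_samples = 368L, planted = 0L,
                                theta = 0.5, missing_rate = 0, seed = 1L) {
  if (is.numeric(planted) && length(planted) == 1L)
    planted <- if (planted >= 1) planted_triplets(planted, theta)
               else planted_triplets(0L, theta)[0L, ]
  stopifnot(is.data.frame(planted))
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("'missing_rate' must be in [0, 0.5)")
  used <- c(planted$x_index, planted$y_index, planted$z_index)
  if (anyDuplicated(used))
    stop("planted triplets have overlapping gene indices")
  if (n_genes < 3L * nrow(planted))
    stop("'n_genes' must be >= 3 * number of planted triplets")
  if (length(used) && max(used) > n_genes)
    stop("planted gene index exceeds 'n_genes'")
  set.seed(derive_seed(seed, 0L))
  mat <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
  for (t in seq_len(nrow(planted))) {
    z <- stats::rnorm(n_samples)
    w <- stats::rnorm(n_samples)
    e <- stats::rnorm(n_samples)
    rho <- tanh(planted$theta[t] * z)
    mat[planted$x_index[t], ] <- w
    mat[planted$y_index[t], ] <- rho * w + sqrt(1 - rho^2) * e
    mat[planted$z_index[t], ] <- z
  }
  if (missing_rate > 0) {
    drop <- which(stats::runif(length(mat)) < missing_rate)
    mat[drop] <- NA_real_
  }
  rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
  colnames(mat) <- sprintf("s%04d", seq_len(n_samples))
  truth <- planted
  if (nrow(truth)) {
    truth$x_id <- rownames(mat)[truth$x_index]
    truth$y_id <- rownames(mat)[truth$y_index]
    truth$z_id <- rownames(mat)[truth$z_index]
    if (is.null(truth$theoretical_la))
      truth$theoretical_la <- vapply(truth$theta, theoretical_la, numeric(1))
  }
  list(matrix = mat, truth = truth)
}

#' Generate a synthetic trait dataset with planted mediator genes
#'
#' Emulates a gene-trait analysis in which a candidate gene's correlation
#' with a quantitative trait is modulated by mediator genes: for mediator
#' set \{Z_k\} of a target gene X, the trait is
#' T = s X + sqrt(1 - s^2) E with s = mean_k tanh(theta_k Z_k), so
#' corr(X, T | Z = z) follows the tanh link (exactly so with a single
#' mediator). The odd link forces the overall corr(X, T) toward 0, the
#' situation where marginal correlation misses a real, conditional
#' gene-trait relationship. The trait has no missing values.
#'
#' @param n_genes total genes; mediators and the target occupy the lowest
#'   indices.
#' @param n_samples samples; 349 matches the phenotype-aligned panel
#'   regime.
#' @param mediator_specs data.frame with columns gene_index (the target X),
#'   mediator_index (Z), theta; several rows may share one gene_index.
#'   Default: one target (gene 1) with one mediator (gene 2), theta 0.6.
#' @param missing_rate missing fraction for the expression matrix only.
#' @param seed integer seed.
#' @return list with \code{matrix}, \code{trait} (named numeric), and
#'   \code{truth} (mediator table with identifiers and theoretical LA).
#' @export
generate_trait_dataset <- function(n_genes, n_samples = 349L,
                                   mediator_specs = NULL,
                                   missing_rate = 0, seed = 1L) {
  if (is.null(mediator_specs))
    mediator_specs <- data.frame(gene_index = 1L, mediator_index = 2L,
                                 theta = 0.6)
  stopifnot(is.data.frame(mediator_specs),
            all(c("gene_index", "mediator_index", "theta") %in%
                  names(mediator_specs)))
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("'missing_rate' must be in [0, 0.5)")
  idx <- c(mediator_specs$gene_index, mediator_specs$mediator_index)
  if (anyDuplicated(mediator_specs$mediator_index) ||
      any(mediator_specs$mediator_index %in% mediator_specs$gene_index))
    stop("mediator indices overlap each other or a target gene")
  if (max(idx) > n_genes) stop("spec index exceeds 'n_genes'")
  targets <- unique(mediator_specs$gene_index)
  if (length(targets) > 1L)
    stop("one target gene per dataset is supported (the trait is a single vector)")
  set.seed(derive_seed(seed, 0L))
  mat <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
  x <- mat[targets, ]
  s <- rowMeans(vapply(seq_len(nrow(mediator_specs)), function(k) {
    tanh(mediator_specs$theta[k] * mat[mediator_specs$mediator_index[k], ])
  }, numeric(n_samples)))
  e <- stats::rnorm(n_samples)
  trait <- s * x + sqrt(1 - s^2) * e
  if (missing_rate > 0) {
    drop <- which(stats::runif(length(mat)) < missing_rate)
    mat[drop] <- NA_real_
  }
  rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
  colnames(mat) <- sprintf("s%04d", seq_len(n_samples))
  names(trait) <- colnames(mat)
  truth <- mediator_specs
  truth$gene_id <- rownames(mat)[truth$gene_index]
  truth$mediator_id <- rownames(mat)[truth$mediator_index]
  truth$theoretical_la <- vapply(truth$theta, theoretical_la, numeric(1)) /
    nrow(truth)
  truth$kind <- "gene-trait"
  list(matrix = mat, trait = trait, truth = truth)
}
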