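#' Gene-trait liquid association screen
#'
#' Treats each candidate gene's expression as X and a quantitative trait as
#' Y, and scores LA against every other gene of the matrix as conditioner
#' Z. Significance uses local permutation of the sample pairing with Z
#' (the genome-wide reference is too strict for within-pathway questions).
#' Retained triplets are labelled co-regulated (LA > 0: the gene-trait
#' correlation rises with the scout) or contra-regulated (LA < 0).
#'
#' Samples are aligned on the intersection of matrix and trait sample
#' identifiers; profiles and the trait are then normal-score transformed on
#' the aligned samples (the transform depends on the sample set, so it must
#' happen after alignment).
#'
#' P values are computed in two stages: every triplet gets
#' \code{stage1_perm} permutations, and only triplets that look extreme
#' there (at most one permuted score as extreme as the observed one) are
#' re-run at the full \code{n_perm}, each from its own derived seed. The
#' reported P value always states the permutation count actually used via
#' its granularity; the full count is what makes a cutoff of 1e-4
#' attainable.
#'
#' @param mat gene x sample matrix (raw or transformed; rows are
#'   re-transformed after sample alignment).
#' @param candidate_ids rownames of the candidate X genes.
#' @param trait named numeric vector (names are sample identifiers).
#' @param p_cutoff retention cutoff on the local permutation P value;
#'   default 1e-4. \code{NULL} retains every triplet (no P values needed
#'   beyond stage 1 screening is skipped too when \code{n_perm = 0}).
#' @param n_perm full permutation count for extreme triplets (default 1e4;
#'   0 skips P values entirely and retains all triplets with \code{NA} P).
#' @param seed master seed.
#' @param trait_name label for the Y role in the output.
#' @param stage1_perm permutations of the screening stage.
#' @return data.frame with one row per retained (candidate, conditioner)
#'   triplet: gene_id, trait_name, z_id, la, p_value, corr_gene_trait,
#'   corr_low, corr_high, regulation; sorted by gene then descending |LA|.
#'   Attribute \code{n_shared_samples} records the alignment size.
#' @export
gene_trait_la <- function(mat, candidate_ids, trait, p_cutoff = 1e-4,
                          n_perm = 1e4, seed = 1L, trait_name = "trait",
                          stage1_perm = 500L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  missing_c <- setdiff(candidate_ids, rownames(mat))
  if (length(missing_c))
    stop("candidate gene(s) absent from matrix: ",
         paste(missing_c, collapse = ", "))
  al <- align_samples(mat, trait)
  if (al$n_shared < 30L)
    stop("only ", al$n_shared,
         " shared samples; need >= 30 for stable correlation estimates")
  mat <- transform_matrix(al$matrix)
  yv <- normal_quantile_transform(al$trait)
  m <- ncol(mat)
  ids <- rownames(mat)
  n_perm <- as.integer(n_perm)
  rows <- vector("list", length(candidate_ids))
  for (ci in seq_along(candidate_ids)) {
    cid <- candidate_ids[ci]
    x <- mat[cid, ]
    r_gt <- stats::cor(x, yv)
    z_idx <- which(ids != cid)
    # literal la_score loop keeps gene-trait scores bit-identical to the
    # gene-gene path with the trait in the Y role
    la_all <- vapply(z_idx, function(j) la_score(x, yv, mat[j, ]), numeric(1))
    pvals <- rep(NA_real_, length(z_idx))
    if (n_perm > 0L) {
      for (k in seq_along(z_idx)) {
        sub <- derive_seed(seed, (ci - 1L) * nrow(mat) + z_idx[k])
        p1 <- local_permutation_p(x, yv, mat[z_idx[k], ],
                                  n_perm = stage1_perm, seed = sub,
                                  early_stop = 2L)
        if (p1 <= 2 / (stage1_perm + 1) && n_perm > stage1_perm) {
          pvals[k] <- local_permutation_p(x, yv, mat[z_idx[k], ],
                                          n_perm = n_perm,
                                          seed = derive_seed(sub, 1L))
        } else pvals[k] <- p1
      }
    }
    keep <- if (is.null(p_cutoff) || n_perm == 0L) seq_along(z_idx)
            else which(pvals <= p_cutoff)
    if (!length(keep)) { rows[[ci]] <- NULL; next }
    cl <- ch <- numeric(length(keep))
    for (j in seq_along(keep)) {
      cc <- conditional_correlations(x, yv, mat[z_idx[keep[j]], ],
                                     3L)$correlations
      cl[j] <- cc[["low"]]; ch[j] <- cc[["high"]]
    }
    la_k <- la_all[keep]
    rows[[ci]] <- data.frame(
      gene_id = cid, trait_name = trait_name, z_id = ids[z_idx[keep]],
      la = la_k, p_value = pvals[keep], corr_gene_trait = r_gt,
      corr_low = cl, corr_high = ch,
      regulation = ifelse(la_k > 0, "co-regulated", "contra-regulated"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), trait_name = character(0),
                      z_id = character(0), la = numeric(0),
                      p_value = numeric(0), corr_gene_trait = numeric(0),
                      corr_low = numeric(0), corr_high = numeric(0),
                      regulation = character(0), stringsAsFactors = FALSE)
  ord <- order(match(out$gene_id, candidate_ids), -abs(out$la), out$z_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_shared_samples") <- al$n_shared
  out
}

#' Summarize co-/contra-regulation across candidate genes
#'
#' @param results data.frame from \code{\link{gene_trait_la}} (needs
#'   gene_id, z_id, regulation).
#' @return list with \code{n_co_genes}, \code{n_contra_genes},
#'   \code{n_both} (candidate genes with hits of both polarities), and
#'   \code{unique_scouts} (distinct conditioner genes across all hits).
#' @export
summarize_regulation <- function(results) {
  stopifnot(all(c("gene_id", "z_id", "regulation") %in% names(results)))
  co <- unique(results$gene_id[results$regulation == "co-regulated"])
  contra <- unique(results$gene_id[results$regulation == "contra-regulated"])
  list(n_co_genes = length(co),
       n_contra_genes = length(contra),
       n_both = length(intersect(co, contra)),
       unique_scouts = length(unique(results$z_id)))
}
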