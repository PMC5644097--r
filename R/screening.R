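#' Configuration for a genome-wide LA scan
#'
#' Bundles the screening thresholds. Defaults mirror the full-scale
#' analysis: tail quantile 1e-5, top 1000 LA pairs, conditional-LAP filter
#' |r| < 0.17 with |LA| > 0.60, and a leader cutoff of 5e5 linkages. The
#' leader cutoff is only meaningful at full genome scale (~25k genes); for
#' synthetic runs with g genes a scaled value of
#' \code{ceiling(5e5 * (g / 24907)^3)} is a sensible choice, since the
#' triplet count grows with the cube of g.
#'
#' @param tail_quantile reference-distribution tail for significance.
#' @param top_k_laps how many top-|LA| pairs to consider for the
#'   conditional filter.
#' @param conditional_r_max pair-correlation bound of the conditional
#'   filter (applied to |r_xy|).
#' @param conditional_la_min LA bound of the conditional filter (applied
#'   to |LA|).
#' @param leader_min_linkages minimum linkages for a scouting leader
#'   (inclusive).
#' @param n_permutations,seed permutation settings for the reference
#'   distribution.
#' @return a list of class \code{scan_config}.
#' @export
scan_config <- function(tail_quantile = 1e-5, top_k_laps = 1000L,
                        conditional_r_max = 0.17, conditional_la_min = 0.60,
                        leader_min_linkages = 5e5, n_permutations = 1e4,
                        seed = 1L) {
  if (tail_quantile <= 0 || tail_quantile >= 1)
    stop("'tail_quantile' must be in (0, 1)")
  if (top_k_laps < 1) stop("'top_k_laps' must be >= 1")
  if (conditional_r_max <= 0 || conditional_r_max >= 1)
    stop("'conditional_r_max' must be in (0, 1)")
  if (conditional_la_min <= 0) stop("'conditional_la_min' must be > 0")
  if (leader_min_linkages < 1) stop("'leader_min_linkages' must be >= 1")
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  structure(list(tail_quantile = tail_quantile,
                 top_k_laps = as.integer(top_k_laps),
                 conditional_r_max = conditional_r_max,
                 conditional_la_min = conditional_la_min,
                 leader_min_linkages = leader_min_linkages,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Genome-wide LA scan
#'
#' Enumerates every unordered gene pair \{X, Y\} with every third gene Z as
#' conditioner (C(g, 2) * (g - 2) combinations), scores LA, and keeps the
#' triplets whose score reaches the positive or negative tail threshold of
#' the reference distribution. For each retained triplet it reports the
#' pairwise correlations, the conditional correlations of the pair within
#' low/mid/high conditioner terciles, the MLA values with each member as
#' conditioner, the designated scouting gene, and the permutation P value.
#'
#' Scores are computed in blocked matrix products; retained triplets are
#' re-annotated one at a time. Results are sorted by descending |LA| (ties
#' by identifiers), so runs with identical input and configuration are
#' byte-identical when written.
#'
#' @param mat transformed gene x sample matrix (checked; see
#'   \code{override_transform_check}).
#' @param ref an \code{la_reference} for the same sample count, from
#'   \code{\link{build_reference_distribution}}.
#' @param config a \code{\link{scan_config}}.
#' @param override_transform_check skip the standardization check.
#' @param block_size number of pairs scored per matrix product.
#' @return data.frame with one row per significant (pair, conditioner)
#'   record: columns x_id, y_id, z_id, la, r_xy, r_xz, r_yz, corr_low,
#'   corr_mid, corr_high, mla, scout_id, p_value. Attributes
#'   \code{n_pairs}, \code{n_evaluated}, \code{n_significant}, and
#'   \code{thresholds} carry the scan bookkeeping.
#' @export
scan_all <- function(mat, ref, config = scan_config(),
                     override_transform_check = FALSE, block_size = 2000L) {
  stopifnot(is.matrix(mat), inherits(ref, "la_reference"),
            inherits(config, "scan_config"))
  g <- nrow(mat)
  if (g < 3L) stop("need at least 3 genes")
  assert_transformed(mat, override = override_transform_check)
  ids <- rownames(mat) %||% as.character(seq_len(g))
  m <- ncol(mat)
  thr <- la_threshold(ref, config$tail_quantile)
  pairs <- utils::combn(g, 2L)
  n_pairs <- ncol(pairs)
  n_eval <- n_pairs * (g - 2L)
  message("scan_all: ", g, " genes, ", n_pairs, " pairs, ",
          n_eval, " triplet evaluations; thresholds [",
          format(thr["neg"], digits = 4), ", ",
          format(thr["pos"], digits = 4), "]")
  tmat <- t(mat)
  hit_x <- integer(0); hit_y <- integer(0); hit_z <- integer(0)
  hit_la <- numeric(0)
  for (start in seq(1L, n_pairs, by = block_size)) {
    idx <- start:min(n_pairs, start + block_size - 1L)
    ii <- pairs[1L, idx]; jj <- pairs[2L, idx]
    xy <- tmat[, ii, drop = FALSE] * tmat[, jj, drop = FALSE]  # m x nb
    s <- (mat %*% xy) / m                                      # g x nb
    # the pair's own rows are not valid conditioners
    nb <- length(idx)
    s[cbind(ii, seq_len(nb))] <- NA_real_
    s[cbind(jj, seq_len(nb))] <- NA_real_
    keep <- which(!is.na(s) & (s >= thr[["pos"]] | s <= thr[["neg"]]),
                  arr.ind = TRUE)
    if (nrow(keep)) {
      hit_x <- c(hit_x, ii[keep[, 2L]])
      hit_y <- c(hit_y, jj[keep[, 2L]])
      hit_z <- c(hit_z, keep[, 1L])
      hit_la <- c(hit_la, s[keep])
    }
  }
  n_sig <- length(hit_la)
  res <- annotate_triplets(mat, ids, hit_x, hit_y, hit_z, hit_la, ref)
  message("scan_all: ", n_sig, " significant triplet records")
  attr(res, "n_pairs") <- n_pairs
  attr(res, "n_evaluated") <- n_eval
  attr(res, "n_significant") <- n_sig
  attr(res, "thresholds") <- thr
  res
}

annotate_triplets <- function(mat, ids, xi, yi, zi, la, ref) {
  n <- length(la)
  r_xy <- r_xz <- r_yz <- numeric(n)
  c_low <- c_mid <- c_high <- mla_v <- numeric(n)
  scout <- character(n)
  for (k in seq_len(n)) {
    x <- mat[xi[k], ]; y <- mat[yi[k], ]; z <- mat[zi[k], ]
    r_xy[k] <- stats::cor(x, y)
    r_xz[k] <- stats::cor(x, z)
    r_yz[k] <- stats::cor(y, z)
    cc <- conditional_correlations(x, y, z, 3L)$correlations
    c_low[k] <- cc[["low"]]; c_mid[k] <- cc[["mid"]]; c_high[k] <- cc[["high"]]
    sc <- assign_scouting_gene(x, y, z, ids = ids[c(xi[k], yi[k], zi[k])])
    scout[k] <- sc$scout_id
    mla_v[k] <- sc$mla_values[[ids[zi[k]]]]
  }
  p <- if (n) permutation_p_value(la, ref) else numeric(0)
  res <- data.frame(x_id = ids[xi], y_id = ids[yi], z_id = ids[zi],
                    la = la, r_xy = r_xy, r_xz = r_xz, r_yz = r_yz,
                    corr_low = c_low, corr_mid = c_mid, corr_high = c_high,
                    mla = mla_v, scout_id = scout, p_value = p,
                    stringsAsFactors = FALSE)
  ord <- order(-abs(res$la), res$x_id, res$y_id, res$z_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Conditional-correlation filter for LA pairs
#'
#' Among scored triplets, keeps those whose pair is essentially
#' uncorrelated overall yet strongly liquid-associated: |r_xy| < r_max and
#' |LA| > la_min. These "conditional LAPs" are pairs whose correlation
#' exists only conditioning on the scouting gene. Both conditions are
#' applied to magnitudes so negative-LA triplets are treated symmetrically;
#' the signs remain in the output.
#'
#' @param results data.frame from \code{\link{scan_all}}.
#' @param r_max pair-correlation bound, default 0.17.
#' @param la_min LA bound, default 0.60.
#' @return the retained subset, order preserved.
#' @export
classify_conditional_laps <- function(results, r_max = 0.17, la_min = 0.60) {
  stopifnot(all(c("r_xy", "la") %in% names(results)))
  results[abs(results$r_xy) < r_max & abs(results$la) > la_min, , drop = FALSE]
}

#' Count significant linkages per scouting gene
#'
#' Tallies significant triplet records per designated scouting gene, split
#' by LA sign (the positive/negative scouting frequency). Zero scores
#' count on the positive side; totals conserve the number of input records.
#'
#' @param results data.frame with \code{scout_id} and \code{la}.
#' @return data.frame with scout_id, n_positive, n_negative, sorted by
#'   total count descending (ties by scout_id).
#' @export
count_linkages_per_scout <- function(results) {
  stopifnot(all(c("scout_id", "la") %in% names(results)))
  if (nrow(results) == 0L)
    return(data.frame(scout_id = character(0), n_positive = integer(0),
                      n_negative = integer(0), stringsAsFactors = FALSE))
  scouts <- sort(unique(results$scout_id))
  pos <- results$la >= 0
  np <- vapply(scouts, function(s) sum(results$scout_id == s & pos), integer(1))
  nn <- vapply(scouts, function(s) sum(results$scout_id == s & !pos), integer(1))
  out <- data.frame(scout_id = scouts, n_positive = np, n_negative = nn,
                    stringsAsFactors = FALSE)
  out <- out[order(-(out$n_positive + out$n_negative), out$scout_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select LA-scouting leaders
#'
#' Leaders are scouting genes with at least \code{min_linkages} significant
#' linkages of the requested sign ("at least" is inclusive: a count exactly
#' at the cutoff qualifies).
#'
#' @param counts data.frame from \code{\link{count_linkages_per_scout}}.
#' @param min_linkages inclusive cutoff (>= 1).
#' @param sign \code{"positive"} or \code{"negative"}.
#' @return data.frame of leaders sorted by the requested count descending.
#' @export
select_leaders <- function(counts, min_linkages, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (min_linkages < 1) stop("'min_linkages' must be >= 1")
  col <- if (sign == "positive") "n_positive" else "n_negative"
  keep <- counts[counts[[col]] >= min_linkages, , drop = FALSE]
  keep <- keep[order(-keep[[col]], keep$scout_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Export a gene / scouting-gene network edge list
#'
#' Restricts results to the given focus genes in the X role and emits one
#' edge per (x_id, z_id) pair, deduplicated keeping the record with the
#' largest |LA| (edge weight). Node and edge counts are attached as
#' attributes.
#'
#' @param results data.frame with x_id, z_id, la, p_value.
#' @param focus_genes character vector of X-role genes to keep.
#' @return data.frame with columns x_id, z_id, la, p_value; attributes
#'   \code{n_nodes}, \code{n_edges}.
#' @export
export_network <- function(results, focus_genes) {
  stopifnot(all(c("x_id", "z_id", "la") %in% names(results)))
  sub <- results[results$x_id %in% focus_genes, , drop = FALSE]
  if (nrow(sub) == 0L) {
    out <- data.frame(x_id = character(0), z_id = character(0),
                      la = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_nodes") <- 0L
    attr(out, "n_edges") <- 0L
    return(out)
  }
  if (!"p_value" %in% names(sub)) sub$p_value <- NA_real_
  sub <- sub[order(-abs(sub$la), sub$x_id, sub$z_id), , drop = FALSE]
  sub <- sub[!duplicated(sub[c("x_id", "z_id")]), , drop = FALSE]
  out <- sub[c("x_id", "z_id", "la", "p_value")]
  rownames(out) <- NULL
  attr(out, "n_nodes") <- length(unique(c(out$x_id, out$z_id)))
  attr(out, "n_edges") <- nrow(out)
  out
}
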