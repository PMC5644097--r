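#' Read a tab-delimited expression matrix
#'
#' Dialect: header row of sample identifiers, first column gene
#' identifiers, tab separated; the tokens \code{NA}, \code{NaN} and the
#' empty field are read as missing. Ragged rows and duplicated gene or
#' sample identifiers are rejected with the offending line named.
#'
#' @param path file path.
#' @return numeric gene x sample matrix with dimnames; \code{NA} marks
#'   missing entries.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            blank.lines.skip = FALSE, comment.char = "")
  if (length(nf) < 2L) stop("matrix file needs a header and at least one gene row")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = c("NA", "NaN", ""), comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character", rep("numeric", nf[1L] - 1L)))
  gene_ids <- df[[1L]]
  dup <- which(duplicated(gene_ids))
  if (length(dup))
    stop("duplicated gene identifier '", gene_ids[dup[1L]],
         "' at line ", dup[1L] + 1L)
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample identifier '",
         sample_ids[which(duplicated(sample_ids))[1L]], "' in header")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- gene_ids
  colnames(mat) <- sample_ids
  mat
}

#' Write an expression matrix in the package's TSV dialect
#'
#' Values are written with 12 significant digits so a write/read round trip
#' is lossless at that precision; missing entries are written as \code{NA}.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_column header label of the gene-identifier column.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r) paste(num_token(r), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

num_token <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 12))

#' Read / write a trait vector (two-column TSV with header)
#'
#' @param path file path.
#' @return named numeric vector (names are sample identifiers).
#' @export
read_trait <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = c("NA", "NaN", ""), comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("trait file must have exactly two columns")
  if (anyDuplicated(df[[1L]]))
    stop("duplicated sample identifier in trait file: ",
         df[[1L]][which(duplicated(df[[1L]]))[1L]])
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_trait
#' @param trait named numeric vector.
#' @param trait_name header label of the value column.
#' @export
write_trait <- function(trait, path, trait_name = "value") {
  stopifnot(!is.null(names(trait)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("sample_id", trait_name, sep = "\t"), con)
  writeLines(paste(names(trait), num_token(unname(trait)), sep = "\t"), con)
  invisible(path)
}

#' Write / read a permutation reference distribution (two-column TSV)
#'
#' @param ref an \code{la_reference}.
#' @param path file path.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "la_reference"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_permutations=%d seed=%d sampler=%s",
                     ref$n_permutations, ref$seed, ref$sampler), con)
  writeLines("pos_extreme\tneg_extreme", con)
  writeLines(paste(num_token(ref$pos_extremes),
                   num_token(ref$neg_extremes), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(seed = NA_integer_, sampler = "unknown")
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("seed=(-?[0-9]+)", first))[[1L]]
    if (length(m) == 2L) meta$seed <- as.integer(m[2L])
    m <- regmatches(first, regexec("sampler=(\\S+)", first))[[1L]]
    if (length(m) == 2L) meta$sampler <- m[2L]
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(list(pos_extremes = sort(df$pos_extreme),
                 neg_extremes = sort(df$neg_extreme),
                 n_permutations = nrow(df), seed = meta$seed,
                 sampler = meta$sampler),
            class = "la_reference")
}

#' Write a triplet result table as TSV
#'
#' Columns follow the screening layout (x_id, y_id, z_id, la, pairwise and
#' conditional correlations, mla, scout_id, p_value); numeric columns get
#' 12 significant digits so identical runs produce byte-identical files.
#'
#' @param results data.frame of triplet records.
#' @param path output path.
#' @export
write_triplet_results <- function(results, path) {
  df <- results
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- num_token(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplet_results
#' @export
read_triplet_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
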