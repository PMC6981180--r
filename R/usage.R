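# Gene-segment usage profiles, z-score heatmap clustering, pairwise
# regressions.

#' Gene-segment usage profile of a repertoire
#'
#' Duplicate-weighted frequency of each (allele-stripped) gene among
#' productive records. Genes present in the repertoire's germline set but
#' unobserved get frequency 0, so profiles from repertoires sharing a
#' germline set are directly comparable.
#'
#' @param rep a `repertoire`.
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param weighted weight records by `duplicate_count` (default); `FALSE`
#'   counts each unique record once.
#' @param productive_only restrict to productive records (default).
#' @return tibble with `gene` and `frequency` (sums to 1); attributes
#'   `segment` and `label`.
#' @export
gene_usage <- function(rep, segment = c("V", "D", "J"), weighted = TRUE,
                       productive_only = TRUE) {
  segment <- match.arg(segment)
  recs <- productive_records(rep, productive_only)
  if (nrow(recs) == 0) stop("no records to profile")
  col <- c(V = "v_gene", D = "d_gene", J = "j_gene")[[segment]]
  genes <- recs[[col]]
  if (all(is.na(genes))) stop("no ", segment, " calls in this repertoire")
  w <- if (weighted) recs$duplicate_count else rep(1, nrow(recs))
  keep <- !is.na(genes)
  tot <- tapply(w[keep], genes[keep], sum)
  universe <- if (!is.null(rep$germline)) {
    rep$germline$gene[rep$germline$segment == segment]
  } else {
    sort(unique(genes[keep]))
  }
  freq <- stats::setNames(rep(0, length(universe)), universe)
  shared <- intersect(names(tot), universe)
  freq[shared] <- tot[shared]
  freq <- freq / sum(freq)
  out <- tibble::tibble(gene = names(freq), frequency = as.numeric(freq))
  attr(out, "segment") <- segment
  attr(out, "label") <- paste(rep$subject_id, rep$tissue, sep = ".")
  out
}

#' Assemble usage profiles into a gene-by-repertoire matrix
#'
#' Profiles are aligned on the intersection of their gene supports and
#' renormalized, so repertoires annotated against different germline sets
#' remain comparable.
#'
#' @param profiles named list of [gene_usage()] tibbles; names become
#'   column labels (falling back to each profile's `label` attribute).
#' @return numeric matrix, rows = genes, columns = repertoires; every
#'   column sums to 1.
#' @export
usage_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  labels <- names(profiles) %||% vapply(profiles, function(p) attr(p, "label"), character(1))
  if (is.null(names(profiles))) names(profiles) <- labels
  shared <- Reduce(intersect, lapply(profiles, function(p) p$gene))
  if (length(shared) == 0) stop("profiles share no genes")
  cols <- lapply(profiles, function(p) {
    f <- p$frequency[match(shared, p$gene)]
    f / sum(f)
  })
  mat <- do.call(cbind, cols)
  rownames(mat) <- shared
  mat
}

#' Row z-score a usage matrix and cluster rows and columns
#'
#' Each gene row is centred and scaled by its population standard deviation
#' (rows with zero spread map to all-zeros), then rows and columns are
#' clustered agglomeratively with Euclidean distance and average (UPGMA)
#' linkage. Columns are ordered lexicographically before clustering so
#' dendrogram tie-breaks are reproducible.
#'
#' @param mat gene-by-repertoire frequency matrix (>= 2 columns).
#' @return list with `z` (z-scored matrix), `row_hclust`, `col_hclust`
#'   (class `hclust`), and `col_newick` (Newick string for the column
#'   dendrogram, `NULL` if \pkg{ape} is unavailable).
#' @export
zscore_and_cluster <- function(mat) {
  if (ncol(mat) < 2) stop("need at least 2 repertoires to cluster")
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  mu <- rowMeans(mat)
  sdev <- sqrt(rowMeans((mat - mu)^2))  # population denominator
  z <- (mat - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  col_hc <- stats::hclust(stats::dist(t(z), method = "euclidean"), method = "average")
  row_hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  newick <- NULL
  if (requireNamespace("ape", quietly = TRUE)) {
    newick <- ape::write.tree(ape::as.phylo(col_hc))
  }
  list(z = z, row_hclust = row_hc, col_hclust = col_hc, col_newick = newick)
}

# labels of the two top-level branches of an hclust tree
top_level_split <- function(hc) {
  grp <- stats::cutree(hc, k = 2)
  split(names(grp), grp)
}

#' Pairwise usage regression between two repertoires
#'
#' Ordinary least squares of repertoire `b`'s gene frequencies on `a`'s,
#' over the intersection of their gene supports (both renormalized).
#'
#' @param a,b [gene_usage()] profiles of the same segment.
#' @return list with `slope`, `intercept`, `r_squared`, `n_genes`.
#' @export
usage_regression <- function(a, b) {
  if (!identical(attr(a, "segment"), attr(b, "segment"))) {
    stop("profiles are for different segments")
  }
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  x <- a$frequency[match(shared, a$gene)]
  y <- b$frequency[match(shared, b$gene)]
  x <- x / sum(x); y <- y / sum(y)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_genes = length(shared))
}
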