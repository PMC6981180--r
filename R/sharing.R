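# Public-clonotype sharing: pairwise and multiway Venn decompositions,
# pool overlap, shared-vs-unshared characterization, CDR3 sequence logos.
# All sharing operations use set semantics on clonotype keys: each unique
# clonotype counts once, matching the "unique clonotypes" framing.

AA_CATEGORIES <- list(
  polar = strsplit("GSTYCQN", "")[[1]],
  basic = strsplit("KRH", "")[[1]],
  acidic = strsplit("DE", "")[[1]],
  hydrophobic = strsplit("AVLIPWFM", "")[[1]]
)
AA_ALPHABET <- unlist(AA_CATEGORIES, use.names = FALSE)

share_keys <- function(x) {
  k <- if (is.character(x)) x else x$key
  unique(k[!is.na(k)])
}

#' Pairwise clonotype sharing between two sets
#'
#' Reports the intersection size and the shared fraction under three
#' normalizations, which are always computed side by side because the
#' appropriate denominator is study-dependent: `union` (Jaccard,
#' |a n b| / |a u b|, the default), `mean` (|a n b| / mean set size), and
#' `per_set` (|a n b| / |a| and / |b|).
#'
#' @param a,b clonotype tibbles (from [assign_clonotypes()]) or character
#'   key vectors.
#' @param mode default normalization reported as `fraction`.
#' @return object of class `sharing_result`.
#' @export
pairwise_sharing <- function(a, b, mode = c("union", "mean", "per_set")) {
  mode <- match.arg(mode)
  ka <- share_keys(a); kb <- share_keys(b)
  if (length(ka) == 0 || length(kb) == 0) stop("empty clonotype set")
  i <- length(intersect(ka, kb))
  u <- length(union(ka, kb))
  fractions <- list(
    union = i / u,
    mean = i / ((length(ka) + length(kb)) / 2),
    per_set = c(a = i / length(ka), b = i / length(kb))
  )
  structure(
    list(set_sizes = c(a = length(ka), b = length(kb)),
         intersection = i, union = u,
         fractions = fractions, mode = mode,
         fraction = if (mode == "per_set") fractions$per_set else fractions[[mode]]),
    class = "sharing_result"
  )
}

#' @export
print.sharing_result <- function(x, ...) {
  cat(sprintf("<sharing_result> |intersection| = %d, union fraction %.4f (mode %s)\n",
              x$intersection, x$fractions$union, x$mode))
  invisible(x)
}

#' Multiway sharing with exact Venn regions
#'
#' Decomposes two or more clonotype sets into all exclusive Venn regions
#' (every membership pattern) by direct membership tabulation; region sizes
#' sum to the union size. The all-way shared fraction uses the union
#' denominator.
#'
#' @param sets named list (>= 2) of clonotype tibbles or key vectors.
#' @return object of class `sharing_result` with a `regions` tibble
#'   (`pattern`, `size`) and `all_shared_fraction`.
#' @export
multiway_sharing <- function(sets) {
  stopifnot(length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  keys <- lapply(sets, share_keys)
  all_keys <- unique(unlist(keys))
  membership <- vapply(keys, function(k) all_keys %in% k, logical(length(all_keys)))
  if (length(all_keys) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  regions <- tibble::as_tibble(table(pattern = pattern), .name_repair = "minimal")
  names(regions) <- c("pattern", "size")
  regions$size <- as.integer(regions$size)
  n_all <- sum(rowSums(membership) == length(sets))
  structure(
    list(set_sizes = vapply(keys, length, integer(1)),
         union = length(all_keys),
         regions = regions,
         intersection = n_all,
         all_shared_fraction = n_all / length(all_keys),
         fractions = list(union = n_all / length(all_keys)),
         mode = "union"),
    class = "sharing_result"
  )
}

#' Overlap of per-subject clonotype sets with a reference pool
#'
#' For each query set, the fraction of its clonotypes found in the pool;
#' plus the combined fraction for the union of all query sets.
#'
#' @param query_sets named list of clonotype tibbles or key vectors.
#' @param pool clonotype tibble or key vector (e.g. the pooled clonotypes
#'   of the other species).
#' @return tibble with `subject` and `fraction_in_pool`; the final row
#'   (`combined`) is the union-level fraction.
#' @export
pool_overlap <- function(query_sets, pool) {
  pool_keys <- share_keys(pool)
  if (length(pool_keys) == 0) stop("empty pool")
  if (is.null(names(query_sets))) names(query_sets) <- paste0("S", seq_along(query_sets))
  keys <- lapply(query_sets, share_keys)
  if (any(vapply(keys, length, integer(1)) == 0)) stop("empty query set")
  per <- vapply(keys, function(k) mean(k %in% pool_keys), numeric(1))
  comb_keys <- unique(unlist(keys))
  tibble::tibble(
    subject = c(names(query_sets), "combined"),
    fraction_in_pool = unname(c(per, mean(comb_keys %in% pool_keys)))
  )
}

#' Characterize shared versus unshared clonotypes
#'
#' Partitions a clonotype set by membership in a comparison pool and
#' contrasts the two sides: CDR3 length distributions and V-family usage,
#' each clonotype counted once. An empty side yields a warning and a
#' single-sided result.
#'
#' @param clonotypes clonotype tibble from [assign_clonotypes()].
#' @param pool comparison pool (clonotype tibble or key vector).
#' @return list with `shared` and `unshared` (each `NULL` or a list with
#'   `n`, `length_table`, `mean_length`, `v_family`), plus `n_shared` /
#'   `n_unshared`.
#' @export
compare_shared_unshared <- function(clonotypes, pool) {
  pool_keys <- share_keys(pool)
  shared_sel <- clonotypes$key %in% pool_keys
  side_summary <- function(ct) {
    if (nrow(ct) == 0) return(NULL)
    lens <- ct$cdr3_length
    tab <- table(factor(lens, levels = seq(min(lens), max(lens))))
    fam <- table(gene_family(ct$v_gene))
    list(
      n = nrow(ct),
      length_table = tibble::tibble(value = as.integer(names(tab)),
                                    frequency = as.numeric(tab) / sum(tab)),
      mean_length = mean(lens),
      v_family = tibble::tibble(family = names(fam),
                                frequency = as.numeric(fam) / sum(fam))
    )
  }
  if (!any(shared_sel) || all(shared_sel)) {
    warning("one side of the shared/unshared partition is empty")
  }
  list(
    shared = side_summary(clonotypes[shared_sel, ]),
    unshared = side_summary(clonotypes[!shared_sel, ]),
    n_shared = sum(shared_sel),
    n_unshared = sum(!shared_sel)
  )
}

#' Position frequency matrix (sequence logo) of fixed-length CDR3s
#'
#' Column-normalized amino-acid frequencies over all clonotypes whose CDR3
#' has length `L`, with residue-category annotation (polar GSTYCQN, basic
#' KRH, acidic DE, hydrophobic AVLIPWFM) and torso-position flags (the
#' first `t_n` and last `t_c` positions; the remainder is the loop head).
#'
#' @param clonotypes clonotype tibble from [assign_clonotypes()].
#' @param length CDR3 length L to select.
#' @param t_n,t_c number of N- and C-terminal torso positions.
#' @return object of class `position_frequency_matrix`: list with `pfm`
#'   (20 x L matrix, columns sum to 1), `length`, `n`, `categories`,
#'   `torso` (logical per position).
#' @export
cdr3_logo <- function(clonotypes, length, t_n = 2, t_c = 2) {
  sel <- clonotypes$cdr3_length == length
  if (!any(sel)) stop("no clonotypes with CDR3 length ", length)
  seqs <- clonotypes$cdr3_aa[sel]
  mat <- matrix(0, length(AA_ALPHABET), length,
                dimnames = list(sort(AA_ALPHABET), NULL))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (pos in seq_len(length)) {
    tab <- table(factor(chars[, pos], levels = rownames(mat)))
    mat[, pos] <- as.numeric(tab) / sum(tab)
  }
  category <- stats::setNames(rep(names(AA_CATEGORIES),
                                  lengths(AA_CATEGORIES))[match(rownames(mat), AA_ALPHABET)],
                              rownames(mat))
  torso <- seq_len(length) <= t_n | seq_len(length) > length - t_c
  structure(
    list(pfm = mat, length = length, n = length(seqs),
         categories = category, torso = torso),
    class = "position_frequency_matrix"
  )
}
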