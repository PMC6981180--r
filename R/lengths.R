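# CDR3 and junction statistics: length distributions, D3-J6 co-usage,
# long-CDRH3 tails, short-CDRL3 fractions, isotype and mutation summaries.
# All statistics are duplicate-weighted over productive records unless
# noted.

#' Integer length distribution of a record variable
#'
#' Duplicate-weighted normalized histogram over the observed integer
#' support, with weighted mean and SEM.
#'
#' @param rep a `repertoire`.
#' @param variable one of `"cdr3_length"`, `"n1_length"`, `"n2_length"`,
#'   `"vj_insertion_length"`.
#' @param weighted weight by `duplicate_count`.
#' @return object of class `distribution_summary`: list with `variable`,
#'   `table` (tibble `value`, `frequency` over the full integer range),
#'   `mean`, `sem`, `n`.
#' @export
length_distribution <- function(rep, variable = c("cdr3_length", "n1_length",
                                                  "n2_length",
                                                  "vj_insertion_length"),
                                weighted = TRUE) {
  variable <- match.arg(variable)
  recs <- productive_records(rep)
  x <- recs[[variable]]
  w <- if (weighted) recs$duplicate_count else rep(1L, nrow(recs))
  keep <- !is.na(x)
  if (!any(keep)) stop("no non-missing values of ", variable)
  x <- x[keep]; w <- w[keep]
  support <- seq(min(x), max(x))
  h <- tapply(w, factor(x, levels = support), sum, default = 0)
  freq <- as.numeric(h) / sum(h)
  ms <- wmean_sem(x, w)
  structure(
    list(variable = variable,
         table = tibble::tibble(value = support, frequency = freq),
         mean = ms$mean, sem = ms$sem, n = ms$n),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary> %s: mean %.3f (SEM %.4f), n = %d, support %d..%d\n",
              x$variable, x$mean, x$sem, x$n,
              min(x$table$value), max(x$table$value)))
  invisible(x)
}

#' Co-usage frequency of a D family and a J family
#'
#' Duplicate-weighted fraction of productive heavy chain records whose D
#' gene and J gene belong to the given families (e.g. D family 3 with J
#' family 6, the pairing behind unusually long CDRH3 loops).
#'
#' @param rep an IGH `repertoire`.
#' @param d_family,j_family family names, e.g. `"IGHD3"`, `"IGHJ6"`.
#' @return scalar frequency.
#' @export
family_pair_frequency <- function(rep, d_family = "IGHD3", j_family = "IGHJ6") {
  if (rep_locus(rep) != "IGH") stop("family_pair_frequency requires an IGH repertoire")
  recs <- productive_records(rep)
  if (nrow(recs) == 0) stop("no productive records")
  w <- recs$duplicate_count
  hit <- !is.na(recs$d_gene) & gene_family(recs$d_gene) == d_family &
    gene_family(recs$j_gene) == j_family
  sum(w[hit]) / sum(w)
}

#' Cumulative long-CDR3 frequency
#'
#' For each observed length L, the duplicate-weighted fraction of records
#' with `cdr3_length >= L`: monotone non-increasing, equal to 1 at the
#' minimum observed length, and equal to `1 - CDF` of
#' [length_distribution()] shifted by one support step.
#'
#' @param rep a `repertoire`.
#' @return tibble with `length` and `tail_frequency`.
#' @export
cdr3_tail_frequency <- function(rep) {
  d <- length_distribution(rep, "cdr3_length")
  tibble::tibble(
    length = d$table$value,
    tail_frequency = rev(cumsum(rev(d$table$frequency)))
  )
}

#' Fraction of kappa chains with a short CDRL3
#'
#' Duplicate-weighted fraction of productive kappa records with
#' `cdr3_length == k` (default 5 aa, the length relevant to
#' germline-targeting immunogen work).
#'
#' @param rep an IGK `repertoire`.
#' @param k CDRL3 length in amino acids.
#' @return scalar fraction.
#' @export
short_cdrl3_fraction <- function(rep, k = 5) {
  if (rep_locus(rep) != "IGK") stop("short_cdrl3_fraction requires an IGK repertoire")
  recs <- productive_records(rep)
  if (nrow(recs) == 0) stop("no productive records")
  w <- recs$duplicate_count
  hit <- !is.na(recs$cdr3_length) & recs$cdr3_length == k
  sum(w[hit]) / sum(w)
}

#' Isotype frequencies of a heavy chain repertoire
#'
#' @param rep an IGH `repertoire` with isotype labels.
#' @return tibble with `isotype` (IgM, IgG, unknown) and `frequency`
#'   (sums to 1).
#' @export
isotype_frequencies <- function(rep) {
  if (rep_locus(rep) != "IGH") stop("isotype_frequencies requires an IGH repertoire")
  recs <- productive_records(rep)
  iso <- recs$isotype
  if (nrow(recs) == 0 || all(is.na(iso))) stop("no isotype labels")
  iso[is.na(iso)] <- "unknown"
  w <- recs$duplicate_count
  tot <- tapply(w, factor(iso, levels = c("IgM", "IgG", "unknown")), sum,
                default = 0)
  tibble::tibble(isotype = names(tot),
                 frequency = as.numeric(tot) / sum(tot))
}

#' Somatic mutation summary by group
#'
#' Duplicate-weighted mean V-region mutation count per group (default:
#' isotype), with SEM. Groups with a single record report SEM 0 and are
#' flagged; empty groups are omitted with a warning.
#'
#' @param rep a `repertoire`.
#' @param by grouping record column (default `"isotype"`).
#' @return tibble with `group`, `mean_mutations`, `sem`, `n`,
#'   `single_record`.
#' @export
mutation_summary <- function(rep, by = "isotype") {
  recs <- productive_records(rep)
  if (!by %in% names(recs)) stop("no such grouping column: ", by)
  if (all(is.na(recs$v_mutation_count))) stop("v_mutation_count is absent")
  grp <- recs[[by]]
  grp[is.na(grp)] <- "unknown"
  levels <- unique(grp)
  rows <- lapply(levels, function(gl) {
    sel <- grp == gl & !is.na(recs$v_mutation_count)
    if (!any(sel)) {
      warning("group ", gl, " has no mutation counts; omitted")
      return(NULL)
    }
    ms <- wmean_sem(recs$v_mutation_count[sel], recs$duplicate_count[sel])
    tibble::tibble(group = gl, mean_mutations = ms$mean, sem = ms$sem,
                   n = ms$n, single_record = ms$n == 1)
  })
  dplyr::bind_rows(rows)
}
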