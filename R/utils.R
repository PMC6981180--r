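# Internal helpers shared across modules.

# Derive a child seed from a root seed and a fixed stream offset.
# Arithmetic in doubles is exact here (all terms < 2^53); result < 2^31.
sub_seed <- function(seed, stream) {
  ((abs(as.numeric(seed)) %% 1000003) * 75011 + stream * 104729) %% 2147483587 + 1
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

NT <- c("A", "C", "G", "T")

# Reverse complement of short nucleotide strings (vectorized).
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Translate in-frame nucleotide strings to amino acids; stops are "*".
translate_nt <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nchar(x) > 0 & nchar(x) %% 3 == 0
  if (any(ok)) {
    aa <- suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(x[ok]),
                            if.fuzzy.codon = "X")
    )
    out[ok] <- as.character(aa)
  }
  out
}

#' Strip the allele suffix from a gene call
#'
#' `"IGHV4-34*01"` becomes `"IGHV4-34"`. All analyses in this package work at
#' the gene level; original calls are kept alongside the stripped form.
#'
#' @param call character vector of gene calls.
#' @return character vector of allele-stripped gene names.
#' @export
strip_allele <- function(call) {
  sub("\\*.*$", "", call)
}

#' Gene family of a gene name
#'
#' The family is the gene name up to the first hyphen-delimited position
#' token: `"IGHD3-10"` belongs to family `"IGHD3"`.
#'
#' @param gene character vector of (allele-stripped) gene names.
#' @return character vector of family names.
#' @export
gene_family <- function(gene) {
  sub("-.*$", "", strip_allele(gene))
}

# Weighted mean and (weighted) standard error of the mean.
wmean_sem <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0) stop("no non-missing values")
  m <- sum(w * x) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  v <- sum(w * (x - m)^2) / sum(w)
  sem <- if (n_eff > 1) sqrt(v * n_eff / (n_eff - 1)) / sqrt(n_eff) else 0
  list(mean = m, sem = sem, n = length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
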