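# Clonotype assignment, cross-compartment incidence, Chao richness
# estimation and rarefaction.
#
# A clonotype is the exact-identity class (V gene, J gene, CDR3 amino acid
# sequence), allele-stripped. Chao2 with m = 2 sampling units keeps the
# (m-1)/m = 1/2 factor explicitly:
#   S_chao2 = S_obs + (1/2) * Q1^2 / (2 Q2)            (Q2 > 0)
#   S_chao2 = S_obs + (1/2) * Q1 (Q1 - 1) / (2 (Q2+1)) (bias-corrected)
# Chao1 is the abundance analogue on singleton/doubleton counts F1, F2.

clonotype_key <- function(v_gene, j_gene, cdr3_aa) {
  paste(v_gene, j_gene, cdr3_aa, sep = "|")
}

#' Collapse a repertoire into clonotypes
#'
#' Productive heavy chain records are grouped by (V gene, J gene, CDR3
#' amino acid sequence); read counts are aggregated duplicate-weighted.
#' Productive records lacking a CDR3 or a gene call are rejected and
#' tallied in the `rejections` attribute. Output rows are ordered by key.
#'
#' @param rep a `repertoire` (or record tibble).
#' @return tibble with `key`, `v_gene`, `j_gene`, `cdr3_aa`, `cdr3_length`,
#'   `n_reads`; attribute `rejections`.
#' @export
assign_clonotypes <- function(rep) {
  recs <- productive_records(rep)
  ok <- !is.na(recs$v_gene) & !is.na(recs$j_gene) & !is.na(recs$cdr3_aa) &
    nchar(recs$cdr3_aa) > 0
  rejected <- sum(!ok)
  recs <- recs[ok, ]
  if (nrow(recs) == 0) stop("no records eligible for clonotype assignment")
  key <- clonotype_key(recs$v_gene, recs$j_gene, recs$cdr3_aa)
  out <- tibble::tibble(key = key, v_gene = recs$v_gene, j_gene = recs$j_gene,
                        cdr3_aa = recs$cdr3_aa, w = recs$duplicate_count) |>
    dplyr::group_by(.data$key, .data$v_gene, .data$j_gene, .data$cdr3_aa) |>
    dplyr::summarise(n_reads = sum(.data$w), .groups = "drop") |>
    dplyr::arrange(.data$key)
  out$cdr3_length <- nchar(out$cdr3_aa)
  attr(out, "rejections") <- rejected
  out
}

#' Two-compartment incidence table
#'
#' Builds the m = 2 capture-recapture incidence summary from the clonotype
#' sets of the two tissue compartments of one subject: Q1 clonotypes seen
#' in exactly one compartment, Q2 seen in both, S_obs = Q1 + Q2.
#'
#' @param ln,sp clonotype tibbles from [assign_clonotypes()] (or character
#'   vectors of clonotype keys).
#' @return object of class `incidence_table`: list with `S_obs`, `Q1`,
#'   `Q2`, `m`, and the key sets.
#' @export
build_incidence <- function(ln, sp) {
  ln_keys <- unique(if (is.character(ln)) ln else ln$key)
  sp_keys <- unique(if (is.character(sp)) sp else sp$key)
  s_obs <- length(union(ln_keys, sp_keys))
  if (s_obs == 0) stop("empty clonotype union")
  q2 <- length(intersect(ln_keys, sp_keys))
  structure(
    list(S_obs = s_obs, Q1 = s_obs - q2, Q2 = q2, m = 2L,
         ln_keys = ln_keys, sp_keys = sp_keys),
    class = "incidence_table"
  )
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("<incidence_table> m = %d: S_obs %d, Q1 %d, Q2 %d\n",
              x$m, x$S_obs, x$Q1, x$Q2))
  invisible(x)
}

new_diversity_estimate <- function(estimator, estimate, inputs) {
  structure(list(estimator = estimator, estimate = estimate, inputs = inputs),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> %s: %.1f (inputs: %s)\n", x$estimator,
              x$estimate,
              paste(names(x$inputs), unlist(x$inputs), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Chao2 incidence-based richness estimate
#'
#' Classic lower-bound estimator from a two-unit incidence table. When
#' `Q2 = 0` (or on request) the bias-corrected form is used, which is
#' always finite.
#'
#' @param table an `incidence_table` with `m = 2`.
#' @param bias_corrected force the bias-corrected form.
#' @return a `diversity_estimate` (estimate always >= S_obs).
#' @export
chao2 <- function(table, bias_corrected = FALSE) {
  stopifnot(inherits(table, "incidence_table"), table$m == 2L)
  k <- (table$m - 1) / table$m
  if (bias_corrected || table$Q2 == 0) {
    est <- table$S_obs + k * table$Q1 * (table$Q1 - 1) / (2 * (table$Q2 + 1))
    name <- "chao2_bias_corrected"
  } else {
    est <- table$S_obs + k * table$Q1^2 / (2 * table$Q2)
    name <- "chao2"
  }
  new_diversity_estimate(name, est,
                         list(S_obs = table$S_obs, Q1 = table$Q1, Q2 = table$Q2))
}

#' Chao1 abundance-based richness estimate
#'
#' Stand-in abundance estimator (the incidence-based Chao2 is the primary
#' estimator for the two-tissue design): S_obs + F1^2 / (2 F2) from
#' singleton/doubleton counts, bias-corrected when F2 = 0.
#'
#' @param abundances positive integer abundance vector (one entry per
#'   clonotype or sequence).
#' @param bias_corrected force the bias-corrected form.
#' @return a `diversity_estimate`.
#' @export
chao1 <- function(abundances, bias_corrected = FALSE) {
  if (length(abundances) == 0) stop("empty abundance vector")
  stopifnot(all(abundances >= 1))
  s_obs <- length(abundances)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  if (bias_corrected || f2 == 0) {
    est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    name <- "chao1_bias_corrected"
  } else {
    est <- s_obs + f1^2 / (2 * f2)
    name <- "chao1"
  }
  new_diversity_estimate(name, est, list(S_obs = s_obs, F1 = f1, F2 = f2))
}

# expand a repertoire (or clonotype tibble) to one key per read
read_level_keys <- function(x, unit = c("clonotype", "sequence")) {
  unit <- match.arg(unit)
  if (inherits(x, "repertoire") || (is.data.frame(x) && "sequence" %in% names(x) &&
                                    !"n_reads" %in% names(x))) {
    recs <- productive_records(x)
    keys <- if (unit == "sequence") {
      recs$sequence
    } else {
      clonotype_key(recs$v_gene, recs$j_gene, recs$cdr3_aa)
    }
    keep <- !is.na(keys)
    rep(keys[keep], recs$duplicate_count[keep])
  } else {
    rep(x$key, x$n_reads)
  }
}

#' Rarefaction curve of unique clonotypes
#'
#' For each fraction f < 1: subsample `floor(f * N)` reads without
#' replacement (duplicate counts expanded), count unique clonotypes, and
#' average over `n_reps` replicates; f = 1 is computed once on the full
#' data. A perfectly diverse sample lies on the diagonal; a monoclonal one
#' is flat at 1.
#'
#' @param x a `repertoire` or a clonotype tibble from
#'   [assign_clonotypes()].
#' @param fractions subsampling fractions in (0, 1].
#' @param n_reps replicates per fraction below 1.
#' @param seed integer seed.
#' @param unit `"clonotype"` or `"sequence"` (unique nucleotide sequence).
#' @return tibble with `fraction`, `n_reads`, `mean_unique`.
#' @export
rarefaction <- function(x, fractions = seq(0.1, 1, by = 0.1), n_reps = 10,
                        seed = 1, unit = "clonotype") {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  keys <- read_level_keys(x, unit)
  n <- length(keys)
  fractions <- sort(fractions)
  with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      size <- max(1L, floor(f * n))
      uniq <- if (f == 1) {
        length(unique(keys))
      } else {
        mean(vapply(seq_len(n_reps), function(r) {
          length(unique(keys[sample.int(n, size)]))
        }, numeric(1)))
      }
      tibble::tibble(fraction = f, n_reads = size, mean_unique = uniq)
    })
    dplyr::bind_rows(rows)
  })
}

#' Diversity estimates over increasing sample fractions
#'
#' Applies the rarefaction subsampling scheme and recomputes the richness
#' estimator at each fraction: reads of both compartments are subsampled
#' without replacement, clonotypes rebuilt, and the estimator applied; means
#' over `n_reps` replicates are reported (the 1.0 fraction once).
#'
#' @param ln,sp `repertoire` objects (or clonotype tibbles) for the two
#'   compartments.
#' @param fractions subsampling fractions in (0, 1].
#' @param estimator `"chao2"` (incidence, two compartments) or `"chao1"`
#'   (abundance, pooled).
#' @param n_reps replicates per fraction below 1.
#' @param seed integer seed.
#' @param unit `"clonotype"` or `"sequence"`.
#' @return tibble with `fraction` and `mean_estimate`; the last row
#'   (fraction 1) is the full-data maximum estimate.
#' @export
diversity_vs_fraction <- function(ln, sp, fractions = seq(0.1, 1, by = 0.1),
                                  estimator = c("chao2", "chao1"),
                                  n_reps = 10, seed = 1, unit = "clonotype") {
  estimator <- match.arg(estimator)
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  ln_keys <- read_level_keys(ln, unit)
  sp_keys <- read_level_keys(sp, unit)
  est_once <- function(a, b) {
    if (estimator == "chao2") {
      chao2(build_incidence(unique(a), unique(b)))$estimate
    } else {
      chao1(as.integer(table(c(a, b))))$estimate
    }
  }
  fractions <- sort(fractions)
  with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      est <- if (f == 1) {
        est_once(ln_keys, sp_keys)
      } else {
        mean(vapply(seq_len(n_reps), function(r) {
          a <- ln_keys[sample.int(length(ln_keys), max(1L, floor(f * length(ln_keys))))]
          b <- sp_keys[sample.int(length(sp_keys), max(1L, floor(f * length(sp_keys))))]
          est_once(a, b)
        }, numeric(1)))
      }
      tibble::tibble(fraction = f, mean_estimate = est)
    })
    dplyr::bind_rows(rows)
  })
}
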