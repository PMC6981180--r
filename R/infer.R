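# Annotation-based inference of recombination models.
#
# Event distributions are empirical conditional frequencies with additive
# (pseudocount) smoothing over a declared support, computed from the single
# best annotation per read. This replaces scenario-marginalizing EM: with
# simulator-grade annotations the event fields are exact, and the estimator
# is consistent (KL(truth || inferred) shrinks as training size grows; see
# the test suite).

#' Select unmutated productive records for model inference
#'
#' Keeps productive records with `v_mutation_count == 0`; when more than
#' `n` qualify, draws a uniform subsample of size `n` (seeded). A shortfall
#' is reported via message and the `n_selected` attribute.
#'
#' @param rep a `repertoire`.
#' @param n target number of training records.
#' @param seed subsampling seed.
#' @return a `repertoire` containing the selected records.
#' @export
select_unmutated <- function(rep, n = 100000, seed = 1) {
  stopifnot(n > 0)
  recs <- productive_records(rep)
  recs <- recs[!is.na(recs$v_mutation_count) & recs$v_mutation_count == 0L, ]
  if (nrow(recs) == 0) stop("no unmutated productive records to select")
  if (nrow(recs) > n) {
    keep <- with_seed(seed, sort(sample.int(nrow(recs), n)))
    recs <- recs[keep, ]
  } else if (nrow(recs) < n) {
    message("select_unmutated: only ", nrow(recs), " of the requested ", n,
            " records qualify")
  }
  out <- repertoire(recs, subject_id = rep$subject_id, tissue = rep$tissue,
                    locus = rep$locus, species = rep$species,
                    germline = rep$germline)
  attr(out, "n_selected") <- nrow(recs)
  out
}

count_smooth <- function(x, levels, pseudocount) {
  cnt <- table(factor(x, levels = levels))
  p <- (as.numeric(cnt) + pseudocount) / (sum(cnt) + pseudocount * length(levels))
  if (sum(cnt) == 0 && pseudocount == 0) p <- rep(1 / length(levels), length(levels))
  stats::setNames(p, levels)
}

cond_count_smooth <- function(parent, x, parent_levels, levels, pseudocount) {
  mat <- matrix(0, length(parent_levels), length(levels),
                dimnames = list(parent_levels, levels))
  for (pl in parent_levels) {
    mat[pl, ] <- count_smooth(x[parent == pl], levels, pseudocount)
  }
  mat
}

#' Infer a recombination model from annotated records
#'
#' Each event distribution is `(count + pseudocount) / (total + pseudocount
#' * support size)` over its declared support. The default pseudocount of
#' 0.5 per support cell keeps every probability strictly positive, so KL
#' divergences against the inferred model are finite.
#'
#' @param rep a `repertoire` (typically from [select_unmutated()]); records
#'   must carry gene calls, trim and insertion-length fields. Insertion
#'   nucleotide sequences (`n1_sequence`/`n2_sequence`) feed the Markov
#'   estimate when present; otherwise the insertion chain is left uniform
#'   with a warning.
#' @param germline germline-set tibble defining the gene supports.
#' @param pseudocount additive smoothing per support cell.
#' @param max_v_trim,max_d_trim,max_j_trim,max_insertion support bounds
#'   (defaults match the species presets).
#' @return a `recomb_model`.
#' @export
infer_model <- function(rep, germline = rep$germline, pseudocount = 0.5,
                        max_v_trim = NULL, max_d_trim = 6, max_j_trim = NULL,
                        max_insertion = NULL) {
  # records are used exactly as provided: upstream selection (e.g.
  # select_unmutated) decides which rearrangements train the model, and
  # conditioning on productivity is a property of the training set, not of
  # the estimator
  recs <- productive_records(rep, productive_only = FALSE)
  locus <- rep_locus(rep)
  if (is.null(germline)) stop("a germline reference is required")
  if (is.null(max_v_trim)) max_v_trim <- if (locus == "IGH") 8 else 12
  if (is.null(max_j_trim)) max_j_trim <- if (locus == "IGH") 8 else 9
  if (is.null(max_insertion)) max_insertion <- if (locus == "IGH") 15 else 8

  needed <- if (locus == "IGH") {
    c("v_gene", "d_gene", "j_gene", "v_trim3", "d_trim5", "d_trim3",
      "j_trim5", "n1_length", "n2_length")
  } else {
    c("v_gene", "j_gene", "v_trim3", "j_trim5", "vj_insertion_length")
  }
  for (f in needed) {
    if (!f %in% names(recs) || all(is.na(recs[[f]]))) {
      stop("records are missing the annotation field: ", f)
    }
  }

  v_genes <- germline$gene[germline$segment == "V"]
  j_genes <- germline$gene[germline$segment == "J"]
  trim_lv <- function(max) as.character(0:max)
  ins_lv <- trim_lv(max_insertion)

  p_v <- count_smooth(recs$v_gene, v_genes, pseudocount)
  p_v_trim <- cond_count_smooth(recs$v_gene, recs$v_trim3, v_genes,
                                trim_lv(max_v_trim), pseudocount)
  p_j_trim <- cond_count_smooth(recs$j_gene, recs$j_trim5, j_genes,
                                trim_lv(max_j_trim), pseudocount)

  # insertion-nucleotide Markov chain, pooled over junctions
  ins_seqs <- recs$n1_sequence
  if (locus == "IGH" && "n2_sequence" %in% names(recs)) {
    ins_seqs <- c(ins_seqs, recs$n2_sequence)
  }
  ins_seqs <- ins_seqs[!is.na(ins_seqs) & nchar(ins_seqs) > 0]
  if (length(ins_seqs) == 0) {
    warning("no insertion nucleotide sequences; Markov parameters left uniform")
    markov_init <- stats::setNames(rep(0.25, 4), NT)
    markov_trans <- matrix(0.25, 4, 4, dimnames = list(NT, NT))
  } else {
    markov_init <- count_smooth(substr(ins_seqs, 1, 1), NT, pseudocount)
    chars <- strsplit(ins_seqs[nchar(ins_seqs) > 1], "")
    from <- unlist(lapply(chars, function(x) x[-length(x)]))
    to <- unlist(lapply(chars, function(x) x[-1]))
    markov_trans <- cond_count_smooth(from, to, NT, NT, pseudocount)
  }

  if (locus == "IGH") {
    d_genes <- germline$gene[germline$segment == "D"]
    dj <- paste(recs$d_gene, recs$j_gene, sep = "\r")
    dj_levels <- as.vector(outer(d_genes, j_genes, paste, sep = "\r"))
    p_dj <- matrix(count_smooth(dj, dj_levels, pseudocount),
                   nrow = length(d_genes), dimnames = list(d_genes, j_genes))
    td <- trim_lv(max_d_trim)
    dt_cell <- paste(recs$d_trim5, recs$d_trim3, sep = "\r")
    dt_levels <- as.vector(outer(td, td, paste, sep = "\r"))
    dmat <- cond_count_smooth(recs$d_gene, dt_cell, d_genes, dt_levels, pseudocount)
    p_d_trim <- array(dmat, dim = c(length(d_genes), length(td), length(td)),
                      dimnames = list(d_genes, td, td))
    recomb_model(
      locus = "IGH", germline = germline,
      p_v = p_v, p_dj = p_dj,
      p_v_trim = p_v_trim, p_d_trim = p_d_trim, p_j_trim = p_j_trim,
      p_n1 = count_smooth(recs$n1_length, ins_lv, pseudocount),
      p_n2 = count_smooth(recs$n2_length, ins_lv, pseudocount),
      markov_init = markov_init, markov_trans = markov_trans,
      species_tag = paste0("inferred:", rep$subject_id)
    )
  } else {
    recomb_model(
      locus = "IGK", germline = germline,
      p_v = p_v,
      p_j = count_smooth(recs$j_gene, j_genes, pseudocount),
      p_v_trim = p_v_trim, p_j_trim = p_j_trim,
      p_n1 = count_smooth(recs$vj_insertion_length, ins_lv, pseudocount),
      markov_init = markov_init, markov_trans = markov_trans,
      species_tag = paste0("inferred:", rep$subject_id)
    )
  }
}

#' Generate a synthetic repertoire from a model
#'
#' Draws `n` rearrangements via [simulate_rearrangement()] and wraps them as
#' a repertoire labelled with the model's species tag.
#'
#' @param model a normalized `recomb_model`.
#' @param n number of rearrangements (>= 1).
#' @param seed integer seed.
#' @return a `repertoire`.
#' @export
generate <- function(model, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  recs <- simulate_rearrangement(model, n = n, seed = seed)
  repertoire(recs, subject_id = paste0("synthetic:", model$species_tag),
             tissue = "pooled", locus = model$locus,
             species = model$species_tag, germline = model$germline)
}
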