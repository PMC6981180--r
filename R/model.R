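# Factorized generative model of V(D)J recombination.
#
# Heavy chain factorization:
#   P(V) * P(D,J) * P(v_trim3 | V) * P(d_trim5, d_trim3 | D) * P(j_trim5 | J)
#   * P(n1_len) * P(n1 nt | len) * P(n2_len) * P(n2 nt | len)
# Kappa factorization:
#   P(V) * P(J) * P(v_trim3 | V) * P(j_trim5 | J) * P(n1_len) * P(n1 nt | len)
# Insertion nucleotides follow a shared first-order Markov chain
# (markov_init over ACGT, markov_trans 4x4, rows = current nucleotide).
# P nucleotides are a deterministic assembly rule (see simulate_rearrangement),
# not a model event.

MODEL_TOL <- 1e-9

#' Construct a recombination model
#'
#' @param locus `"IGH"` or `"IGK"`.
#' @param germline germline-set tibble covering all needed segments, with
#'   anchors on V and J genes.
#' @param p_v named probability vector over V genes.
#' @param p_dj matrix P(D, J) with D rows and J columns (IGH).
#' @param p_j named probability vector over J genes (IGK).
#' @param p_v_trim matrix, one row per V gene, columns trim sizes `0:max`.
#' @param p_d_trim 3-d array `[D, d_trim5, d_trim3]` of joint trim
#'   probabilities per D gene (each D slice sums to 1; IGH).
#' @param p_j_trim matrix, one row per J gene, columns trim sizes `0:max`.
#' @param p_n1,p_n2 probability vectors over insertion lengths `0:max`
#'   (`p_n2` is `NULL` for IGK; `p_n1` then describes the V-J insertion).
#' @param markov_init,markov_trans first-order Markov parameters for
#'   insertion nucleotides (states A, C, G, T).
#' @param p_nucleotides add 2-nt palindromic P extensions at untrimmed ends
#'   during generation.
#' @param species_tag free label.
#' @return an object of class `recomb_model`.
#' @export
recomb_model <- function(locus, germline, p_v, p_dj = NULL, p_j = NULL,
                         p_v_trim, p_d_trim = NULL, p_j_trim,
                         p_n1, p_n2 = NULL,
                         markov_init, markov_trans,
                         p_nucleotides = TRUE, species_tag = "custom") {
  m <- structure(
    list(locus = locus, germline = germline,
         p_v = p_v, p_dj = p_dj, p_j = p_j,
         p_v_trim = p_v_trim, p_d_trim = p_d_trim, p_j_trim = p_j_trim,
         p_n1 = p_n1, p_n2 = p_n2,
         markov_init = markov_init, markov_trans = markov_trans,
         p_nucleotides = p_nucleotides, species_tag = species_tag),
    class = "recomb_model"
  )
  validate_model(m)
  m
}

#' Validate a recombination model
#'
#' Checks that every event distribution is non-negative and sums to 1
#' within `1e-9`, and that dimensions and names agree with the germline set.
#'
#' @param model a `recomb_model`.
#' @return the model, invisibly; stops on violation.
#' @export
validate_model <- function(model) {
  chk1 <- function(p, what) {
    if (any(is.na(p)) || any(p < 0)) stop(what, ": negative or NA probability")
    if (abs(sum(p) - 1) > MODEL_TOL) {
      stop(sprintf("%s does not sum to 1 (sum = %.12f)", what, sum(p)))
    }
  }
  g <- model$germline
  v_genes <- g$gene[g$segment == "V"]
  j_genes <- g$gene[g$segment == "J"]
  stopifnot(identical(sort(names(model$p_v)), sort(v_genes)))
  chk1(model$p_v, "P(V)")
  if (model$locus == "IGH") {
    d_genes <- g$gene[g$segment == "D"]
    stopifnot(identical(sort(rownames(model$p_dj)), sort(d_genes)),
              identical(sort(colnames(model$p_dj)), sort(j_genes)))
    chk1(model$p_dj, "P(D,J)")
    stopifnot(identical(dimnames(model$p_d_trim)[[1]], rownames(model$p_dj)))
    for (d in rownames(model$p_dj)) {
      chk1(model$p_d_trim[d, , ], paste0("P(d_trim5,d_trim3 | ", d, ")"))
    }
    chk1(model$p_n2, "P(n2_length)")
  } else {
    stopifnot(identical(sort(names(model$p_j)), sort(j_genes)))
    chk1(model$p_j, "P(J)")
  }
  stopifnot(identical(rownames(model$p_v_trim), names(model$p_v)))
  for (v in rownames(model$p_v_trim)) chk1(model$p_v_trim[v, ], paste0("P(v_trim | ", v, ")"))
  jnames <- if (model$locus == "IGH") colnames(model$p_dj) else names(model$p_j)
  stopifnot(identical(rownames(model$p_j_trim), jnames))
  for (j in rownames(model$p_j_trim)) chk1(model$p_j_trim[j, ], paste0("P(j_trim | ", j, ")"))
  chk1(model$p_n1, "P(n1_length)")
  chk1(model$markov_init, "markov_init")
  for (a in NT) chk1(model$markov_trans[a, ], paste0("markov_trans[", a, ",]"))
  invisible(model)
}

#' @export
print.recomb_model <- function(x, ...) {
  cat(sprintf("<recomb_model> %s (%s): %d V, %s%d J; trims 0:%d/0:%d; insertions 0:%d\n",
              x$locus, x$species_tag, length(x$p_v),
              if (x$locus == "IGH") paste0(nrow(x$p_dj), " D, ") else "",
              nrow(x$p_j_trim), ncol(x$p_v_trim) - 1L, ncol(x$p_j_trim) - 1L,
              length(x$p_n1) - 1L))
  invisible(x)
}

# Marginals used as conditioning-parent weights in KL computations.
model_d_marginal <- function(model) rowSums(model$p_dj)
model_j_marginal <- function(model) {
  if (model$locus == "IGH") colSums(model$p_dj) else model$p_j
}

#' Event names of a model's factorization
#' @param model a `recomb_model`.
#' @return character vector of event names.
#' @export
model_events <- function(model) {
  if (model$locus == "IGH") {
    c("v_choice", "dj_choice", "v_trim", "d_trim", "j_trim",
      "n1_length", "n1_nt", "n2_length", "n2_nt")
  } else {
    c("v_choice", "j_choice", "v_trim", "j_trim", "n1_length", "n1_nt")
  }
}

#' Serialize a recombination model to JSON
#'
#' The schema stores the locus, germline table, every event distribution
#' (with names/dimnames) and the Markov insertion parameters; exact
#' round-trip via [read_model()].
#'
#' @param model a `recomb_model`.
#' @param path output JSON file.
#' @export
write_model <- function(model, path) {
  x <- list(
    locus = model$locus,
    species_tag = model$species_tag,
    p_nucleotides = model$p_nucleotides,
    germline = as.list(model$germline),
    p_v = as.list(model$p_v),
    p_j = if (!is.null(model$p_j)) as.list(model$p_j),
    p_dj = if (!is.null(model$p_dj)) {
      list(d = rownames(model$p_dj), j = colnames(model$p_dj), prob = model$p_dj)
    },
    p_v_trim = list(v = rownames(model$p_v_trim), prob = model$p_v_trim),
    p_d_trim = if (!is.null(model$p_d_trim)) {
      list(d = dimnames(model$p_d_trim)[[1]], dim = dim(model$p_d_trim),
           prob = as.vector(model$p_d_trim))
    },
    p_j_trim = list(j = rownames(model$p_j_trim), prob = model$p_j_trim),
    p_n1 = as.list(model$p_n1),
    p_n2 = if (!is.null(model$p_n2)) as.list(model$p_n2),
    markov_init = as.list(model$markov_init),
    markov_trans = model$markov_trans
  )
  # I(17) significant digits: doubles round-trip bit-exactly, so a
  # deserialized model generates identical sequences under the same seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a recombination model from JSON
#' @param path JSON file written by [write_model()].
#' @return a `recomb_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  germline <- tibble::as_tibble(x$germline)
  named <- function(l) {
    v <- unlist(l)
    stats::setNames(as.numeric(v), names(l))
  }
  trim_sup <- function(mat, rn) {
    mat <- as.matrix(mat)
    rownames(mat) <- rn
    colnames(mat) <- as.character(seq_len(ncol(mat)) - 1L)
    mat
  }
  p_dj <- NULL
  p_d_trim <- NULL
  if (!is.null(x$p_dj)) {
    p_dj <- as.matrix(x$p_dj$prob)
    dimnames(p_dj) <- list(x$p_dj$d, x$p_dj$j)
    p_d_trim <- array(x$p_d_trim$prob, dim = x$p_d_trim$dim)
    td <- x$p_d_trim$dim[2] - 1L
    dimnames(p_d_trim) <- list(x$p_d_trim$d, as.character(0:td), as.character(0:td))
  }
  trans <- as.matrix(x$markov_trans)
  dimnames(trans) <- list(NT, NT)
  recomb_model(
    locus = x$locus, germline = germline,
    p_v = named(x$p_v),
    p_dj = p_dj,
    p_j = if (!is.null(x$p_j)) named(x$p_j),
    p_v_trim = trim_sup(x$p_v_trim$prob, x$p_v_trim$v),
    p_d_trim = p_d_trim,
    p_j_trim = trim_sup(x$p_j_trim$prob, x$p_j_trim$j),
    p_n1 = stats::setNames(named(x$p_n1), names(x$p_n1)),
    p_n2 = if (!is.null(x$p_n2)) named(x$p_n2),
    markov_init = stats::setNames(named(x$markov_init)[NT], NT),
    markov_trans = trans,
    p_nucleotides = x$p_nucleotides,
    species_tag = x$species_tag
  )
}

# Same germline genes and identical event supports: precondition for KL.
assert_same_support <- function(p, q) {
  if (p$locus != q$locus) stop("models have different loci")
  if (!identical(sort(names(p$p_v)), sort(names(q$p_v))) ||
      !identical(dim(p$p_v_trim), dim(q$p_v_trim)) ||
      !identical(dim(p$p_j_trim), dim(q$p_j_trim)) ||
      length(p$p_n1) != length(q$p_n1)) {
    stop("mismatched model supports")
  }
  if (p$locus == "IGH") {
    if (!identical(sort(rownames(p$p_dj)), sort(rownames(q$p_dj))) ||
        !identical(sort(colnames(p$p_dj)), sort(colnames(q$p_dj))) ||
        !identical(dim(p$p_d_trim), dim(q$p_d_trim)) ||
        length(p$p_n2) != length(q$p_n2)) {
      stop("mismatched model supports")
    }
  }
  g_p <- p$germline[order(p$germline$gene), c("gene", "segment")]
  g_q <- q$germline[order(q$germline$gene), c("gene", "segment")]
  if (!identical(as.data.frame(g_p), as.data.frame(g_q))) {
    stop("models were built on different germline references")
  }
  invisible(TRUE)
}
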