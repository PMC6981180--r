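# Shared fixtures: enumerable toy models, a brute-force joint-KL oracle,
# and small hand-built repertoires.

# Minimal germline: 2 V, 2 D, 2 J drawn from the packaged toy set.
tiny_germline <- function() {
  gs <- toy_germline_set("human_like", "IGH")
  gs[gs$gene %in% c("IGHV1-2", "IGHV3-23", "IGHD1-1", "IGHD3-10",
                    "IGHJ4", "IGHJ6"), ]
}

# Fully enumerable model: trims in {0,1}, insertions in {0,1}.
tiny_model <- function(p_v = c(0.6, 0.4),
                       p_d = c(0.7, 0.3), p_j = c(0.55, 0.45),
                       vt = c(0.8, 0.2), dt5 = c(0.75, 0.25),
                       dt3 = c(0.65, 0.35), jt = c(0.7, 0.3),
                       n1 = c(0.5, 0.5), n2 = c(0.6, 0.4),
                       init = c(A = 0.3, C = 0.3, G = 0.25, T = 0.15),
                       trans = NULL, species_tag = "toy") {
  g <- tiny_germline()
  v_genes <- g$gene[g$segment == "V"]
  d_genes <- g$gene[g$segment == "D"]
  j_genes <- g$gene[g$segment == "J"]
  if (is.null(trans)) {
    trans <- matrix(c(0.25, 0.3, 0.25, 0.2,
                      0.2, 0.3, 0.3, 0.2,
                      0.3, 0.2, 0.3, 0.2,
                      0.25, 0.25, 0.2, 0.3),
                    4, 4, byrow = TRUE, dimnames = list(c("A","C","G","T"),
                                                        c("A","C","G","T")))
  }
  sup <- c("0", "1")
  vmat <- matrix(rep(vt, each = 2), 2, 2, dimnames = list(v_genes, sup))
  jmat <- matrix(rep(jt, each = 2), 2, 2, dimnames = list(j_genes, sup))
  darr <- array(rep(as.vector(outer(dt5, dt3)), each = 2), dim = c(2, 2, 2),
                dimnames = list(d_genes, sup, sup))
  recomb_model(
    locus = "IGH", germline = g,
    p_v = setNames(p_v, v_genes),
    p_dj = outer(setNames(p_d, d_genes), setNames(p_j, j_genes)),
    p_v_trim = vmat, p_d_trim = darr, p_j_trim = jmat,
    p_n1 = setNames(n1, sup), p_n2 = setNames(n2, sup),
    markov_init = init, markov_trans = trans,
    species_tag = species_tag
  )
}

# A different toy model on the same supports (for KL tests).
tiny_model_q <- function() {
  tiny_model(p_v = c(0.35, 0.65), p_d = c(0.5, 0.5), p_j = c(0.3, 0.7),
             vt = c(0.6, 0.4), dt5 = c(0.55, 0.45), dt3 = c(0.5, 0.5),
             jt = c(0.45, 0.55), n1 = c(0.7, 0.3), n2 = c(0.4, 0.6),
             init = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
             species_tag = "toy-q")
}

# Probability of an insertion string under a model's Markov chain.
string_prob <- function(s, model) {
  if (nchar(s) == 0) return(1)
  ch <- strsplit(s, "")[[1]]
  p <- model$markov_init[ch[1]]
  if (length(ch) > 1) {
    for (i in 2:length(ch)) p <- p * model$markov_trans[ch[i - 1], ch[i]]
  }
  unname(p)
}

# Brute-force KL over the fully enumerated joint event distribution of two
# tiny models (independent of the chain-rule implementation under test).
joint_kl_oracle <- function(p, q) {
  strings_for <- function(L) if (L == 0) "" else c("A", "C", "G", "T")
  total <- 0
  for (v in names(p$p_v)) for (d in rownames(p$p_dj)) for (j in colnames(p$p_dj)) {
    for (vt in 0:1) for (t5 in 0:1) for (t3 in 0:1) for (jt in 0:1) {
      base_p <- p$p_v[v] * p$p_dj[d, j] * p$p_v_trim[v, vt + 1] *
        p$p_d_trim[d, t5 + 1, t3 + 1] * p$p_j_trim[j, jt + 1]
      base_q <- q$p_v[v] * q$p_dj[d, j] * q$p_v_trim[v, vt + 1] *
        q$p_d_trim[d, t5 + 1, t3 + 1] * q$p_j_trim[j, jt + 1]
      for (l1 in 0:1) for (s1 in strings_for(l1)) {
        for (l2 in 0:1) for (s2 in strings_for(l2)) {
          pp <- base_p * p$p_n1[l1 + 1] * string_prob(s1, p) *
            p$p_n2[l2 + 1] * string_prob(s2, p)
          qq <- base_q * q$p_n1[l1 + 1] * string_prob(s1, q) *
            q$p_n2[l2 + 1] * string_prob(s2, q)
          if (pp > 0) total <- total + pp * log2(pp / qq)
        }
      }
    }
  }
  unname(total)
}

# Hand-built record table (productive unless stated).
hand_records <- function(junctions, v = "IGHV1-2*01", j = "IGHJ4*01",
                         d = "IGHD3-10*01", dup = 1L, isotype = "IgM") {
  n <- length(junctions)
  tibble::tibble(
    sequence_id = sprintf("r%03d", seq_len(n)),
    v_call = rep_len(v, n), d_call = rep_len(d, n), j_call = rep_len(j, n),
    v_gene = strip_allele(rep_len(v, n)),
    d_gene = strip_allele(rep_len(d, n)),
    j_gene = strip_allele(rep_len(j, n)),
    junction_aa = junctions,
    cdr3_aa = substr(junctions, 2, nchar(junctions) - 1),
    cdr3_length = nchar(junctions) - 2L,
    isotype = rep_len(isotype, n),
    v_mutation_count = 0L,
    duplicate_count = rep_len(as.integer(dup), n),
    productive = junction_is_productive_pub(junctions)
  )
}

# productivity rule re-exposed for fixtures (mirrors the package's rule)
junction_is_productive_pub <- function(junction_aa) {
  !is.na(junction_aa) & nchar(junction_aa) >= 4 &
    startsWith(junction_aa, "C") &
    substr(junction_aa, nchar(junction_aa), nchar(junction_aa)) %in% c("W", "F") &
    !grepl("*", junction_aa, fixed = TRUE)
}

hand_repertoire <- function(junctions, locus = "IGH", tissue = "pooled", ...) {
  repertoire(hand_records(junctions, ...), subject_id = "T1", tissue = tissue,
             locus = locus)
}
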