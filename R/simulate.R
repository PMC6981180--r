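# Generative V(D)J recombination simulator.
#
# A rearrangement is assembled as
#   V[1 .. len-v_trim3] (+P) | n1 insertion | (+P) D[d_trim5+1 .. len-d_trim3] (+P)
#   | n2 insertion | (+P) J[j_trim5+1 .. end]
# The junction runs from the V second-CYS codon to the end of the J
# TRP/PHE codon. P nucleotides are a deterministic 2-nt palindromic
# (reverse-complement) extension added at each coding end whose adjacent
# trim is exactly 0 (hairpin-opening mimic); they are an assembly rule, not
# a model event. The kappa locus drops the D segment and uses a single V-J
# insertion.

# truncated geometric: P(k) propto decay^k on 0:max
tgeom <- function(decay, max) {
  p <- decay^(0:max)
  stats::setNames(p / sum(p), as.character(0:max))
}

# truncated negative binomial insertion-length profile
tnbinom <- function(mu, max, size = 2) {
  p <- stats::dnbinom(0:max, size = size, mu = mu)
  stats::setNames(p / sum(p), as.character(0:max))
}

# conditional trim matrix: one row per gene, shared length profile
trim_matrix <- function(genes, decay, max) {
  p <- tgeom(decay, max)
  mat <- matrix(rep(p, each = length(genes)), nrow = length(genes),
                dimnames = list(genes, names(p)))
  mat
}

# joint (trim5, trim3 | D) array from independent per-side profiles
d_trim_array <- function(genes, decay5, decay3, max) {
  p5 <- tgeom(decay5, max); p3 <- tgeom(decay3, max)
  joint <- outer(p5, p3)
  arr <- array(rep(as.vector(joint), each = length(genes)),
               dim = c(length(genes), max + 1L, max + 1L),
               dimnames = list(genes, names(p5), names(p3)))
  arr
}

#' Species preset models and simulator defaults
#'
#' Returns toy recombination models (IGH and IGK) plus simulator parameter
#' defaults for one of two species-like presets. Both presets share a single
#' human-style toy germline set (the transgenic animal the rat-like preset
#' emulates carries human V, D and J segments), so models from different
#' presets are directly comparable by KL divergence. The presets are
#' constructed so that, in expectation, the rat-like preset has: shorter
#' mean CDRH3; shorter V-D and D-J insertions; lower D-family-3 / J-family-6
#' co-usage (0.012 vs 0.028); a lower frequency of 5-aa CDRL3 kappa chains;
#' tissue-dependent IgG fractions (0.15 lymph node, 0.003 spleen) versus a
#' tissue-independent 0.16 for the human-like preset; and roughly half the
#' somatic hypermutation load.
#'
#' @param name `"human_like"` or `"omnirat_like"`.
#' @return list with `name`, `igh_model`, `igk_model` (class `recomb_model`)
#'   and `defaults` (simulator parameters: SHM Poisson means per isotype and
#'   per-tissue IgG fractions).
#' @export
species_preset <- function(name = c("omnirat_like", "human_like")) {
  species_preset_impl(match.arg(name))
}

species_preset_impl <- function(name) {
  igh <- toy_germline_set("human_like", "IGH")
  igk <- toy_germline_set("human_like", "IGK")
  v_genes <- igh$gene[igh$segment == "V"]
  d_genes <- igh$gene[igh$segment == "D"]
  j_genes <- igh$gene[igh$segment == "J"]
  kv_genes <- igk$gene[igk$segment == "V"]
  kj_genes <- igk$gene[igk$segment == "J"]

  if (name == "human_like") {
    p_v <- c(0.10, 0.06, 0.12, 0.04, 0.07, 0.14, 0.09, 0.10, 0.06, 0.08, 0.09, 0.05)
    p_d <- c(0.06, 0.08, 0.13, 0.12, 0.045, 0.052, 0.030, 0.10, 0.08, 0.13, 0.133, 0.04)
    p_j <- c(0.04, 0.04, 0.10, 0.45, 0.15, 0.22)
    v_decay <- 0.78; d_decay <- 0.70; j_decay <- 0.76
    n1 <- tnbinom(4.3, 15); n2 <- tnbinom(4.0, 15)
    init <- c(A = 0.18, C = 0.30, G = 0.34, T = 0.18)
    trans <- rbind(A = c(0.22, 0.28, 0.32, 0.18),
                   C = c(0.18, 0.30, 0.32, 0.20),
                   G = c(0.20, 0.26, 0.34, 0.20),
                   T = c(0.18, 0.28, 0.30, 0.24))
    kp_v <- c(0.11, 0.07, 0.08, 0.12, 0.05, 0.09, 0.06, 0.08, 0.09, 0.13, 0.07, 0.05)
    kp_j <- c(0.28, 0.22, 0.06, 0.32, 0.12)
    kv_decay <- 0.76; kj_decay <- 0.70
    kins <- tgeom(0.55, 8)
    defaults <- list(shm_rate_igm = 5, shm_rate_igg = 18,
                     igg_fraction_by_tissue = c(lymph_node = 0.16, spleen = 0.16,
                                                pooled = 0.16))
  } else {
    p_v <- c(0.05, 0.12, 0.04, 0.09, 0.13, 0.06, 0.05, 0.14, 0.10, 0.05, 0.07, 0.10)
    p_d <- c(0.15, 0.12, 0.02, 0.02, 0.04, 0.06, 0.02, 0.15, 0.10, 0.08, 0.08, 0.16)
    p_j <- c(0.06, 0.06, 0.14, 0.50, 0.14, 0.10)
    v_decay <- 0.72; d_decay <- 0.60; j_decay <- 0.72
    n1 <- tnbinom(1.6, 15); n2 <- tnbinom(1.4, 15)
    init <- c(A = 0.22, C = 0.26, G = 0.28, T = 0.24)
    trans <- rbind(A = c(0.26, 0.24, 0.26, 0.24),
                   C = c(0.22, 0.28, 0.26, 0.24),
                   G = c(0.24, 0.24, 0.28, 0.24),
                   T = c(0.24, 0.24, 0.26, 0.26))
    kp_v <- c(0.06, 0.10, 0.12, 0.08, 0.07, 0.05, 0.09, 0.11, 0.06, 0.08, 0.10, 0.08)
    kp_j <- c(0.30, 0.24, 0.10, 0.26, 0.10)
    kv_decay <- 0.55; kj_decay <- 0.60
    kins <- tgeom(0.45, 8)
    defaults <- list(shm_rate_igm = 2.5, shm_rate_igg = 9,
                     igg_fraction_by_tissue = c(lymph_node = 0.15, spleen = 0.003,
                                                pooled = 0.08))
  }
  colnames(trans) <- NT

  igh_model <- recomb_model(
    locus = "IGH", germline = igh,
    p_v = stats::setNames(p_v, v_genes),
    p_dj = outer(stats::setNames(p_d, d_genes), stats::setNames(p_j, j_genes)),
    p_v_trim = trim_matrix(v_genes, v_decay, 8),
    p_d_trim = d_trim_array(d_genes, d_decay, d_decay, 6),
    p_j_trim = trim_matrix(j_genes, j_decay, 8),
    p_n1 = n1, p_n2 = n2,
    markov_init = init, markov_trans = trans,
    species_tag = name
  )
  igk_model <- recomb_model(
    locus = "IGK", germline = igk,
    p_v = stats::setNames(kp_v, kv_genes),
    p_j = stats::setNames(kp_j, kj_genes),
    p_v_trim = trim_matrix(kv_genes, kv_decay, 12),
    p_j_trim = trim_matrix(kj_genes, kj_decay, 9),
    p_n1 = kins,
    markov_init = init, markov_trans = trans,
    species_tag = name
  )
  list(name = name, igh_model = igh_model, igk_model = igk_model,
       defaults = defaults)
}

# draw from a conditional distribution: probmat has one row per parent level
draw_conditional <- function(idx, probmat) {
  out <- integer(length(idx))
  for (i in unique(idx)) {
    sel <- idx == i
    out[sel] <- sample.int(ncol(probmat), sum(sel), replace = TRUE,
                           prob = probmat[i, ]) - 1L
  }
  out
}

# first-order Markov insertion strings of given lengths
markov_strings <- function(lens, init, trans) {
  n <- length(lens)
  maxl <- max(lens, 0L)
  if (n == 0 || maxl == 0) return(rep("", n))
  chars <- matrix("", n, maxl)
  state <- integer(n)
  active <- which(lens >= 1L)
  state[active] <- sample.int(4, length(active), replace = TRUE, prob = init)
  chars[cbind(active, 1L)] <- NT[state[active]]
  if (maxl >= 2L) {
    for (t in 2:maxl) {
      active <- which(lens >= t)
      if (length(active) == 0) break
      prev <- state  # snapshot: all transitions at step t leave the t-1 state
      for (a in 1:4) {
        sel <- active[prev[active] == a]
        if (length(sel)) {
          state[sel] <- sample.int(4, length(sel), replace = TRUE, prob = trans[a, ])
        }
      }
      chars[cbind(active, t)] <- NT[state[active]]
    }
  }
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

# 2-nt palindromic extension of a coding end (same reverse-complement rule
# for either end: append revcomp(last 2) at 3', prepend revcomp(first 2) at 5')
p_ext <- function(seqs, end = c("3", "5"), on) {
  end <- match.arg(end)
  out <- rep("", length(seqs))
  if (!any(on)) return(out)
  piece <- if (end == "3") {
    substr(seqs[on], nchar(seqs[on]) - 1L, nchar(seqs[on]))
  } else {
    substr(seqs[on], 1L, 2L)
  }
  out[on] <- revcomp(piece)
  out
}

#' Draw rearrangements from a recombination model
#'
#' Samples recombination events from the factorized model, assembles the
#' nucleotide sequence and junction, translates, and flags productivity
#' (in-frame junction starting with CYS, ending with TRP/PHE, no stop).
#' Non-productive draws are kept and flagged, never redrawn. The chosen
#' events (gene calls, trims, insertion lengths and nucleotides) are
#' recorded verbatim on each row, so the returned table carries its own
#' generative ground truth.
#'
#' @param model a normalized `recomb_model` (validated on entry).
#' @param n number of rearrangements.
#' @param seed integer seed; identical `(model, n, seed)` give identical
#'   output.
#' @return tibble of rearrangement records.
#' @export
simulate_rearrangement <- function(model, n = 1, seed = 1) {
  validate_model(model)
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, simulate_events_impl(model, n))
}

simulate_events_impl <- function(model, n) {
  g <- model$germline
  vtab <- g[g$segment == "V", ][match(names(model$p_v), g$gene[g$segment == "V"]), ]
  jtab <- g[g$segment == "J", ]
  jnames <- rownames(model$p_j_trim)
  jtab <- jtab[match(jnames, jtab$gene), ]
  pn <- model$p_nucleotides

  v_idx <- sample.int(nrow(vtab), n, replace = TRUE, prob = model$p_v)
  vt <- draw_conditional(v_idx, model$p_v_trim)
  vseq <- vtab$sequence[v_idx]
  vlen <- nchar(vseq)
  vanch <- vtab$anchor[v_idx]
  v_kept_len <- vlen - vt
  p_v3 <- p_ext(vseq, "3", pn & vt == 0L)

  n1_sup <- length(model$p_n1) - 1L
  n1 <- sample.int(n1_sup + 1L, n, replace = TRUE, prob = model$p_n1) - 1L
  n1_seq <- markov_strings(n1, model$markov_init, model$markov_trans)

  if (model$locus == "IGH") {
    dtab <- g[g$segment == "D", ][match(rownames(model$p_dj), g$gene[g$segment == "D"]), ]
    nD <- nrow(dtab); nJ <- nrow(jtab)
    cell <- sample.int(nD * nJ, n, replace = TRUE, prob = as.vector(model$p_dj))
    d_idx <- (cell - 1L) %% nD + 1L
    j_idx <- (cell - 1L) %/% nD + 1L
    td <- dim(model$p_d_trim)[2]
    dt_cell <- draw_conditional(d_idx, matrix(apply(model$p_d_trim, 1, as.vector),
                                              nrow = nD, byrow = TRUE))
    dt5 <- dt_cell %% td
    dt3 <- dt_cell %/% td
    dseq <- dtab$sequence[d_idx]
    dlen <- nchar(dseq)
    d_kept <- ifelse(dlen - dt3 >= dt5 + 1L,
                     substr(dseq, dt5 + 1L, dlen - dt3), "")
    p_d5 <- p_ext(dseq, "5", pn & dt5 == 0L & d_kept != "")
    p_d3 <- p_ext(dseq, "3", pn & dt3 == 0L & d_kept != "")

    n2_sup <- length(model$p_n2) - 1L
    n2 <- sample.int(n2_sup + 1L, n, replace = TRUE, prob = model$p_n2) - 1L
    n2_seq <- markov_strings(n2, model$markov_init, model$markov_trans)
  } else {
    j_idx <- sample.int(nrow(jtab), n, replace = TRUE, prob = model$p_j)
  }

  jt <- draw_conditional(j_idx, model$p_j_trim)
  jseq <- jtab$sequence[j_idx]
  janch <- jtab$anchor[j_idx]
  p_j5 <- p_ext(jseq, "5", pn & jt == 0L)
  j_junction_part <- substr(jseq, jt + 1L, janch + 2L)
  j_full_part <- substr(jseq, jt + 1L, nchar(jseq))
  v_full_part <- substr(vseq, 1L, v_kept_len)
  v_junction_part <- substr(vseq, vanch, v_kept_len)

  if (model$locus == "IGH") {
    mid_junction <- paste0(n1_seq, p_d5, d_kept, p_d3, n2_seq)
  } else {
    mid_junction <- n1_seq
  }
  junction <- paste0(v_junction_part, p_v3, mid_junction, p_j5, j_junction_part)
  sequence <- paste0(v_full_part, p_v3, mid_junction, p_j5, j_full_part)

  junction_aa <- translate_nt(junction)
  productive <- junction_is_productive(junction_aa)
  cdr3_aa <- ifelse(is.na(junction_aa), NA_character_,
                    substr(junction_aa, 2L, nchar(junction_aa) - 1L))

  rec <- tibble::tibble(
    sequence_id = sprintf("sim-%07d", seq_len(n)),
    subject_id = "sim", species = model$species_tag, tissue = "pooled",
    locus = model$locus,
    v_call = vtab$name[v_idx], v_gene = vtab$gene[v_idx],
    j_call = jtab$name[j_idx], j_gene = jtab$gene[j_idx],
    sequence = sequence, junction = junction,
    junction_start = as.integer(vanch),
    junction_aa = junction_aa, cdr3_aa = cdr3_aa,
    cdr3_length = ifelse(is.na(junction_aa), NA_integer_,
                         nchar(junction_aa) - 2L),
    isotype = "unknown",
    v_mutation_count = 0L,
    n1_sequence = n1_seq,
    v_trim3 = as.integer(vt), j_trim5 = as.integer(jt),
    v_sequence_length = as.integer(v_kept_len),
    duplicate_count = 1L,
    productive = productive,
    clone_id = NA_character_
  )
  if (model$locus == "IGH") {
    rec$d_call <- dtab$name[d_idx]
    rec$d_gene <- dtab$gene[d_idx]
    rec$n1_length <- as.integer(n1)
    rec$n2_length <- as.integer(n2)
    rec$n2_sequence <- n2_seq
    rec$d_trim5 <- as.integer(dt5)
    rec$d_trim3 <- as.integer(dt3)
    rec$vj_insertion_length <- NA_integer_
  } else {
    rec$d_call <- NA_character_
    rec$d_gene <- NA_character_
    rec$n1_length <- NA_integer_
    rec$n2_length <- NA_integer_
    rec$n2_sequence <- NA_character_
    rec$d_trim5 <- NA_integer_
    rec$d_trim3 <- NA_integer_
    rec$vj_insertion_length <- as.integer(n1)
  }
  rec[, intersect(RECORD_COLUMNS, names(rec))]
}

#' Apply somatic hypermutation to records
#'
#' Draws a Poisson(`mean_mutations`) mutation count per record and applies
#' that many point substitutions uniformly at random (without replacement)
#' over the record's retained V-region positions. Counts exceeding the
#' V-region length are capped with a warning. Mutations landing inside the
#' junction part of V re-derive `junction`, `junction_aa`, `cdr3_aa` and
#' `productive`.
#'
#' @param rep a `repertoire` or a record tibble.
#' @param mean_mutations Poisson mean (>= 0), recycled over records.
#' @param seed integer seed.
#' @return object of the same type with mutated records.
#' @export
apply_shm <- function(rep, mean_mutations, seed = 1) {
  stopifnot(all(mean_mutations >= 0))
  recs <- if (inherits(rep, "repertoire")) rep$records else tibble::as_tibble(rep)
  recs <- with_seed(seed, {
    m <- stats::rpois(nrow(recs), mean_mutations)
    mutate_records_impl(recs, m)
  })
  if (inherits(rep, "repertoire")) {
    rep$records <- recs
    rep
  } else {
    recs
  }
}

# deterministic core given mutation counts m (RNG state managed by caller)
mutate_records_impl <- function(recs, m) {
  vlen <- recs$v_sequence_length
  if (any(m > vlen)) {
    warning(sum(m > vlen), " mutation draw(s) exceeded the V-region length; capped")
    m <- pmin(m, vlen)
  }
  recs$v_mutation_count <- as.integer(m)
  idx <- which(m > 0L)
  if (length(idx) == 0) return(recs)
  seqs <- strsplit(recs$sequence[idx], "")
  jstart <- recs$junction_start[idx]
  touched_junction <- logical(length(idx))
  for (k in seq_along(idx)) {
    pos <- sample.int(vlen[idx[k]], m[idx[k]])
    ch <- seqs[[k]]
    shift <- sample.int(3L, length(pos), replace = TRUE)
    ch[pos] <- NT[(match(ch[pos], NT) - 1L + shift) %% 4L + 1L]
    seqs[[k]] <- ch
    touched_junction[k] <- any(pos >= jstart[k])
  }
  recs$sequence[idx] <- vapply(seqs, paste, character(1), collapse = "")
  upd <- idx[touched_junction]
  if (length(upd) > 0) {
    jlen <- nchar(recs$junction[upd])
    recs$junction[upd] <- substr(recs$sequence[upd], recs$junction_start[upd],
                                 recs$junction_start[upd] + jlen - 1L)
    in_frame <- !is.na(recs$junction_aa[upd])
    aa <- rep(NA_character_, length(upd))
    aa[in_frame] <- translate_nt(recs$junction[upd][in_frame])
    recs$junction_aa[upd] <- aa
    recs$cdr3_aa[upd] <- ifelse(is.na(aa), NA_character_,
                                substr(aa, 2L, nchar(aa) - 1L))
    recs$productive[upd] <- junction_is_productive(aa)
  }
  recs
}

#' Simulator configuration
#'
#' Bundles the generative conditions for a two-compartment repertoire
#' simulation. Fields left `NULL` are filled from the species preset.
#'
#' @param species_preset `"omnirat_like"` or `"human_like"`.
#' @param locus `"IGH"` or `"IGK"`.
#' @param n_clones number of distinct founder clones. The default (10,000
#'   clones against 20,000 reads per compartment) keeps rarefaction curves
#'   near the diagonal, matching the low clonotype-recapture regime the
#'   analyses assume.
#' @param n_reads_per_compartment reads sampled per tissue.
#' @param clone_abundance_exponent power-law exponent alpha > 1 of the
#'   clone-size law P(size = k) proportional to k^-alpha.
#' @param clone_size_max truncation of the clone-size support.
#' @param tissue_overlap_prob probability a clone is seeded in both
#'   compartments (otherwise one compartment, chosen fairly).
#' @param shm_rate_igm,shm_rate_igg mean V-region mutation counts (Poisson)
#'   per isotype; the IgM rate is used for kappa reads.
#' @param igg_fraction_by_tissue named vector of per-tissue IgG
#'   probabilities (IGH only).
#' @param p_nucleotides enable palindromic P additions.
#' @param seed root seed; every subsystem draws from a stream derived from
#'   it by fixed offsets.
#' @param subject_id subject label.
#' @param model optional explicit `recomb_model` overriding the preset.
#' @return list of class `simulator_config`.
#' @export
simulator_config <- function(species_preset = "omnirat_like", locus = "IGH",
                             n_clones = 10000, n_reads_per_compartment = 20000,
                             clone_abundance_exponent = 2.0,
                             clone_size_max = 10000,
                             tissue_overlap_prob = 0.5,
                             shm_rate_igm = NULL, shm_rate_igg = NULL,
                             igg_fraction_by_tissue = NULL,
                             p_nucleotides = TRUE, seed = 1,
                             subject_id = "S1", model = NULL) {
  preset <- species_preset_impl(match.arg(species_preset,
                                          c("omnirat_like", "human_like")))
  cfg <- list(
    species_preset = preset$name, locus = locus,
    n_clones = as.integer(n_clones),
    n_reads_per_compartment = as.integer(n_reads_per_compartment),
    clone_abundance_exponent = clone_abundance_exponent,
    clone_size_max = as.integer(clone_size_max),
    tissue_overlap_prob = tissue_overlap_prob,
    shm_rate_igm = shm_rate_igm %||% preset$defaults$shm_rate_igm,
    shm_rate_igg = shm_rate_igg %||% preset$defaults$shm_rate_igg,
    igg_fraction_by_tissue = igg_fraction_by_tissue %||%
      preset$defaults$igg_fraction_by_tissue,
    p_nucleotides = p_nucleotides,
    seed = as.integer(seed), subject_id = subject_id,
    model = model %||% (if (locus == "IGH") preset$igh_model else preset$igk_model)
  )
  stopifnot(cfg$n_clones > 0, cfg$n_reads_per_compartment > 0,
            cfg$clone_abundance_exponent > 1,
            cfg$tissue_overlap_prob >= 0, cfg$tissue_overlap_prob <= 1,
            all(cfg$igg_fraction_by_tissue >= 0),
            all(cfg$igg_fraction_by_tissue <= 1),
            cfg$shm_rate_igm >= 0, cfg$shm_rate_igg >= 0)
  structure(cfg, class = "simulator_config")
}

#' Simulate a two-compartment repertoire with ground truth
#'
#' Creates `n_clones` independent productive founder rearrangements (clones;
#' non-productive founder draws are rejected so that the truth set defines a
#' clean expressed richness), seeds each clone into one or both tissue
#' compartments, draws clone sizes from a truncated power law, samples reads
#' per compartment proportionally to clone size, and applies per-read
#' isotype assignment and somatic hypermutation. Fully reproducible from the
#' config's root seed.
#'
#' @param config a [simulator_config()].
#' @return list with `lymph_node` and `spleen` (class `repertoire`) and
#'   `truth` (founder clone table, the generating `recomb_model`, and the
#'   config).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "simulator_config"))
  model <- config$model
  model$p_nucleotides <- config$p_nucleotides
  seed <- config$seed

  # founder clones, conditioned on productivity by rejection
  founders <- with_seed(sub_seed(seed, 1), {
    acc <- NULL
    need <- config$n_clones
    while (need > 0) {
      batch <- simulate_events_impl(model, max(200L, ceiling(need * 3.2)))
      batch <- batch[batch$productive, ]
      acc <- if (is.null(acc)) batch else dplyr::bind_rows(acc, batch)
      need <- config$n_clones - nrow(acc)
    }
    acc[seq_len(config$n_clones), ]
  })
  founders$clone_id <- sprintf("%s-C%06d", config$subject_id, seq_len(config$n_clones))

  sizes <- with_seed(sub_seed(seed, 2), {
    k <- seq_len(config$clone_size_max)
    sample(k, config$n_clones, replace = TRUE,
           prob = k^(-config$clone_abundance_exponent))
  })
  placement <- with_seed(sub_seed(seed, 3), {
    u <- stats::runif(config$n_clones)
    both <- u < config$tissue_overlap_prob
    side <- stats::runif(config$n_clones) < 0.5
    tibble::tibble(in_ln = both | side, in_sp = both | !side)
  })

  sample_compartment <- function(tissue, present, stream) {
    reads <- with_seed(sub_seed(seed, stream), {
      pool <- which(present)
      read_clone <- sample(pool, config$n_reads_per_compartment, replace = TRUE,
                           prob = sizes[pool])
      recs <- founders[read_clone, ]
      recs$tissue <- tissue
      recs$subject_id <- config$subject_id
      recs$sequence_id <- sprintf("%s-%s-%07d", config$subject_id,
                                  substr(tissue, 1, 2),
                                  seq_len(config$n_reads_per_compartment))
      if (config$locus == "IGH") {
        igg_p <- config$igg_fraction_by_tissue[[tissue]]
        is_igg <- stats::runif(nrow(recs)) < igg_p
        recs$isotype <- ifelse(is_igg, "IgG", "IgM")
        rate <- ifelse(is_igg, config$shm_rate_igg, config$shm_rate_igm)
      } else {
        recs$isotype <- "unknown"
        rate <- rep(config$shm_rate_igm, nrow(recs))
      }
      m <- stats::rpois(nrow(recs), rate)
      mutate_records_impl(recs, m)
    })
    repertoire(reads, subject_id = config$subject_id, tissue = tissue,
               locus = config$locus, species = model$species_tag,
               germline = model$germline)
  }

  ln <- sample_compartment("lymph_node", placement$in_ln, 4)
  sp <- sample_compartment("spleen", placement$in_sp, 5)

  truth <- list(
    clones = tibble::tibble(
      clone_id = founders$clone_id,
      v_gene = founders$v_gene,
      j_gene = founders$j_gene,
      cdr3_aa = founders$cdr3_aa,
      cdr3_length = founders$cdr3_length,
      size = sizes,
      in_lymph_node = placement$in_ln,
      in_spleen = placement$in_sp
    ),
    model = model,
    config = config
  )
  list(lymph_node = ln, spleen = sp, truth = truth)
}
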