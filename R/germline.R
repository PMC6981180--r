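# Germline gene sets: packaged toy sets, FASTA input, segment-length summaries.
#
# A germline set is a tibble with one row per gene:
#   name (with allele, e.g. "IGHV4-34*01"), gene (allele-stripped), family,
#   segment (V/D/J), locus (IGH/IGK), sequence, species_tag, anchor.
# `anchor` is the 1-based start of the conserved junction-anchor codon: the
# second-CYS codon for V genes, the J-TRP (IGH) or J-PHE (IGK) codon for J
# genes; NA for D genes.

V_AFTER_CYS <- c(IGH = 12L, IGK = 21L)  # nt from anchor-codon start to V end
J_PRE_ANCHOR_TAIL <- list(
  IGH = "GGCCAAGGGACCACGGTCACCGTCTCCTCAG",  # FR4 beyond the J-TRP codon
  IGK = "GGCCAAGGGACCAAGGTGGAAATCAAAC"
)

new_germline_set <- function(name, sequence, segment, locus, species_tag, anchor = NA_integer_) {
  gs <- tibble::tibble(
    name = name,
    gene = strip_allele(name),
    family = gene_family(name),
    segment = segment,
    locus = locus,
    sequence = toupper(sequence),
    species_tag = species_tag,
    anchor = as.integer(anchor)
  )
  validate_germline_set(gs)
  gs
}

validate_germline_set <- function(gs) {
  stopifnot(all(gs$segment %in% c("V", "D", "J")), all(gs$locus %in% c("IGH", "IGK")))
  if (any(gs$segment == "D" & gs$locus == "IGK")) {
    stop("kappa locus has no D segment")
  }
  bad <- !grepl("^[ACGT]+$", gs$sequence)
  if (any(bad)) stop("non-ACGT or empty sequence for: ", paste(gs$name[bad], collapse = ", "))
  if (anyDuplicated(gs$name)) {
    stop("duplicate gene names: ",
         paste(unique(gs$name[duplicated(gs$name)]), collapse = ", "))
  }
  stopifnot(all(startsWith(gs$gene, gs$family)))
  invisible(gs)
}

# deterministic pseudo-random nucleotide core with mild GC bias
random_core <- function(n_genes, lengths, seed) {
  with_seed(seed, lapply(seq_len(n_genes), function(i) {
    paste(sample(NT, lengths[i], replace = TRUE, prob = c(0.22, 0.28, 0.30, 0.20)),
          collapse = "")
  }))
}

#' Packaged toy germline gene sets
#'
#' Deterministically constructed synthetic germline sets used by the species
#' presets and shipped as FASTA under `inst/extdata/germline`. The
#' `human_like` collection covers IGHV/IGHD/IGHJ and IGKV/IGKJ (both heavy
#' chain presets share it, mirroring a transgenic animal carrying human
#' V/D/J segments); `rat_like` provides only an IGHD set with shorter genes,
#' for germline D-segment length comparisons against the human-like set.
#'
#' D gene lengths follow the human IMGT genes they are named after
#' (11-31 nt, mean about 23.6); the rat-like D set spans 8-20 nt (mean about
#' 14). V genes end in a second-CYS codon followed by a short CDR3 stub; J
#' genes carry a 5' overhang, the conserved TRP/PHE codon and a fixed FR4.
#'
#' @param collection `"human_like"` or `"rat_like"`.
#' @param locus `"IGH"` or `"IGK"`.
#' @param segment optional filter: `"V"`, `"D"` or `"J"`.
#' @return a germline-set tibble (one row per gene).
#' @export
toy_germline_set <- function(collection = c("human_like", "rat_like"),
                             locus = c("IGH", "IGK"),
                             segment = NULL) {
  collection <- match.arg(collection)
  locus <- match.arg(locus)
  gs <- if (collection == "rat_like") {
    if (locus != "IGH") stop("rat_like collection provides IGH D genes only")
    toy_rat_d_set()
  } else if (locus == "IGH") {
    dplyr::bind_rows(toy_ighv_set(), toy_ighd_set(), toy_ighj_set())
  } else {
    dplyr::bind_rows(toy_igkv_set(), toy_igkj_set())
  }
  if (!is.null(segment)) gs <- gs[gs$segment == segment, ]
  gs
}

toy_ighv_set <- function() {
  names <- c("IGHV1-2*01", "IGHV1-18*01", "IGHV1-69*01", "IGHV2-5*01",
             "IGHV3-7*01", "IGHV3-23*01", "IGHV3-30*01", "IGHV4-34*01",
             "IGHV4-39*01", "IGHV4-59*01", "IGHV5-51*01", "IGHV6-1*01")
  core_len <- c(282L, 285L, 288L, 279L, 282L, 285L, 282L, 288L, 285L, 282L, 279L, 288L)
  # 3 stop-free codons after the CYS codon (CDR3 stub, e.g. "ARD")
  tails <- c("GCGAGAGAT", "GCGAGAGGT", "GCGAAAGAT", "GCCAGAGAC",
             "GCGAAAGAC", "GCGAGAGAC", "GCGAGGGAT", "GCGAGAGTT",
             "GCAAGAGAT", "GCGAGAGCT", "GCGACAGAT", "GCAAGAGGT")
  cores <- random_core(12, core_len, seed = 20101)
  seqs <- paste0(unlist(cores), "TGT", tails)
  new_germline_set(names, seqs, "V", "IGH", "human_like",
                   anchor = core_len + 1L)
}

toy_ighd_set <- function() {
  names <- c("IGHD1-1*01", "IGHD1-26*01", "IGHD2-2*01", "IGHD2-15*01",
             "IGHD3-3*01", "IGHD3-10*01", "IGHD3-22*01", "IGHD4-17*01",
             "IGHD4-23*01", "IGHD5-12*01", "IGHD6-19*01", "IGHD7-27*01")
  lens <- c(17L, 20L, 31L, 31L, 31L, 31L, 28L, 16L, 19L, 23L, 21L, 11L)
  seqs <- unlist(random_core(12, lens, seed = 20102))
  new_germline_set(names, seqs, "D", "IGH", "human_like")
}

toy_rat_d_set <- function() {
  names <- c("IGHD1-1*01", "IGHD1-26*01", "IGHD2-2*01", "IGHD2-15*01",
             "IGHD3-3*01", "IGHD3-10*01", "IGHD3-22*01", "IGHD4-17*01",
             "IGHD4-23*01", "IGHD5-12*01", "IGHD6-19*01", "IGHD7-27*01")
  lens <- c(12L, 13L, 17L, 16L, 18L, 17L, 16L, 10L, 12L, 14L, 13L, 8L)
  seqs <- unlist(random_core(12, lens, seed = 20103))
  new_germline_set(names, seqs, "D", "IGH", "rat_like")
}

toy_ighj_set <- function() {
  names <- paste0("IGHJ", 1:6, "*01")
  pre <- c(9L, 9L, 9L, 9L, 12L, 15L)  # 5' overhang before the TRP codon
  overhangs <- unlist(random_core(6, pre, seed = 20104))
  seqs <- paste0(overhangs, "TGG", J_PRE_ANCHOR_TAIL$IGH)
  new_germline_set(names, seqs, "J", "IGH", "human_like", anchor = pre + 1L)
}

toy_igkv_set <- function() {
  names <- c("IGKV1-5*01", "IGKV1-9*01", "IGKV1-33*01", "IGKV1-39*01",
             "IGKV2-24*01", "IGKV2-28*01", "IGKV2-30*01", "IGKV3-11*01",
             "IGKV3-15*01", "IGKV3-20*01", "IGKV4-1*01", "IGKV5-2*01")
  core_len <- c(270L, 273L, 270L, 276L, 279L, 276L, 273L, 270L, 276L, 273L, 282L, 270L)
  # 6 stop-free codons after CYS (e.g. "QQYNSY"), kappa CDR3 stubs
  tails <- c("CAACAGTATAATAGTTAT", "CAACAGTATGATAATCTT", "CAACAGTATGATAATTTA",
             "CAACAGAGTTACAGTACT", "CAACAATATAATAGTTAC", "ATGCAAGCTCTACAAACT",
             "ATGCAAGGTACACACTGG", "CAGCAGCGTAGCAACTGG", "CAGCAGTATAATAACTGG",
             "CAGCAGTATGGTAGCTCA", "CAGCAATATTATAGTACT", "CAACAGTATAGTAGTTCT")
  cores <- random_core(12, core_len, seed = 20105)
  seqs <- paste0(unlist(cores), "TGT", tails)
  new_germline_set(names, seqs, "V", "IGK", "human_like",
                   anchor = core_len + 1L)
}

toy_igkj_set <- function() {
  names <- paste0("IGKJ", 1:5, "*01")
  pre <- c(12L, 12L, 12L, 12L, 12L)  # 5' overhang before the PHE codon
  overhangs <- unlist(random_core(5, pre, seed = 20106))
  seqs <- paste0(overhangs, "TTC", J_PRE_ANCHOR_TAIL$IGK)
  new_germline_set(names, seqs, "J", "IGK", "human_like", anchor = pre + 1L)
}

#' Read a germline gene set from FASTA
#'
#' Headers are parsed IMGT-style: when the header contains pipe characters
#' the gene name is the second pipe-delimited token, otherwise the first
#' whitespace-delimited word. Anchor codons (second-CYS for V, J-TRP/J-PHE
#' for J) are located heuristically; genes whose anchor cannot be found get
#' `NA` (they can still be used for length statistics, but not for
#' simulation).
#'
#' @param path FASTA file.
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param locus `"IGH"` or `"IGK"`.
#' @param species_tag free-text label attached to every gene.
#' @return a germline-set tibble.
#' @export
read_germline_fasta <- function(path, segment = c("V", "D", "J"),
                                locus = c("IGH", "IGK"),
                                species_tag = "unknown") {
  segment <- match.arg(segment)
  locus <- match.arg(locus)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  name <- ifelse(
    grepl("|", headers, fixed = TRUE),
    vapply(strsplit(headers, "|", fixed = TRUE), function(x) x[2], character(1)),
    vapply(strsplit(headers, "\\s+"), function(x) x[1], character(1))
  )
  if (anyDuplicated(name)) {
    stop("duplicate gene names in FASTA: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  seqs <- unname(toupper(as.character(set)))
  anchor <- rep(NA_integer_, length(seqs))
  if (segment == "V") anchor <- vapply(seqs, find_v_anchor, integer(1), USE.NAMES = FALSE)
  if (segment == "J") anchor <- vapply(seqs, find_j_anchor, integer(1), locus = locus, USE.NAMES = FALSE)
  new_germline_set(name, seqs, segment, locus, species_tag, anchor)
}

# last in-frame TGT/TGC (frame anchored at the 3' end of the V region)
# with at least two codons following it
find_v_anchor <- function(seq) {
  m <- gregexpr("(?=TG[TC])", seq, perl = TRUE)[[1]]  # overlap-aware
  m <- m[m > 0 & (nchar(seq) - m - 2) >= 6 & (nchar(seq) - m + 1) %% 3 == 0]
  if (length(m) == 0) return(NA_integer_)
  as.integer(m[length(m)])
}

# last TRP (IGH) / PHE (IGK) codon opening the FR4 glycine run
find_j_anchor <- function(seq, locus) {
  pat <- if (locus == "IGH") "(?=TGGGG)" else "(?=TT[TC]GG)"
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] < 0) NA_integer_ else as.integer(m[length(m)])
}

#' Write a germline set to FASTA
#'
#' @param gs germline-set tibble.
#' @param path output file.
#' @export
write_germline_fasta <- function(gs, path) {
  validate_germline_set(gs)
  lines <- as.vector(rbind(paste0(">", gs$name), gs$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Mean germline segment length
#'
#' Arithmetic mean and standard error of the nucleotide lengths of a set of
#' germline genes of a single segment type (e.g. all D genes of a species).
#'
#' @param gs germline-set tibble containing a single segment type.
#' @return list with `mean`, `sem` and `n`.
#' @export
mean_segment_length <- function(gs) {
  if (nrow(gs) == 0) stop("empty germline set")
  if (length(unique(gs$segment)) != 1) {
    stop("mixed segment types: ", paste(unique(gs$segment), collapse = ", "))
  }
  len <- nchar(gs$sequence)
  m <- mean(len)
  sem <- if (length(len) > 1) stats::sd(len) / sqrt(length(len)) else 0
  list(mean = m, sem = sem, n = length(len))
}
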