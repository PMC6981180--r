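# AIRR rearrangement TSV input/output.
#
# The dialect uses AIRR-C v1 column names where they exist (sequence_id,
# sequence, v_call, d_call, j_call, junction, junction_aa, productive,
# duplicate_count, locus) and carries the remaining fields (tissue, isotype,
# n1_length, trims, ...) as custom columns. Column order is fixed by
# RECORD_COLUMNS and is lossless for every canonical field.

#' Read an AIRR rearrangement TSV
#'
#' Reads a tab-separated rearrangement table, derives allele-stripped gene
#' columns (`v_gene`, `d_gene`, `j_gene`) and CDR3 fields from
#' `junction_aa`, applies the record invariants and drops failing rows.
#' Dropped rows are tallied by reason in the returned repertoire's
#' `$rejections` table; accepted + rejected always equals the input row
#' count.
#'
#' @param path TSV file with a header row containing at least
#'   `sequence_id`, `v_call`, `j_call`, `junction_aa`.
#' @param locus `"IGH"` or `"IGK"`.
#' @param subject_id,tissue,species label fields; when the file carries
#'   `subject_id`/`tissue` columns those win.
#' @param germline optional germline-set tibble to attach.
#' @return a `repertoire`.
#' @export
read_airr <- function(path, locus = c("IGH", "IGK"), subject_id = NULL,
                      tissue = NULL, species = "unknown", germline = NULL) {
  locus <- match.arg(locus)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA"))
  required <- c("sequence_id", "v_call", "j_call", "junction_aa")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("empty rearrangement file: ", path)
    return(repertoire(tab, subject_id = subject_id %||% "S1",
                      tissue = tissue %||% "pooled", locus = locus,
                      species = species, germline = germline))
  }
  for (col in intersect(RECORD_INT_COLUMNS, names(tab))) {
    tab[[col]] <- suppressWarnings(as.integer(tab[[col]]))
  }
  if (!"duplicate_count" %in% names(tab)) tab$duplicate_count <- 1L
  if ("productive" %in% names(tab)) {
    tab$productive <- toupper(tab$productive) %in% c("T", "TRUE")
  }
  tab$v_gene <- strip_allele(tab$v_call)
  tab$j_gene <- strip_allele(tab$j_call)
  tab$d_gene <- if ("d_call" %in% names(tab)) strip_allele(tab$d_call) else NA_character_
  has_junc <- !is.na(tab$junction_aa) & nchar(tab$junction_aa) > 0
  if (!"cdr3_aa" %in% names(tab)) tab$cdr3_aa <- NA_character_
  if (!"cdr3_length" %in% names(tab)) tab$cdr3_length <- NA_integer_
  derive <- has_junc & is.na(tab$cdr3_aa)
  tab$cdr3_aa[derive] <- substr(tab$junction_aa[derive], 2,
                                nchar(tab$junction_aa[derive]) - 1L)
  tab$cdr3_length[has_junc & is.na(tab$cdr3_length)] <-
    nchar(tab$junction_aa[has_junc & is.na(tab$cdr3_length)]) - 2L
  if (!"productive" %in% names(tab) || all(is.na(tab$productive))) {
    tab$productive <- junction_is_productive(tab$junction_aa)
  }

  # empty insertion strings are written as "" and must not collapse into NA:
  # a zero-length insertion has an empty sequence by definition
  len1 <- if ("n1_length" %in% names(tab) && !all(is.na(tab$n1_length))) {
    tab$n1_length
  } else if ("vj_insertion_length" %in% names(tab)) {
    tab$vj_insertion_length
  }
  if ("n1_sequence" %in% names(tab) && !is.null(len1)) {
    tab$n1_sequence[is.na(tab$n1_sequence) & !is.na(len1) & len1 == 0] <- ""
  }
  if (all(c("n2_sequence", "n2_length") %in% names(tab))) {
    tab$n2_sequence[is.na(tab$n2_sequence) & !is.na(tab$n2_length) &
                      tab$n2_length == 0] <- ""
  }

  reason <- record_invariant_failures(tab)
  kept <- tab[is.na(reason), ]
  tb <- table(reason[!is.na(reason)])
  rejections <- tibble::tibble(reason = names(tb), n = as.integer(tb))
  subject_id <- subject_id %||%
    (if ("subject_id" %in% names(kept) && nrow(kept) > 0 && !is.na(kept$subject_id[1]))
       kept$subject_id[1] else "S1")
  tissue <- tissue %||%
    (if ("tissue" %in% names(kept) && nrow(kept) > 0 && !is.na(kept$tissue[1]))
       kept$tissue[1] else "pooled")
  repertoire(kept, subject_id = subject_id, tissue = tissue, locus = locus,
             species = species, germline = germline, rejections = rejections)
}

#' Write a repertoire as an AIRR rearrangement TSV
#'
#' One row per record, canonical column order, header always written (an
#' empty repertoire produces a header-only file). Field-level lossless
#' against [read_airr()].
#'
#' @param rep a `repertoire`.
#' @param path output file.
#' @export
write_airr <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  out <- rep$records[, RECORD_COLUMNS]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
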