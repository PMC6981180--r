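# The repertoire container: an ordered table of annotated rearrangement
# records plus a (subject, tissue, locus) label and a germline reference.

# Canonical record columns, in file order. Numeric/integer/logical columns
# are typed on read; everything else is character.
RECORD_COLUMNS <- c(
  "sequence_id", "subject_id", "species", "tissue", "locus",
  "v_call", "d_call", "j_call", "v_gene", "d_gene", "j_gene",
  "sequence", "junction", "junction_start", "junction_aa", "cdr3_aa",
  "cdr3_length", "isotype", "v_mutation_count",
  "n1_length", "n1_sequence", "n2_length", "n2_sequence",
  "vj_insertion_length", "v_trim3", "d_trim5", "d_trim3", "j_trim5",
  "v_sequence_length", "duplicate_count", "productive", "clone_id"
)
RECORD_INT_COLUMNS <- c(
  "junction_start", "cdr3_length", "v_mutation_count", "n1_length",
  "n2_length", "vj_insertion_length", "v_trim3", "d_trim5", "d_trim3",
  "j_trim5", "v_sequence_length", "duplicate_count"
)

#' Construct a repertoire
#'
#' A repertoire bundles an ordered tibble of rearrangement records with a
#' `(subject_id, tissue, locus)` label and, optionally, the germline gene
#' set the records were annotated (or simulated) against.
#'
#' @param records tibble of rearrangement records; missing canonical columns
#'   are added as `NA`, extra columns are kept.
#' @param subject_id,tissue,locus,species label fields; `tissue` is one of
#'   `"lymph_node"`, `"spleen"`, `"pooled"`.
#' @param germline optional germline-set tibble.
#' @param rejections optional tibble describing records dropped upstream.
#' @return an object of class `repertoire`.
#' @export
repertoire <- function(records, subject_id = "S1", tissue = "pooled",
                       locus = c("IGH", "IGK"), species = "unknown",
                       germline = NULL, rejections = NULL) {
  locus <- match.arg(locus)
  stopifnot(tissue %in% c("lymph_node", "spleen", "pooled"))
  records <- tibble::as_tibble(records)
  for (col in setdiff(RECORD_COLUMNS, names(records))) {
    records[[col]] <- if (col %in% RECORD_INT_COLUMNS) {
      NA_integer_
    } else if (col == "productive") NA else NA_character_
  }
  records <- records[, c(RECORD_COLUMNS, setdiff(names(records), RECORD_COLUMNS))]
  if (nrow(records) > 0) {
    records$subject_id <- subject_id
    records$tissue <- tissue
    records$locus <- locus
    if (is.na(records$duplicate_count[1])) records$duplicate_count <- 1L
  }
  structure(
    list(records = records, subject_id = subject_id, tissue = tissue,
         locus = locus, species = species, germline = germline,
         rejections = rejections %||%
           tibble::tibble(reason = character(), n = integer())),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s / %s / %s: %d records (%d productive), %d rejected on ingest\n",
              x$subject_id, x$tissue, x$locus, nrow(x$records),
              sum(x$records$productive, na.rm = TRUE),
              sum(x$rejections$n)))
  invisible(x)
}

#' Number of records in a repertoire
#' @param rep a `repertoire`.
#' @param productive_only count productive records only.
#' @export
n_records <- function(rep, productive_only = FALSE) {
  if (productive_only) sum(rep$records$productive, na.rm = TRUE) else nrow(rep$records)
}

# Productive subset of the record table (the default view of every
# statistics operation; the paper's repertoires are expressed productive
# rearrangements).
productive_records <- function(rep, productive_only = TRUE) {
  recs <- if (inherits(rep, "repertoire")) rep$records else tibble::as_tibble(rep)
  if (productive_only) recs <- recs[!is.na(recs$productive) & recs$productive, ]
  recs
}

rep_locus <- function(rep) {
  if (inherits(rep, "repertoire")) rep$locus else unique(rep$locus)[1]
}

# Row-level invariant checks used by read_airr; returns a character reason
# per row (NA = valid).
record_invariant_failures <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  has_junc <- !is.na(records$junction_aa) & nchar(records$junction_aa) > 0
  reason[!has_junc] <- "missing junction_aa"
  num <- records[, intersect(RECORD_INT_COLUMNS, names(records))]
  neg <- rowSums(!is.na(num) & num < 0) > 0
  reason[is.na(reason) & neg] <- "negative length/trim field"
  dup_bad <- !is.na(records$duplicate_count) & records$duplicate_count < 1
  reason[is.na(reason) & dup_bad] <- "duplicate_count < 1"
  cdr3_bad <- has_junc & !is.na(records$cdr3_length) &
    records$cdr3_length != nchar(records$junction_aa) - 2L
  reason[is.na(reason) & cdr3_bad] <- "cdr3_length inconsistent with junction_aa"
  prod_bad <- has_junc & !is.na(records$productive) & records$productive &
    !junction_is_productive(records$junction_aa)
  reason[is.na(reason) & prod_bad] <- "productive record with invalid junction"
  reason
}

# IMGT-style productive junction: starts with the second-CYS, ends with
# J-TRP or J-PHE, no internal stop.
junction_is_productive <- function(junction_aa) {
  !is.na(junction_aa) &
    nchar(junction_aa) >= 4 &
    startsWith(junction_aa, "C") &
    substr(junction_aa, nchar(junction_aa), nchar(junction_aa)) %in% c("W", "F") &
    !grepl("*", junction_aa, fixed = TRUE)
}
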