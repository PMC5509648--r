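# In-memory repertoire store.
#
# Records live in a data.table; a lazily built (triplet, offset)
# inverted index supports the seed-and-extend stages of the search.
# Restriction to a motif's match set produces a child store that keeps
# the PARENT's category denominators |A| and |B|: thresholds and
# separation scores are always denominated in the original cohort.

.AIRR_REQUIRED <- c("sequence_id", "subject_id", "diagnosis",
                    "sequence_aa", "cdr3_start", "cdr3_end")

#' Build a validated, indexed repertoire store
#'
#' Validates records, drops (and counts) those violating the invariants
#' — sequences with characters outside the 20 standard residues, or CDR3
#' coordinates not satisfying `0 <= cdr3_start < cdr3_end <=
#' nchar(sequence_aa)` — and categorizes subjects: category A if the
#' subject's diagnosis is in `category_a_diagnoses`, category B
#' otherwise.
#'
#' @param records A data.frame with columns `sequence_id`, `subject_id`,
#'   `diagnosis`, `sequence_aa`, `cdr3_start`, `cdr3_end` (0-based,
#'   half-open) and optionally `v_call`, `j_call`; extra columns are
#'   ignored.
#' @param category_a_diagnoses Character vector of diagnosis labels
#'   assigned to category A (the case/disease category).
#' @return A `haystack_store` with elements `records`, `subjects`,
#'   `size_a`, `size_b`, `n_dropped`, `drop_reasons`.
#' @export
repertoire_store <- function(records, category_a_diagnoses) {
  records <- as.data.table(records)
  missing_cols <- setdiff(.AIRR_REQUIRED, names(records))
  if (length(missing_cols)) {
    .data_error(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!is.character(category_a_diagnoses) || length(category_a_diagnoses) == 0L) {
    .data_error("category_a_diagnoses must be a non-empty character vector")
  }
  keep_cols <- c(.AIRR_REQUIRED, intersect(c("v_call", "j_call"), names(records)))
  recs <- records[, keep_cols, with = FALSE]
  recs[, `:=`(sequence_id = as.character(sequence_id),
              subject_id = as.character(subject_id),
              diagnosis = as.character(diagnosis),
              sequence_aa = as.character(sequence_aa),
              cdr3_start = suppressWarnings(as.integer(cdr3_start)),
              cdr3_end = suppressWarnings(as.integer(cdr3_end)))]

  aa_ok <- grepl(sprintf("^[%s]+$", paste(amino_acids(), collapse = "")),
                 recs$sequence_aa)
  aa_ok[is.na(aa_ok)] <- FALSE
  co_ok <- !is.na(recs$cdr3_start) & !is.na(recs$cdr3_end) &
    recs$cdr3_start >= 0L & recs$cdr3_start < recs$cdr3_end &
    recs$cdr3_end <= nchar(recs$sequence_aa)
  co_ok[is.na(co_ok)] <- FALSE
  drop_reasons <- c(invalid_residue = sum(!aa_ok),
                    invalid_cdr3 = sum(aa_ok & !co_ok))
  valid <- aa_ok & co_ok
  recs <- recs[valid]
  if (nrow(recs) == 0L) .data_error("no valid records after validation")

  recs[, category := ifelse(diagnosis %chin% category_a_diagnoses, "A", "B")]
  subjects <- unique(recs[, .(subject_id, diagnosis, category)],
                     by = "subject_id")
  setkey(subjects, subject_id)

  structure(list(
    records = recs,
    subjects = subjects,
    size_a = sum(subjects$category == "A"),
    size_b = sum(subjects$category == "B"),
    n_dropped = sum(!valid),
    drop_reasons = drop_reasons,
    category_a_diagnoses = category_a_diagnoses,
    index = new.env(parent = emptyenv())
  ), class = "haystack_store")
}

#' Load an AIRR-style rearrangement TSV
#'
#' Reads a UTF-8 tab-separated table with a header row and the required
#' columns `sequence_id`, `subject_id`, `diagnosis`, `sequence_aa`,
#' `cdr3_start`, `cdr3_end` (CDR3 columns 0-based, half-open); extra
#' columns are ignored.
#'
#' @param path Path to the TSV file.
#' @inheritParams repertoire_store
#' @return A `haystack_store`; see [repertoire_store()].
#' @export
load_airr <- function(path, category_a_diagnoses) {
  if (!file.exists(path)) .data_error(sprintf("input file not found: %s", path))
  dt <- fread(path, sep = "\t", header = TRUE)
  repertoire_store(dt, category_a_diagnoses)
}

#' Load a repertoire from FASTA plus metadata tables
#'
#' Secondary input path: amino-acid sequences come from a FASTA file
#' (record id = first header token), CDR3 coordinates from an annotation
#' TSV (`sequence_id`, `subject_id`, `cdr3_start`, `cdr3_end`), and
#' diagnoses from a subject metadata TSV (`subject_id`, `diagnosis`).
#'
#' @param fasta Path to the amino-acid FASTA file.
#' @param annotation Path to the annotation TSV.
#' @param metadata Path to the subject metadata TSV.
#' @inheritParams repertoire_store
#' @return A `haystack_store`.
#' @export
load_fasta <- function(fasta, annotation, metadata, category_a_diagnoses) {
  for (p in c(fasta, annotation, metadata)) {
    if (!file.exists(p)) .data_error(sprintf("input file not found: %s", p))
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readAAStringSet(fasta)
    ids <- sub("\\s.*$", "", names(seqs))
    seq_dt <- data.table(sequence_id = ids, sequence_aa = as.character(seqs))
  } else {
    seq_dt <- .read_fasta_plain(fasta)
  }
  ann <- fread(annotation, sep = "\t", header = TRUE,
               colClasses = list(character = c("sequence_id", "subject_id")))
  for (col in c("sequence_id", "subject_id", "cdr3_start", "cdr3_end")) {
    if (!col %in% names(ann)) {
      .data_error(sprintf("missing required column(s): %s", col))
    }
  }
  meta <- fread(metadata, sep = "\t", header = TRUE,
                colClasses = list(character = "subject_id"))
  for (col in c("subject_id", "diagnosis")) {
    if (!col %in% names(meta)) {
      .data_error(sprintf("missing required column(s): %s", col))
    }
  }
  recs <- merge(merge(seq_dt, ann, by = "sequence_id"),
                meta[, .(subject_id, diagnosis)], by = "subject_id")
  repertoire_store(recs, category_a_diagnoses)
}

# Minimal FASTA reader used only when Biostrings is unavailable.
.read_fasta_plain <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) .data_error(sprintf("no FASTA records in %s", path))
  grp <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, collapse = "",
                 FUN.VALUE = "")
  data.table(sequence_id = ids, sequence_aa = unname(seqs))
}

#' @export
print.haystack_store <- function(x, ...) {
  cat("<repertoire store> ", nrow(x$records), " records, ",
      nrow(x$subjects), " subjects (|A| = ", x$size_a, ", |B| = ", x$size_b,
      "), ", x$n_dropped, " dropped at load\n", sep = "")
  invisible(x)
}

# Lazily built inverted index: one row per triplet occurrence, columns
# triplet / offset / ri (row in records) / subject_id / category.
.triplet_index <- function(store) {
  if (!is.null(store$index$triplets)) return(store$index$triplets)
  recs <- store$records
  lens <- nchar(recs$sequence_aa)
  n3 <- pmax(lens - 2L, 0L)
  ri <- rep.int(seq_len(nrow(recs)), n3)
  posj <- sequence(n3)                       # 1-based triplet start
  idx <- data.table(
    triplet = substring(recs$sequence_aa[ri], posj, posj + 2L),
    offset = recs$cdr3_start[ri] - (posj - 1L),
    ri = ri,
    subject_id = recs$subject_id[ri],
    category = recs$category[ri]
  )
  store$index$triplets <- idx
  idx
}

#' Query a motif against a repertoire store
#'
#' Matches the motif against every record and aggregates the hits by
#' distinct subject: `a` counts matched category-A subjects, `b` matched
#' category-B subjects, and `separation = a - b`.
#'
#' @param store A `haystack_store`.
#' @param m A [motif()] or a parenthesis-notation string.
#' @return A `haystack_match` with elements `motif`,
#'   `matched_record_ids`, `matched_subjects_a`, `matched_subjects_b`,
#'   `a`, `b`, `separation`.
#' @export
query_motif <- function(store, m) {
  stopifnot(inherits(store, "haystack_store"))
  m <- .as_motif(m)
  recs <- store$records
  hit <- motif_matches(m, recs$sequence_aa, recs$cdr3_start)
  sa <- sort(unique(recs$subject_id[hit & recs$category == "A"]))
  sb <- sort(unique(recs$subject_id[hit & recs$category == "B"]))
  structure(list(
    motif = m,
    matched_record_ids = recs$sequence_id[hit],
    matched_subjects_a = sa,
    matched_subjects_b = sb,
    a = length(sa),
    b = length(sb),
    separation = length(sa) - length(sb)
  ), class = "haystack_match")
}

#' @export
print.haystack_match <- function(x, ...) {
  cat("<motif match> ", format(x$motif), ": ",
      length(x$matched_record_ids), " sequences, a = ", x$a,
      ", b = ", x$b, ", separation = ", x$separation, "\n", sep = "")
  invisible(x)
}

#' Restrict a store to a motif's match set
#'
#' Returns the temporary sub-repertoire `dM` holding exactly the records
#' matching the motif. The subject table and the category denominators
#' `|A|`, `|B|` of the parent are preserved: scoring inside a restricted
#' store always uses the original cohort sizes. The parent store is
#' unchanged.
#'
#' @inheritParams query_motif
#' @return A `haystack_store` over the matching records (possibly with
#'   zero records, which is legal: the search skips it).
#' @export
restrict <- function(store, m) {
  stopifnot(inherits(store, "haystack_store"))
  m <- .as_motif(m)
  recs <- store$records
  hit <- motif_matches(m, recs$sequence_aa, recs$cdr3_start)
  structure(list(
    records = recs[hit],
    subjects = store$subjects,
    size_a = store$size_a,
    size_b = store$size_b,
    n_dropped = 0L,
    drop_reasons = c(invalid_residue = 0L, invalid_cdr3 = 0L),
    category_a_diagnoses = store$category_a_diagnoses,
    index = new.env(parent = emptyenv())
  ), class = "haystack_store")
}

#' Write records as an AIRR-style TSV
#'
#' @param records A data.frame of records (e.g. `store$records` or the
#'   `records` element of [simulate_repertoire()] output).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t", quote = FALSE)
  invisible(path)
}
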