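# Independent oracles and fixture builders. The oracles deliberately use
# naive per-record, per-position logic so they share no code path with
# the vectorized implementation they check.

AA <- amino_acids()

# literal position-by-position motif match, one record at a time
oracle_match <- function(m, aa_sequence, cdr3_start) {
  vapply(seq_along(aa_sequence), function(r) {
    seq1 <- aa_sequence[r]
    c0 <- cdr3_start[min(r, length(cdr3_start))]
    for (j in seq_along(m$ems)) {
      ems <- m$ems[j]
      for (p in seq_len(nchar(ems)) - 1L) {
        pos0 <- c0 - m$offset[j] + p
        if (pos0 < 0L || pos0 >= nchar(seq1)) return(FALSE)
        if (substr(seq1, pos0 + 1L, pos0 + 1L) != substr(ems, p + 1L, p + 1L)) {
          return(FALSE)
        }
      }
    }
    TRUE
  }, logical(1))
}

# per-subject distinct 3-mer content, by explicit nested loops
oracle_subject_triplets <- function(store) {
  recs <- store$records
  out <- list()
  for (subj in unique(recs$subject_id)) {
    seqs <- recs$sequence_aa[recs$subject_id == subj]
    trips <- character(0)
    for (s in seqs) {
      if (nchar(s) >= 3L) {
        for (i in seq_len(nchar(s) - 2L)) {
          trips <- c(trips, substr(s, i, i + 2L))
        }
      }
    }
    out[[subj]] <- unique(trips)
  }
  out
}

random_sequence <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# small random store: random sequences, random CDR3 anchors
random_store <- function(n_records = 60, n_subjects = 8, seed = NULL,
                         len_range = c(25, 45)) {
  if (!is.null(seed)) set.seed(seed)
  subj <- sprintf("s%02d", sample.int(n_subjects, n_records, replace = TRUE))
  lens <- sample(seq(len_range[1], len_range[2]), n_records, replace = TRUE)
  cdr3_start <- vapply(lens, function(l) sample.int(l - 5L, 1L) + 2L, integer(1))
  records <- data.frame(
    sequence_id = sprintf("r%04d", seq_len(n_records)),
    subject_id = subj,
    diagnosis = ifelse(as.integer(sub("s", "", subj)) %% 2L == 0L,
                       "case", "control"),
    sequence_aa = vapply(lens, random_sequence, ""),
    cdr3_start = cdr3_start,
    cdr3_end = cdr3_start + 3L
  )
  repertoire_store(records, "case")
}

# random canonical motif; anchored = TRUE copies residues from a store
# record so matches are not vanishingly rare
random_motif <- function(store = NULL, max_components = 3) {
  k <- sample.int(max_components, 1L)
  if (!is.null(store) && nrow(store$records) > 0L) {
    r <- store$records[sample.int(nrow(store$records), 1L)]
    len <- nchar(r$sequence_aa)
    ems <- character(0); off <- integer(0)
    pos_used <- integer(0)
    for (i in seq_len(k)) {
      w <- sample(3:4, 1L)
      start0 <- sample.int(len - w + 1L, 1L) - 1L
      pos <- seq.int(start0, length.out = w)
      if (any(c(pos, pos + 1L, pos - 1L) %in% pos_used)) next
      pos_used <- c(pos_used, pos)
      ems <- c(ems, substr(r$sequence_aa, start0 + 1L, start0 + w))
      off <- c(off, r$cdr3_start - start0)
    }
    if (length(ems) > 0L) return(motif(ems, off))
  }
  # fully random components at non-overlapping, non-adjacent positions
  widths <- sample(3:5, k, replace = TRUE)
  gaps <- sample(1:4, k, replace = TRUE)
  starts <- sample(-20:5, 1L) +
    cumsum(c(0L, (widths[-k] + gaps[-k])[seq_len(k - 1L)]))
  motif(vapply(widths, random_sequence, ""), -starts)
}

# Hand-built cohort in which neither planted component is disease-only
# on its own (each also occurs in controls) but their conjunction is:
# discovering the DOM requires recursive restriction and merging.
# Sequences are length 30, CDR3 at [20, 30); TNE sits at offset 14
# (string positions 7-9) and DTA at offset 6 (positions 15-17).
decoy_store <- function() {
  base <- strrep("G", 30)
  with_parts <- function(tne, dta) {
    s <- base
    substr(s, 7, 9) <- tne
    substr(s, 15, 17) <- dta
    s
  }
  rows <- list()
  add <- function(subj, diag, seqs) {
    for (i in seq_along(seqs)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sequence_id = sprintf("%s_r%d", subj, i), subject_id = subj,
        diagnosis = diag, sequence_aa = seqs[i],
        cdr3_start = 20L, cdr3_end = 30L)
    }
  }
  for (i in 1:6) {
    add(sprintf("A%d", i), "case", c(with_parts("TNE", "DTA"), base))
  }
  for (i in 1:3) {
    add(sprintf("Bt%d", i), "control", c(with_parts("TNE", "KKK"), base))
  }
  for (i in 1:3) {
    add(sprintf("Bd%d", i), "control", c(with_parts("KKK", "DTA"), base))
  }
  repertoire_store(do.call(rbind, rows), "case")
}
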