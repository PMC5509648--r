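# Synthetic repertoire generator.
#
# Emulates germline-templated IgG-VH amino-acid sequences: a fixed
# framework (FR1-FR3) template ending just before the CDR3, a CDR3 of
# variable length beginning with the germline-templated "CAR", and an
# FR4 tail, with independent per-residue substitution noise everywhere.
# A planted motif is written into a carrier-subject fraction of case
# (and optionally control) sequences at its exact CDR3-relative
# offsets AFTER the substitution noise, so planted positions are
# mutation-protected and the prevalence parameters are exact ground
# truth. No indel or lineage structure is simulated.

# Synthetic germline-like template (IGHV3-flavoured framework; the FR3
# end "...AEDTAVYY" places the germline-identical DTA at offset 6, so a
# planted (TNE, 14), (DTA, 6), (CAR, 0) motif is discriminative only
# through its non-germline TNE component, mirroring how a real
# disease-only motif can ride on germline-identical anchors).
.default_template <- function() {
  list(
    left = paste0("EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVS",
                  "AISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYY"),
    right = "WGQGTLVTVSS"
  )
}

#' Configuration for the synthetic repertoire generator
#'
#' @param n_case,n_control Subject counts per category (each >= 1).
#' @param seqs_per_subject Mean sequence count per subject; actual
#'   counts are Poisson-dispersed around this mean (floor 1).
#' @param germline_templates List of templates, each a list with
#'   elements `left` (framework ending immediately before the first
#'   CDR3 residue) and `right` (FR4 tail appended after the CDR3).
#' @param cdr3_length_range Integer bounds `c(lo, hi)` of the uniform
#'   CDR3 length distribution; every CDR3 begins with the
#'   germline-templated `CAR`, so `lo >= 4`.
#' @param point_mutation_rate Per-residue substitution probability
#'   applied independently to every position.
#' @param planted_motif The motif written into carrier sequences (a
#'   [motif()] or parenthesis-notation string), or `NULL` for a null
#'   cohort with no planted signal.
#' @param prevalence_case,prevalence_control Per-subject carrier
#'   probabilities in each category.
#' @param carrier_seq_fraction Probability that any one sequence of a
#'   carrier bears the planted motif.
#' @param diagnosis_case,diagnosis_control Diagnosis labels written to
#'   the records.
#' @param seed Integer RNG seed; generation is deterministic given the
#'   config.
#' @return A `haystack_simconfig` list.
#' @export
generator_config <- function(n_case = 20L, n_control = 20L,
                             seqs_per_subject = 500,
                             germline_templates = list(.default_template()),
                             cdr3_length_range = c(10L, 18L),
                             point_mutation_rate = 0.02,
                             planted_motif = "(TNE, 14), (DTA, 6), (CAR, 0)",
                             prevalence_case = 0.7,
                             prevalence_control = 0,
                             carrier_seq_fraction = 0.05,
                             diagnosis_case = "MS",
                             diagnosis_control = "healthy",
                             seed = 1L) {
  n_case <- as.integer(n_case)
  n_control <- as.integer(n_control)
  if (is.na(n_case) || n_case < 1L || is.na(n_control) || n_control < 1L) {
    stop("need at least one subject in each category")
  }
  stopifnot(seqs_per_subject >= 1,
            point_mutation_rate >= 0, point_mutation_rate < 1,
            prevalence_case >= 0, prevalence_case <= 1,
            prevalence_control >= 0, prevalence_control <= 1,
            carrier_seq_fraction >= 0, carrier_seq_fraction <= 1,
            length(cdr3_length_range) == 2L)
  cdr3_length_range <- as.integer(cdr3_length_range)
  if (cdr3_length_range[1L] < 4L ||
      cdr3_length_range[2L] < cdr3_length_range[1L]) {
    stop("cdr3_length_range must satisfy 4 <= lo <= hi")
  }
  for (tp in germline_templates) {
    stopifnot(is.list(tp), is.character(tp$left), is.character(tp$right))
    .check_residues(c(tp$left, tp$right), "template")
  }
  if (!is.null(planted_motif)) {
    planted_motif <- .as_motif(planted_motif)
    pos <- .motif_positions(planted_motif)
    left_need <- max(0L, -min(pos))
    if (any(vapply(germline_templates,
                   function(tp) nchar(tp$left) < left_need, logical(1)))) {
      stop("template too short for planted motif: framework must cover ",
           left_need, " residues left of the CDR3")
    }
    if (max(pos) >= cdr3_length_range[1L]) {
      stop("template too short for planted motif: components may not extend ",
           "past the shortest CDR3")
    }
  }
  structure(list(
    n_case = n_case, n_control = n_control,
    seqs_per_subject = seqs_per_subject,
    germline_templates = germline_templates,
    cdr3_length_range = cdr3_length_range,
    point_mutation_rate = point_mutation_rate,
    planted_motif = planted_motif,
    prevalence_case = prevalence_case,
    prevalence_control = prevalence_control,
    carrier_seq_fraction = carrier_seq_fraction,
    diagnosis_case = diagnosis_case,
    diagnosis_control = diagnosis_control,
    seed = as.integer(seed)
  ), class = "haystack_simconfig")
}

#' Generate a synthetic annotated repertoire with a planted motif
#'
#' Draws carrier subjects per category by prevalence, builds
#' germline-templated sequences with Poisson-dispersed per-subject
#' counts, applies independent substitution noise, writes the planted
#' motif into carrier sequences at its exact CDR3-relative offsets
#' (planted positions are thereby mutation-protected), and self-checks
#' that every planted record matches the motif. Deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `haystack_sim` list with elements `records` (an AIRR-style
#'   data.table with columns `sequence_id`, `subject_id`, `diagnosis`,
#'   `sequence_aa`, `cdr3_start`, `cdr3_end`, `v_call`, `j_call`),
#'   `manifest` (truth manifest: per-subject carrier flags, planted
#'   record ids, motif string, config echo), and `config`.
#' @export
#' @examples
#' sim <- simulate_repertoire(generator_config(
#'   n_case = 3, n_control = 3, seqs_per_subject = 10, seed = 7))
#' sim$manifest$subjects
simulate_repertoire <- function(config = generator_config()) {
  stopifnot(inherits(config, "haystack_simconfig"))
  set.seed(config$seed)
  aa <- amino_acids()

  subjects <- data.table(
    subject_id = c(sprintf("case%03d", seq_len(config$n_case)),
                   sprintf("ctrl%03d", seq_len(config$n_control))),
    category = rep(c("A", "B"), c(config$n_case, config$n_control)),
    diagnosis = rep(c(config$diagnosis_case, config$diagnosis_control),
                    c(config$n_case, config$n_control))
  )
  prev <- ifelse(subjects$category == "A",
                 config$prevalence_case, config$prevalence_control)
  subjects[, carrier := !is.null(config$planted_motif) &
             runif(.N) < prev]

  n_per_subj <- pmax(1L, rpois(nrow(subjects), config$seqs_per_subject))
  si <- rep.int(seq_len(nrow(subjects)), n_per_subj)
  nrec <- length(si)

  tpl_id <- sample.int(length(config$germline_templates), nrec, replace = TRUE)
  lefts <- vapply(config$germline_templates, `[[`, "", "left")
  rights <- vapply(config$germline_templates, `[[`, "", "right")
  cdr3_len <- sample(seq.int(config$cdr3_length_range[1L],
                             config$cdr3_length_range[2L]),
                     nrec, replace = TRUE)

  # germline-templated base sequences: FR1-3 | CAR + random CDR3 | FR4
  tail_len <- cdr3_len - 3L
  tail_chars <- sample(aa, sum(tail_len), replace = TRUE)
  tails <- vapply(split(tail_chars, rep.int(seq_len(nrec), tail_len)),
                  paste, collapse = "", FUN.VALUE = "")
  seqs <- paste0(lefts[tpl_id], "CAR", unname(tails), rights[tpl_id])
  cdr3_start <- nchar(lefts)[tpl_id]            # 0-based
  cdr3_end <- cdr3_start + cdr3_len

  # independent per-residue substitution noise
  lens <- nchar(seqs)
  n_mut <- rbinom(nrec, lens, config$point_mutation_rate)
  for (i in which(n_mut > 0L)) {
    s <- seqs[i]
    for (j in sample.int(lens[i], n_mut[i])) {
      substr(s, j, j) <- sample(setdiff(aa, substr(s, j, j)), 1L)
    }
    seqs[i] <- s
  }

  # plant the motif into carrier sequences (after noise: protected)
  planted <- rep(FALSE, nrec)
  if (!is.null(config$planted_motif)) {
    planted <- subjects$carrier[si] & runif(nrec) < config$carrier_seq_fraction
    m <- config$planted_motif
    for (ci in seq_along(m$ems)) {
      s0 <- cdr3_start[planted] - m$offset[ci] + 1L   # 1-based start
      s <- seqs[planted]
      substr(s, s0, s0 + nchar(m$ems[ci]) - 1L) <- m$ems[ci]
      seqs[planted] <- s
    }
    ok <- motif_matches(m, seqs[planted], cdr3_start[planted])
    stopifnot(all(ok))
  }

  records <- data.table(
    sequence_id = sprintf("%s_seq%04d", subjects$subject_id[si],
                          sequence(n_per_subj)),
    subject_id = subjects$subject_id[si],
    diagnosis = subjects$diagnosis[si],
    sequence_aa = seqs,
    cdr3_start = cdr3_start,
    cdr3_end = cdr3_end,
    v_call = "IGHV3-SYN",
    j_call = "IGHJ-SYN"
  )

  manifest <- list(
    subjects = subjects,
    planted_motif = if (is.null(config$planted_motif)) NULL
                    else format(config$planted_motif),
    n_planted_records = sum(planted),
    planted_record_ids = records$sequence_id[planted],
    n_records = nrec,
    seed = config$seed
  )
  structure(list(records = records, manifest = manifest, config = config),
            class = "haystack_sim")
}

#' Generate a null cohort (no planted motif)
#'
#' Identical to [simulate_repertoire()] with the planted motif removed:
#' case and control repertoires are drawn from the same background
#' model, so no disease-only signal exists by construction.
#'
#' @inheritParams simulate_repertoire
#' @return A `haystack_sim`; `manifest$planted_motif` is `NULL` and all
#'   carrier flags are `FALSE`.
#' @export
null_cohort <- function(config = generator_config()) {
  config$planted_motif <- NULL
  simulate_repertoire(config)
}

#' Build a repertoire store from generator output
#'
#' @param sim A `haystack_sim` from [simulate_repertoire()].
#' @return A `haystack_store` with category A assigned to the
#'   generator's case diagnosis.
#' @export
sim_store <- function(sim) {
  stopifnot(inherits(sim, "haystack_sim"))
  repertoire_store(sim$records, sim$config$diagnosis_case)
}

#' @export
print.haystack_sim <- function(x, ...) {
  cat("<synthetic repertoire> ", nrow(x$records), " records, ",
      nrow(x$manifest$subjects), " subjects; planted motif: ",
      if (is.null(x$manifest$planted_motif)) "none"
      else x$manifest$planted_motif,
      " (", sum(x$manifest$subjects$carrier), " carriers, ",
      x$manifest$n_planted_records, " planted records)\n", sep = "")
  invisible(x)
}
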