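# Breadth-first DOM search over the motif network.
#
# Level 0 (steps 1-3): tally triplets by distinct category-A subjects,
# turn each surviving triplet into an atomic vector at the
# a-maximizing offset, grow every atomic by one residue on either side,
# and keep candidates whose separation score clears St. Levels 1+
# (steps 4-6): for each frontier motif M, restrict the store to M's
# match set (a temporary sub-repertoire dM that keeps the ORIGINAL
# cohort denominators), rerun steps 1-3 inside dM, and merge each
# resulting non-gapped motif back into M -- overlap-consistent pieces
# lengthen an EMS, disjoint pieces add a gap. Every motif scored
# against the full store is recorded in a visited set keyed on the
# canonical motif string; the traversed count C is the size of that
# set. Motifs scored only inside a dM are search mechanics and are not
# counted until their merged forms face the full store.

#' Search configuration
#'
#' @param dt DOM-determining threshold `Dt` in `(0, 1]`: a motif is a
#'   DOM when it matches at least `floor(Dt * |A|)` category-A subjects
#'   and zero category-B subjects. Default 0.6.
#' @param st Separation threshold `St`: candidates whose separation
#'   score falls below `St` are pruned from the frontier (they are
#'   still scored, and can still be recognized as DOMs). Default 15.
#' @param gc Maximum gap count `Gc` in any output motif; the traversal
#'   stops once the frontier's maximum gap count reaches `Gc`.
#'   Default 2.
#' @param objective `"separation"` scores a candidate as `a - b`;
#'   `"category_blind"` scores it as `-(a + b - k)^2`, maximized when
#'   the total number of matched subjects equals the center `k` (note
#'   that `st` must then be set on the same, non-positive, scale).
#' @param blind_center Center `k` of the category-blind objective;
#'   defaults to `|A|` at run time.
#' @param stop_policy `"finish_level"` (default) completes the level in
#'   which the first DOM appears and reports every DOM found by then;
#'   `"first_dom"` stops at the first DOM; `"exhaust"` ignores DOMs and
#'   runs until the frontier is empty or the gap bound is reached.
#' @param tally_mode `"subjects"` (default) tallies a triplet by the
#'   number of distinct category-A subjects whose repertoires contain
#'   it; `"occurrences"` tallies raw occurrence counts over all
#'   sequences (the literal reading of the seed-stage filter; same
#'   threshold).
#' @param max_levels Safety cap on the number of merge levels.
#' @return A `haystack_config` list.
#' @export
search_config <- function(dt = 0.6, st = 15L, gc = 2L,
                          objective = c("separation", "category_blind"),
                          blind_center = NULL,
                          stop_policy = c("finish_level", "first_dom", "exhaust"),
                          tally_mode = c("subjects", "occurrences"),
                          max_levels = 25L) {
  objective <- match.arg(objective)
  stop_policy <- match.arg(stop_policy)
  tally_mode <- match.arg(tally_mode)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0, dt <= 1,
            is.numeric(st), length(st) == 1L,
            is.numeric(gc), length(gc) == 1L, gc >= 0)
  if (objective == "separation" && st < 0) {
    stop("St must be >= 0 under the separation objective")
  }
  structure(list(dt = dt, st = st, gc = as.integer(gc),
                 objective = objective, blind_center = blind_center,
                 stop_policy = stop_policy, tally_mode = tally_mode,
                 max_levels = as.integer(max_levels)),
            class = "haystack_config")
}

#' Minimum category-A match count for DOM status
#'
#' `floor(Dt * |A|)`, guarded against floating-point representation of
#' `Dt` (so e.g. `Dt = 0.6, |A| = 20` gives 12, not 11).
#'
#' @param dt DOM-determining threshold in `(0, 1]`.
#' @param size_a Number of category-A subjects.
#' @return Integer match-count cutoff.
#' @export
#' @examples
#' dom_count_threshold(0.6, 51)  # 30
dom_count_threshold <- function(dt, size_a) {
  as.integer(floor(dt * size_a + sqrt(.Machine$double.eps)))
}

#' Separation score of a match result
#'
#' Under the `"separation"` objective the score is `a - b`; under
#' `"category_blind"` it is `-(a + b - k)^2` with center `k`
#' (`config$blind_center`, defaulting to `|A|` is supplied by the
#' caller via `k`). Higher is always better.
#'
#' @param match A `haystack_match` (or any list with elements `a`, `b`).
#' @param config A [search_config()].
#' @param k Center of the category-blind objective (ignored under
#'   `"separation"`).
#' @return A single numeric score.
#' @export
#' @examples
#' separation_score(list(a = 20, b = 3), search_config())
separation_score <- function(match, config = search_config(), k = NULL) {
  .sep_score(match$a, match$b, config,
             k = if (is.null(k)) config$blind_center else k)
}

.sep_score <- function(a, b, config, k = NULL) {
  if (config$objective == "separation") {
    a - b
  } else {
    if (is.null(k)) stop("category-blind objective needs a center k")
    -(a + b - k)^2
  }
}

#' Tally triplets against the seed threshold
#'
#' Scans every sequence for all amino-acid triplets and keeps those
#' reaching the seed threshold `floor(Dt * |A|)`. In the default
#' `"subjects"` mode a triplet's tally is the number of distinct
#' category-A subjects whose repertoires contain it anywhere (the
#' threshold is denominated in people); in `"occurrences"` mode it is
#' the raw occurrence count over all sequences.
#'
#' @param store A `haystack_store`.
#' @param config A [search_config()].
#' @return Named integer vector mapping each surviving triplet to its
#'   tally (possibly empty).
#' @export
tally_triplets <- function(store, config = search_config()) {
  stopifnot(inherits(store, "haystack_store"))
  if (nrow(store$records) == 0L) return(setNames(integer(0), character(0)))
  idx <- .triplet_index(store)
  thr <- dom_count_threshold(config$dt, store$size_a)
  if (config$tally_mode == "subjects") {
    tal <- idx[category == "A", .(n = uniqueN(subject_id)), by = triplet]
  } else {
    tal <- idx[, .(n = .N), by = triplet]
  }
  tal <- tal[n >= thr]
  setorder(tal, triplet)
  setNames(tal$n, tal$triplet)
}

# Per-(triplet, offset) distinct-subject counts for a set of triplets.
.atomic_pair_scores <- function(store, triplets) {
  idx <- .triplet_index(store)
  sub <- idx[triplet %chin% triplets]
  ag <- sub[, .(a = uniqueN(subject_id[category == "A"]),
                b = uniqueN(subject_id[category == "B"])),
            by = .(triplet, offset)]
  ag
}

#' Turn a triplet into an atomic vector at its best coordinate
#'
#' Among all offsets at which the triplet occurs in at least one record,
#' selects the one maximizing the distinct category-A subject match
#' count `a`; ties go to the smallest offset (closest to the CDR3).
#'
#' @param triplet A 3-letter amino-acid string.
#' @param store A `haystack_store`.
#' @return A single-component [motif()], or `NULL` if the triplet
#'   occurs nowhere in the store.
#' @export
make_atomic_vector <- function(triplet, store) {
  stopifnot(inherits(store, "haystack_store"))
  ag <- .atomic_pair_scores(store, triplet)
  if (nrow(ag) == 0L) return(NULL)
  setorder(ag, -a, offset)
  motif(triplet, ag$offset[1L])
}

# Score a motif against a store: distinct-subject counts only.
.score_ab <- function(store, m) {
  recs <- store$records
  hit <- motif_matches(m, recs$sequence_aa, recs$cdr3_start)
  list(a = uniqueN(recs$subject_id[hit & recs$category == "A"]),
       b = uniqueN(recs$subject_id[hit & recs$category == "B"]))
}

# All single-residue extensions of a single-component motif that match
# >= 1 record, with their subject counts. Returns a list of entries
# list(motif, a, b, key).
.extension_candidates <- function(store, m) {
  recs <- store$records
  hit <- motif_matches(m, recs$sequence_aa, recs$cdr3_start)
  if (!any(hit)) return(list())
  k <- nchar(m$ems[1L])
  off <- m$offset[1L]
  out <- list()
  for (side in c("N", "C")) {
    pos0 <- if (side == "N") recs$cdr3_start - off - 1L
            else recs$cdr3_start - off + k
    valid <- hit & pos0 >= 0L & (pos0 + 1L) <= nchar(recs$sequence_aa)
    if (!any(valid)) next
    ch <- substr(recs$sequence_aa[valid], pos0[valid] + 1L, pos0[valid] + 1L)
    subj <- recs$subject_id[valid]
    cat_ <- recs$category[valid]
    for (r in sort(unique(ch))) {
      sel <- ch == r
      m2 <- if (side == "N") .motif1(paste0(r, m$ems), off + 1L)
            else .motif1(paste0(m$ems, r), off)
      out[[length(out) + 1L]] <- list(
        motif = m2,
        a = uniqueN(subj[sel & cat_ == "A"]),
        b = uniqueN(subj[sel & cat_ == "B"]),
        key = .motif_key(m2))
    }
  }
  out
}

#' Grow non-gapped candidates by one residue
#'
#' For each single-component input motif, enumerates every one-residue
#' N- or C-side extension supported by at least one record, scores it,
#' and returns the inputs plus all extensions whose separation score
#' clears `St` (candidate list `L` of the seed stage).
#'
#' @param vectors A list of single-component motifs (or a single motif).
#' @param store A `haystack_store`.
#' @param config A [search_config()].
#' @return A list of motifs.
#' @export
extend_nongapped <- function(vectors, store, config = search_config()) {
  if (inherits(vectors, "haystack_motif")) vectors <- list(vectors)
  k <- store$size_a
  out <- list()
  seen <- character(0)
  for (v in vectors) {
    s <- .score_ab(store, v)
    if (.sep_score(s$a, s$b, config, k) >= config$st) {
      key <- .motif_key(v)
      if (!key %chin% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- v
      }
    }
    for (e in .extension_candidates(store, v)) {
      if (.sep_score(e$a, e$b, config, k) >= config$st &&
          !e$key %chin% seen) {
        seen <- c(seen, e$key)
        out[[length(out) + 1L]] <- e$motif
      }
    }
  }
  out
}

# Steps 1-3 on a store, fully batched: tally, atomic vectors at best
# offsets, one-residue extensions of the St-survivors. Returns score
# TABLES (not motif objects) so callers materialize only what they
# need: `pairs` holds every (triplet, offset) candidate examined,
# `best` one a-maximizing atomic vector per triplet (with `sep`), and
# `ext` every scored one-residue extension with its resulting
# component (`res_ems`, `res_off`) and `sep`, deduplicated on the
# resulting motif and ordered deterministically.
.seed_empty <- function() {
  list(
    pairs = data.table(triplet = character(0), offset = integer(0),
                       a = integer(0), b = integer(0)),
    best = data.table(triplet = character(0), offset = integer(0),
                      a = integer(0), b = integer(0), sep = numeric(0)),
    ext = data.table(res_ems = character(0), res_off = integer(0),
                     a = integer(0), b = integer(0), sep = numeric(0)))
}

.seed_and_extend <- function(store, config, thr, k) {
  empty <- .seed_empty()
  recs <- store$records
  if (nrow(recs) == 0L) return(empty)
  idx <- .triplet_index(store)
  # grouping via data.table pays off on big stores; on the small
  # restricted sub-stores of the merge levels its per-call overhead
  # dominates, so a base-R path handles those
  if (nrow(idx) <= getOption("haystack.seed_batch_rows", 200000L)) {
    return(.seed_and_extend_small(idx, recs, config, thr, k))
  }
  u <- unique(idx[, .(triplet, offset, subject_id, category)])

  # step 1: tally against the seed threshold
  if (config$tally_mode == "subjects") {
    tal <- unique(u[category == "A", .(triplet, subject_id)])[, .N, by = triplet]
  } else {
    tal <- idx[, .N, by = triplet]
  }
  tal <- tal[N >= thr]
  if (nrow(tal) == 0L) return(empty)

  # step 2: distinct-subject counts per candidate pair; best offset by
  # a, ties to the smallest offset
  u <- u[triplet %chin% tal$triplet]
  ag <- u[, .(a = sum(category == "A"), b = sum(category == "B")),
          by = .(triplet, offset)]
  setorder(ag, triplet, -a, offset)
  best <- ag[!duplicated(triplet)]
  best[, sep := .sep_score(a, b, config, k)]
  surv <- best[sep >= config$st]

  # step 3: every one-residue extension of the survivors, scored from
  # the inverted index in one pass
  ext <- empty$ext
  if (nrow(surv) > 0L) {
    sub <- idx[surv[, .(triplet, offset)], on = c("triplet", "offset"),
               nomatch = NULL]
    aa <- recs$sequence_aa[sub$ri]
    lenr <- nchar(aa)
    cdr3 <- recs$cdr3_start[sub$ri]
    cand <- list()
    posN <- cdr3 - sub$offset - 1L              # 0-based left neighbor
    vN <- posN >= 0L
    if (any(vN)) {
      cand[[1L]] <- data.table(
        triplet = sub$triplet[vN], offset = sub$offset[vN], side = "N",
        char = substr(aa[vN], posN[vN] + 1L, posN[vN] + 1L),
        subject_id = sub$subject_id[vN], category = sub$category[vN])
    }
    posC <- cdr3 - sub$offset + 3L              # 0-based right neighbor
    vC <- posC < lenr
    if (any(vC)) {
      cand[[length(cand) + 1L]] <- data.table(
        triplet = sub$triplet[vC], offset = sub$offset[vC], side = "C",
        char = substr(aa[vC], posC[vC] + 1L, posC[vC] + 1L),
        subject_id = sub$subject_id[vC], category = sub$category[vC])
    }
    if (length(cand)) {
      eu <- unique(rbindlist(cand))
      ext <- eu[, .(a = sum(category == "A"), b = sum(category == "B")),
                by = .(triplet, offset, side, char)]
      ext[, res_ems := ifelse(side == "N", paste0(char, triplet),
                              paste0(triplet, char))]
      ext[, res_off := ifelse(side == "N", offset + 1L, offset)]
      ext[, sep := .sep_score(a, b, config, k)]
      setorder(ext, triplet, offset, side, char)
      ext <- unique(ext, by = c("res_ems", "res_off"))
      ext <- ext[, .(res_ems, res_off, a, b, sep)]
    }
  }
  list(pairs = ag, best = best, ext = ext)
}

# Base-R twin of the data.table seed stage; identical outputs, built
# for small inverted indexes where vectorized base ops beat grouped
# data.table calls. Covered by an equivalence test against the
# data.table path.
.seed_and_extend_small <- function(idx, recs, config, thr, k) {
  empty <- .seed_empty()
  t <- idx$triplet; o <- idx$offset; s <- idx$subject_id
  isA <- idx$category == "A"
  # pack (triplet, offset) and subject into exact numeric codes: string
  # keys are the bottleneck at this scale
  ut_all <- unique(t)
  ti <- chmatch(t, ut_all)
  us <- unique(s)
  si <- chmatch(s, us)
  oc <- o - min(o)                       # 0-based offset code, < 4096
  code2 <- ti * 4096 + oc                # (triplet, offset)
  code3 <- code2 * 8192 + si             # (triplet, offset, subject)

  # step 1: tally
  if (config$tally_mode == "subjects") {
    cts <- (ti * 8192 + si)[isA]
    tt <- ti[isA][!duplicated(cts)]
    counts <- tabulate(tt, length(ut_all))
  } else {
    counts <- tabulate(ti, length(ut_all))
  }
  passmask <- counts >= thr
  if (!any(passmask)) return(empty)

  # step 2: distinct-subject counts per (triplet, offset)
  d3 <- !duplicated(code3) & passmask[ti]
  c2 <- code2[d3]; A3 <- isA[d3]
  up <- unique(c2)
  gi <- match(c2, up)
  a <- tabulate(gi[A3], length(up))
  b <- tabulate(gi[!A3], length(up))
  fi <- match(up, c2)
  pt <- t[d3][fi]; poff <- o[d3][fi]
  pairs <- data.table(triplet = pt, offset = poff, a = a, b = b)
  sep <- .sep_score(a, b, config, k)
  ordb <- order(pt, -a, poff, method = "radix")
  firstb <- ordb[!duplicated(pt[ordb])]
  best <- data.table(triplet = pt[firstb], offset = poff[firstb],
                     a = a[firstb], b = b[firstb], sep = sep[firstb])
  surv <- best[best$sep >= config$st]

  # step 3: one-residue extensions of the survivors
  ext <- empty$ext
  if (nrow(surv) > 0L) {
    scode <- chmatch(surv$triplet, ut_all) * 4096 + (surv$offset - min(o))
    rows <- which(code2 %in% scode)
    rt <- t[rows]; ro <- o[rows]; rA <- isA[rows]
    rc2 <- code2[rows]; rsi <- si[rows]
    rri <- idx$ri[rows]
    aa <- recs$sequence_aa[rri]
    cdr3 <- recs$cdr3_start[rri]
    lenr <- nchar(aa)
    posN <- cdr3 - ro - 1L; vN <- posN >= 0L
    posC <- cdr3 - ro + 3L; vC <- posC < lenr
    et <- c(rt[vN], rt[vC]); eo <- c(ro[vN], ro[vC])
    eA <- c(rA[vN], rA[vC]); ec2 <- c(rc2[vN], rc2[vC])
    esi <- c(rsi[vN], rsi[vC])
    isN <- rep(c(TRUE, FALSE), c(sum(vN), sum(vC)))
    ch <- c(substr(aa[vN], posN[vN] + 1L, posN[vN] + 1L),
            substr(aa[vC], posC[vC] + 1L, posC[vC] + 1L))
    if (length(et)) {
      ci <- chmatch(ch, amino_acids())
      code4 <- (ec2 * 2 + isN) * 32 + ci           # (t, o, side, char)
      code5 <- code4 * 8192 + esi                  # ... + subject
      dd <- !duplicated(code5)
      code4 <- code4[dd]; et <- et[dd]; eo <- eo[dd]; eA <- eA[dd]
      isN <- isN[dd]; ch <- ch[dd]
      ue <- unique(code4)
      egi <- match(code4, ue)
      ea <- tabulate(egi[eA], length(ue))
      eb <- tabulate(egi[!eA], length(ue))
      efi <- match(ue, code4)
      ft <- et[efi]; fo <- eo[efi]; fc <- ch[efi]
      fs <- ifelse(isN[efi], "N", "C")
      orde <- order(ft, fo, fs, fc, method = "radix")
      ft <- ft[orde]; fo <- fo[orde]; fs <- fs[orde]; fc <- fc[orde]
      ea <- ea[orde]; eb <- eb[orde]
      res_ems <- ifelse(fs == "N", paste0(fc, ft), paste0(ft, fc))
      res_off <- ifelse(fs == "N", fo + 1L, fo)
      kd <- !duplicated(paste0(res_ems, "\r", res_off))
      ext <- data.table(res_ems = res_ems[kd], res_off = res_off[kd],
                        a = ea[kd], b = eb[kd],
                        sep = .sep_score(ea[kd], eb[kd], config, k))
    }
  }
  list(pairs = pairs, best = best, ext = ext)
}

# St-surviving candidates of a seed stage as parallel vectors (ems,
# offset, a, b), atomic vectors first (triplet order), then extensions.
# All components are single EMSs, so no motif objects are needed here.
.seed_survivors <- function(seed, config) {
  bs <- seed$best[sep >= config$st]
  es <- seed$ext[sep >= config$st]
  list(ems = c(bs$triplet, es$res_ems),
       offset = c(bs$offset, es$res_off),
       a = c(bs$a, es$a), b = c(bs$b, es$b))
}

# Materialize the St-surviving candidates of a seed stage as entries
# list(motif, a, b, key), in deterministic order.
.seed_frontier <- function(seed, config) {
  sv <- .seed_survivors(seed, config)
  out <- vector("list", length(sv$ems))
  for (i in seq_along(sv$ems)) {
    m <- .motif1(sv$ems[i], sv$offset[i])
    out[[i]] <- list(motif = m, a = sv$a[i], b = sv$b[i],
                     key = .motif_key(m))
  }
  out
}

#' Seed-and-extend inside a restricted sub-repertoire
#'
#' Runs the seed stage (triplet tally, atomic vector generation,
#' non-gapped extension) on `restrict(store, m)`. The restricted store
#' inherits the parent's category denominators, so all thresholds are
#' computed against the original `|A|`.
#'
#' @param m The motif whose match set defines the sub-repertoire.
#' @param store A `haystack_store`.
#' @param config A [search_config()].
#' @return A list of non-gapped motifs (`L'`) that may be merged into
#'   `m`; empty when the restriction is empty.
#' @export
recursive_restriction <- function(m, store, config = search_config()) {
  m <- .as_motif(m)
  dm <- restrict(store, m)
  if (nrow(dm$records) == 0L) return(list())
  k <- if (is.null(config$blind_center)) store$size_a else config$blind_center
  thr <- dom_count_threshold(config$dt, store$size_a)
  res <- .seed_and_extend(dm, config, thr, k)
  lapply(.seed_frontier(res, config), `[[`, "motif")
}

#' Run the breadth-first DOM search
#'
#' Executes the full heuristic: seed atomic vectors from the triplet
#' tally, filter by separation score, then repeatedly restrict the
#' store to each frontier motif's match set, re-seed inside the
#' restriction, and merge the results back (overlaps lengthen an EMS,
#' disjoint components add a gap) until a DOM is found (per
#' `stop_policy`), the frontier empties, or the frontier's maximum gap
#' count reaches `Gc`. Deterministic: candidates are processed in
#' canonical-string order and a visited set guarantees no motif is
#' scored twice against the full store.
#'
#' @param store A `haystack_store`.
#' @param config A [search_config()].
#' @return A `haystack_result` with elements `doms` (list of
#'   `list(motif, match, significance)`, each re-verified by an
#'   independent [query_motif()] call), `c_traversed` (the visited-set
#'   size `C`), `levels` (per-level log), `dom_threshold`, `config`,
#'   `size_a`, `size_b`.
#' @export
haystack_search <- function(store, config = search_config()) {
  stopifnot(inherits(store, "haystack_store"))
  thr <- dom_count_threshold(config$dt, store$size_a)
  k <- if (is.null(config$blind_center)) store$size_a else config$blind_center

  visited <- new.env(parent = emptyenv(), hash = TRUE)
  n_visited <- 0L
  mark_visited <- function(keys) {
    for (key in keys) {
      if (!exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        n_visited <<- n_visited + 1L
      }
    }
  }
  doms <- list()       # entries list(motif, a, b, key, level)
  dom_keys <- character(0)
  level_rows <- list()
  halt <- FALSE        # first_dom immediate stop

  note_dom <- function(entry, level) {
    if (entry$b == 0L && entry$a >= thr && !entry$key %chin% dom_keys) {
      entry$level <- level
      doms[[length(doms) + 1L]] <<- entry
      dom_keys <<- c(dom_keys, entry$key)
      if (config$stop_policy == "first_dom") halt <<- TRUE
    }
  }

  # ---- level 0: steps 1-3 on the full store --------------------------
  seed <- .seed_and_extend(store, config, thr, k)
  mark_visited(sprintf("(%s, %d)", seed$pairs$triplet, seed$pairs$offset))
  mark_visited(sprintf("(%s, %d)", seed$ext$res_ems, seed$ext$res_off))
  # DOM check over every scored candidate: atomic vectors first (triplet
  # order), then extensions
  scored0 <- rbind(
    seed$best[, .(ems = triplet, offset = offset, a, b)],
    seed$ext[, .(ems = res_ems, offset = res_off, a, b)])
  for (i in which(scored0$b == 0L & scored0$a >= thr)) {
    m <- .motif1(scored0$ems[i], scored0$offset[i])
    note_dom(list(motif = m, a = scored0$a[i], b = scored0$b[i],
                  key = .motif_key(m)), 0L)
    if (halt) break
  }
  frontier <- .seed_frontier(seed, config)
  for (i in seq_along(frontier)) frontier[[i]]$parent <- store
  level_rows[[1L]] <- data.frame(level = 0L, frontier_in = NA_integer_,
                                 scored = n_visited,
                                 doms_total = length(doms),
                                 frontier_out = length(frontier))
  done <- halt ||
    (length(doms) > 0L && config$stop_policy == "finish_level") ||
    length(frontier) == 0L

  # ---- levels 1+: restrict, re-seed, merge ---------------------------
  level <- 0L
  while (!done && level < config$max_levels) {
    gaps <- vapply(frontier, function(e) gap_count(e$motif), integer(1))
    if (max(gaps) >= config$gc) break
    level <- level + 1L
    frontier <- frontier[order(vapply(frontier, `[[`, "", "key"))]
    new_frontier <- list()
    n_scored_level <- 0L
    for (entry in frontier) {
      # entry's match set lies inside its parent's, so restricting the
      # parent sub-store equals restricting the full store
      dm <- restrict(entry$parent, entry$motif)
      if (nrow(dm$records) == 0L) next
      lp <- .seed_survivors(.seed_and_extend(dm, config, thr, k), config)
      for (i in seq_along(lp$ems)) {
        merged <- .merge1(entry$motif, lp$ems[i], lp$offset[i])
        if (is.null(merged)) next                       # residue conflict
        if (length(merged$ems) - 1L > config$gc) next   # gap bound
        key <- .motif_key(merged)
        if (exists(key, envir = visited, inherits = FALSE)) next
        # matchset(merged) = matchset(entry) intersect matchset(piece)
        # = the piece's matches inside dm, so the piece's dm-scores ARE
        # the merged motif's full-store subject counts
        mark_visited(key)
        n_scored_level <- n_scored_level + 1L
        cand <- list(motif = merged, a = lp$a[i], b = lp$b[i], key = key,
                     parent = dm)
        note_dom(cand, level)
        if (halt) break
        if (.sep_score(lp$a[i], lp$b[i], config, k) >= config$st) {
          new_frontier[[length(new_frontier) + 1L]] <- cand
        }
      }
      if (halt) break
    }
    level_rows[[level + 1L]] <- data.frame(
      level = level, frontier_in = length(frontier),
      scored = n_scored_level, doms_total = length(doms),
      frontier_out = length(new_frontier))
    done <- halt ||
      (length(doms) > 0L && config$stop_policy != "exhaust") ||
      length(new_frontier) == 0L
    frontier <- new_frontier
  }

  # ---- report --------------------------------------------------------
  c_traversed <- n_visited
  ord <- order(-vapply(doms, `[[`, 0L, "a"), vapply(doms, `[[`, "", "key"))
  doms <- doms[ord]
  dom_out <- lapply(doms, function(d) {
    q <- query_motif(store, d$motif)   # independent re-verification
    if (q$b != 0L || q$a < thr) {
      stop(errorCondition(
        sprintf("DOM re-verification failed for %s", d$key),
        class = c("haystack_internal_error", "error")))
    }
    list(motif = d$motif, match = q,
         significance = significance_report(q$a, store$size_a, store$size_b,
                                            c_traversed),
         level = d$level)
  })
  structure(list(
    doms = dom_out,
    c_traversed = c_traversed,
    levels = do.call(rbind, level_rows),
    dom_threshold = thr,
    config = config,
    size_a = store$size_a,
    size_b = store$size_b
  ), class = "haystack_result")
}

#' @export
print.haystack_result <- function(x, ...) {
  cat("<haystack search> C = ", format(x$c_traversed, big.mark = ","),
      " motifs traversed, ", length(x$doms), " DOM(s) (threshold a >= ",
      x$dom_threshold, ", b = 0)\n", sep = "")
  for (d in head(x$doms, 10L)) {
    cat("  ", format(d$motif), "  a = ", d$match$a, ", b = ", d$match$b,
        ", sequences = ", length(d$match$matched_record_ids),
        ", Mev = ", signif(d$significance$mev, 3), "\n", sep = "")
  }
  if (length(x$doms) > 10L) cat("  ...\n")
  invisible(x)
}

#' Export search results as a DOM table
#'
#' @param result A `haystack_result`.
#' @return A data.frame with one row per DOM: motif string, `a`, `b`,
#'   matched sequence count, `ml`, `mev`, `neg_ln_mev`, discovery
#'   `level`.
#' @export
dom_table <- function(result) {
  stopifnot(inherits(result, "haystack_result"))
  if (length(result$doms) == 0L) {
    return(data.frame(motif = character(0), a = integer(0), b = integer(0),
                      n_sequences = integer(0), ml = numeric(0),
                      mev = numeric(0), neg_ln_mev = numeric(0),
                      level = integer(0)))
  }
  do.call(rbind, lapply(result$doms, function(d) {
    data.frame(motif = format(d$motif), a = d$match$a, b = d$match$b,
               n_sequences = length(d$match$matched_record_ids),
               ml = d$significance$ml_value, mev = d$significance$mev,
               neg_ln_mev = d$significance$neg_ln_mev, level = d$level)
  }))
}
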