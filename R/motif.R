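# Position-specific gapped motifs.
#
# A motif is an ordered set of components, each an explicit motif
# subsequence (EMS) plus an integer offset counting residues to the LEFT
# of the first CDR3 residue: offset 0 means the component begins on the
# first CDR3 residue, offset 14 means it begins 14 residues upstream.
# In CDR3-relative coordinates (position 0 = first CDR3 residue) a
# component (ems, offset) occupies the contiguous run
# -offset .. -offset + nchar(ems) - 1.
#
# Canonical form: components sorted by decreasing offset (leftmost
# first); overlapping-consistent or directly adjacent components are
# fused into one, so a gap always contains at least one unspecified
# position and gap_count = cardinality - 1.

# Trusted single-component constructor (inputs already validated).
.motif1 <- function(ems, offset) {
  structure(list(ems = ems, offset = as.integer(offset)),
            class = "haystack_motif")
}

# Build a canonical motif from raw component vectors, or return NULL if
# two components claim the same position with different residues.
.motif_build <- function(ems, offset) {
  if (length(ems) == 1L) return(.motif1(ems, offset))
  pos <- integer(0)
  res <- character(0)
  for (i in seq_along(ems)) {
    pos <- c(pos, seq.int(-offset[i], length.out = nchar(ems[i])))
    res <- c(res, strsplit(ems[i], "", fixed = TRUE)[[1]])
  }
  o <- order(pos)
  pos <- pos[o]
  res <- res[o]
  if (anyDuplicated(pos)) {
    first <- match(pos, pos)
    if (any(res != res[first])) return(NULL)
    keep <- !duplicated(pos)
    pos <- pos[keep]
    res <- res[keep]
  }
  brk <- which(diff(pos) != 1L)
  starts_i <- c(1L, brk + 1L)
  ends_i <- c(brk, length(pos))
  ems2 <- character(length(starts_i))
  for (g in seq_along(starts_i)) {
    ems2[g] <- paste(res[starts_i[g]:ends_i[g]], collapse = "")
  }
  structure(list(ems = ems2, offset = -pos[starts_i]),
            class = "haystack_motif")
}

.check_residues <- function(x, what = "EMS") {
  bad <- !grepl(sprintf("^[%s]+$", paste(amino_acids(), collapse = "")), x)
  if (any(bad)) {
    .parse_error(sprintf("%s %s contains characters outside the 20 standard amino-acid codes",
                         what, paste(sQuote(x[bad]), collapse = ", ")))
  }
  invisible(x)
}

#' Construct a position-specific gapped motif
#'
#' @param ems Character vector of explicit motif subsequences, each at
#'   least 3 residues long, over the 20-letter amino-acid alphabet.
#' @param offset Integer vector (same length as `ems`): residues to the
#'   left of the first CDR3 residue at which each subsequence starts
#'   (0 = starts on the first CDR3 residue; negative values start inside
#'   the CDR3).
#' @return A canonical `haystack_motif`: components sorted by decreasing
#'   offset, adjacent/overlapping-consistent components fused.
#' @export
#' @examples
#' motif(c("TNE", "DTA", "CAR"), c(14, 6, 0))
motif <- function(ems, offset) {
  if (length(ems) == 0L) .parse_error("a motif needs at least one component")
  if (length(ems) != length(offset)) {
    .parse_error("ems and offset must have the same length")
  }
  .check_residues(ems)
  if (any(nchar(ems) < 3L)) {
    .parse_error("every motif component must be at least 3 residues long")
  }
  offset <- as.integer(offset)
  if (anyNA(offset)) .parse_error("offsets must be integers")
  m <- .motif_build(ems, offset)
  if (is.null(m)) {
    .conflict_error("components place different residues on the same position")
  }
  m
}

#' Parse a motif from parenthesis notation
#'
#' Parses strings such as `"(TNE, 14), (DTA, 6), (CAR, 0)"`, where
#' `(S, x)` is a non-gapped subsequence `S` starting `x` residues to the
#' left of the first CDR3 residue.
#'
#' @param text A single string in parenthesis notation; whitespace is
#'   flexible.
#' @return A canonical [motif()].
#' @export
#' @examples
#' parse_motif("(TNE, 14), (DTA, 6), (CAR,0)")
parse_motif <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    .parse_error("motif text must be a single non-empty string")
  }
  groups <- regmatches(text, gregexpr("\\(([^()]*)\\)", text))[[1]]
  remainder <- gsub("\\(([^()]*)\\)", "", text)
  if (length(groups) == 0L || grepl("[^,[:space:]]", remainder)) {
    .parse_error(sprintf("cannot parse motif text %s: expected comma-separated '(EMS, offset)' groups",
                         sQuote(text)))
  }
  ems <- character(length(groups))
  off <- integer(length(groups))
  for (i in seq_along(groups)) {
    inner <- sub("^\\(", "", sub("\\)$", "", groups[i]))
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    if (length(parts) != 2L || !grepl("^-?[0-9]+$", parts[2])) {
      .parse_error(sprintf("malformed motif group %s", sQuote(groups[i])))
    }
    .check_residues(parts[1], what = sprintf("group %s:", sQuote(groups[i])))
    ems[i] <- parts[1]
    off[i] <- as.integer(parts[2])
  }
  motif(ems, off)
}

#' @export
format.haystack_motif <- function(x, ...) {
  paste0("(", x$ems, ", ", x$offset, ")", collapse = ", ")
}

#' @export
print.haystack_motif <- function(x, ...) {
  cat("<motif> ", format(x), "  [", gap_count(x), " gap(s), ",
      explicit_length(x), " explicit residues]\n", sep = "")
  invisible(x)
}

#' @export
as.character.haystack_motif <- function(x, ...) format(x)

#' Number of gaps in a motif
#'
#' In canonical form a motif with `n + 1` components has exactly `n`
#' gaps (runs of at least one unspecified position between components).
#'
#' @param m A [motif()].
#' @return Non-negative integer.
#' @export
gap_count <- function(m) {
  stopifnot(inherits(m, "haystack_motif"))
  length(m$ems) - 1L
}

#' Total number of explicitly specified residues in a motif
#'
#' @param m A [motif()].
#' @return Integer `>= 3`: the sum of component subsequence lengths
#'   (gap positions are not counted).
#' @export
explicit_length <- function(m) {
  stopifnot(inherits(m, "haystack_motif"))
  sum(nchar(m$ems))
}

# CDR3-relative positions occupied by the motif, with residues as names.
.motif_positions <- function(m) {
  pos <- integer(0)
  res <- character(0)
  for (i in seq_along(m$ems)) {
    pos <- c(pos, seq.int(-m$offset[i], length.out = nchar(m$ems[i])))
    res <- c(res, strsplit(m$ems[i], "", fixed = TRUE)[[1]])
  }
  names(pos) <- res
  pos
}

#' Match a motif against CDR3-anchored sequences
#'
#' A sequence matches when every occupied CDR3-relative position lies
#' inside the sequence and carries exactly the component's residue.
#' Positions falling outside the sequence mean "no match", never an
#' error.
#'
#' @param m A [motif()].
#' @param aa_sequence Character vector of amino-acid sequences.
#' @param cdr3_start Integer vector (recycled if length 1): 0-based index
#'   of the first CDR3 residue within each sequence.
#' @return Logical vector, one element per sequence.
#' @export
#' @examples
#' m <- parse_motif("(CAR, 0)")
#' motif_matches(m, c("AVYYCARDFDYW", "AVYYCQRDFDYW"), cdr3_start = 5)
motif_matches <- function(m, aa_sequence, cdr3_start) {
  stopifnot(inherits(m, "haystack_motif"))
  n <- nchar(aa_sequence)
  cdr3_start <- rep_len(as.integer(cdr3_start), length(aa_sequence))
  ok <- rep(TRUE, length(aa_sequence))
  for (i in seq_along(m$ems)) {
    len <- nchar(m$ems[i])
    start0 <- cdr3_start - m$offset[i]          # 0-based start in sequence
    inb <- !is.na(start0) & start0 >= 0L & (start0 + len) <= n
    frag <- substr(aa_sequence, start0 + 1L, start0 + len)
    ok <- ok & inb & (frag == m$ems[i])
    if (!any(ok)) break
  }
  ok & !is.na(ok)
}

#' Lengthen one motif component by a single residue
#'
#' The elementary "EMS extension" move of the motif network: one residue
#' is appended at the N-terminal (leftward; the component's offset grows
#' by 1) or C-terminal (rightward; offset unchanged) end of a chosen
#' component. If the extension lands on a position already occupied by
#' another component with the same residue, the two components fuse; a
#' conflicting residue raises a `haystack_conflict` error (the search
#' treats it as a prune signal).
#'
#' @param m A [motif()].
#' @param component_index Which component to extend (1-based, in
#'   canonical order: decreasing offset).
#' @param side `"N"` (leftward) or `"C"` (rightward).
#' @param residue A single standard amino-acid letter.
#' @return The canonicalized extended motif.
#' @export
#' @examples
#' ems_extend(motif("CAT", 14), 1, "C", "P")   # -> (CATP, 14)
#' ems_extend(motif("SSD", 6), 1, "N", "R")    # -> (RSSD, 7)
ems_extend <- function(m, component_index, side = c("N", "C"), residue) {
  stopifnot(inherits(m, "haystack_motif"))
  side <- match.arg(side)
  if (!is.character(residue) || length(residue) != 1L ||
      nchar(residue) != 1L) {
    .parse_error("residue must be a single letter")
  }
  .check_residues(residue, "residue")
  i <- as.integer(component_index)
  if (is.na(i) || i < 1L || i > length(m$ems)) {
    .parse_error("component_index out of range")
  }
  ems <- m$ems
  offset <- m$offset
  if (side == "N") {
    ems[i] <- paste0(residue, ems[i])
    offset[i] <- offset[i] + 1L
  } else {
    ems[i] <- paste0(ems[i], residue)
  }
  out <- .motif_build(ems, offset)
  if (is.null(out)) {
    .conflict_error("extension conflicts with an existing residue at a shared position")
  }
  out
}

#' Append a new atomic component to a motif
#'
#' The "cardinality extension" move: a new length-3 component is added,
#' increasing the gap count by one. The new component must be disjoint
#' from, and not directly adjacent to, every existing component (a gap
#' needs at least one unspecified position); overlapping or adjacent
#' placements must go through [merge_motifs()] instead.
#'
#' @param m A [motif()].
#' @param ems The new component's subsequence (>= 3 residues).
#' @param offset The new component's leftward offset.
#' @return The canonicalized motif with one more component.
#' @export
#' @examples
#' cardinality_extend(motif("CATP", 14), "SSD", 6)
cardinality_extend <- function(m, ems, offset) {
  stopifnot(inherits(m, "haystack_motif"))
  .check_residues(ems)
  if (nchar(ems) < 3L) .parse_error("an atomic component has at least 3 residues")
  offset <- as.integer(offset)
  occ <- .motif_positions(m)
  newpos <- seq.int(-offset, length.out = nchar(ems))
  if (any(newpos %in% occ)) {
    .conflict_error("new component overlaps an existing one; use merge_motifs()")
  }
  if (any((newpos + 1L) %in% occ) || any((newpos - 1L) %in% occ)) {
    .conflict_error("new component is adjacent to an existing one (no gap); use merge_motifs()")
  }
  out <- .motif_build(c(m$ems, ems), c(m$offset, offset))
  stopifnot(!is.null(out))
  out
}

# Merge that returns NULL on residue conflict (internal prune path).
.merge_or_null <- function(m1, m2) {
  .motif_build(c(m1$ems, m2$ems), c(m1$offset, m2$offset))
}

# Hot-path merge of ONE component (ems2, off2) into canonical motif m,
# by interval arithmetic: overlapping/adjacent components fuse into one
# buffer string, disjoint ones are inserted in canonical order.
# Returns NULL on residue conflict.
.merge1 <- function(m, ems2, off2) {
  s2 <- -off2
  e2 <- s2 + nchar(ems2) - 1L
  starts <- -m$offset
  ends <- starts + nchar(m$ems) - 1L
  grp <- which(starts <= e2 + 1L & ends >= s2 - 1L)
  if (length(grp) == 0L) {
    ems <- c(m$ems, ems2)
    off <- c(m$offset, as.integer(off2))
    ord <- order(off, decreasing = TRUE)
    return(structure(list(ems = ems[ord], offset = off[ord]),
                     class = "haystack_motif"))
  }
  ns <- min(s2, starts[grp])
  ne <- max(e2, ends[grp])
  buf <- strrep(" ", ne - ns + 1L)
  substr(buf, s2 - ns + 1L, e2 - ns + 1L) <- ems2
  for (g in grp) {
    substr(buf, starts[g] - ns + 1L, ends[g] - ns + 1L) <- m$ems[g]
  }
  # m's components wrote last, so a conflict shows up as a changed ems2
  if (substr(buf, s2 - ns + 1L, e2 - ns + 1L) != ems2) return(NULL)
  keep <- setdiff(seq_along(m$ems), grp)
  ems <- c(m$ems[keep], buf)
  off <- c(m$offset[keep], -ns)
  ord <- order(off, decreasing = TRUE)
  structure(list(ems = ems[ord], offset = as.integer(off[ord])),
            class = "haystack_motif")
}

#' Merge two motifs
#'
#' Takes the union of the two motifs' position-to-residue maps.
#' Components that overlap consistently or sit adjacent are fused into
#' longer subsequences (the EMS-extension analogue); disjoint components
#' are appended (the cardinality-extension analogue). Overlapping
#' positions with conflicting residues raise a `haystack_conflict`
#' error, which the search treats as a prune signal.
#'
#' @param m1,m2 Motifs ([motif()]).
#' @return The canonical merged motif.
#' @export
#' @examples
#' merge_motifs(motif("SSD", 6), motif("RSS", 7))  # -> (RSSD, 7)
merge_motifs <- function(m1, m2) {
  stopifnot(inherits(m1, "haystack_motif"), inherits(m2, "haystack_motif"))
  out <- .merge_or_null(m1, m2)
  if (is.null(out)) {
    .conflict_error("motifs place different residues on a shared position")
  }
  out
}

#' Serialize / deserialize a motif as JSON
#'
#' The JSON form is `{"components": [{"ems": ..., "offset": ...}, ...]}`.
#'
#' @param m A [motif()].
#' @param json A JSON string produced by `motif_to_json()`.
#' @return `motif_to_json()` a JSON string; `motif_from_json()` a motif.
#' @export
motif_to_json <- function(m) {
  stopifnot(inherits(m, "haystack_motif"))
  jsonlite::toJSON(list(components = data.frame(ems = m$ems, offset = m$offset)),
                   auto_unbox = TRUE)
}

#' @rdname motif_to_json
#' @export
motif_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  motif(x$components$ems, x$components$offset)
}

# Canonical string key used for visited-set bookkeeping.
.motif_key <- function(m) format(m)

# Coerce a motif given as string or motif object.
.as_motif <- function(m) {
  if (inherits(m, "haystack_motif")) m else parse_motif(m)
}
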