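# Motif model: parsing, canonical form, match semantics, extension and
# merge operators.

test_that("parenthesis notation parses to canonical components", {
  m <- parse_motif("(TNE, 14), (DTA, 6), (CAR,0)")
  expect_s3_class(m, "haystack_motif")
  expect_equal(m$ems, c("TNE", "DTA", "CAR"))
  expect_equal(m$offset, c(14L, 6L, 0L))
  expect_equal(gap_count(m), 2L)
  expect_equal(explicit_length(m), 9L)

  single <- parse_motif("(CAT, 1)")
  expect_equal(single$ems, "CAT")
  expect_equal(single$offset, 1L)
  expect_equal(gap_count(single), 0L)
})

test_that("malformed motif text is rejected with an informative error", {
  expect_error(parse_motif("CAT 1"), "expected comma-separated")
  expect_error(parse_motif("(CAT)"), "malformed motif group")
  expect_error(parse_motif("(CAT, x)"), "malformed motif group")
  expect_error(parse_motif("(CXT, 1)"), "outside the 20 standard")
  expect_error(parse_motif(""), "non-empty")
  # same position claimed by different residues
  expect_error(motif(c("CAT", "GGG"), c(10, 9)), class = "haystack_conflict")
})

test_that("format/parse round-trips and canonical form is order-invariant", {
  set.seed(42)
  for (i in 1:100) {
    m <- random_motif()
    expect_identical(parse_motif(format(m)), m)
  }
  # permutation of the same components canonicalizes identically
  m1 <- motif(c("TNE", "DTA", "CAR"), c(14, 6, 0))
  m2 <- motif(c("CAR", "TNE", "DTA"), c(0, 14, 6))
  expect_identical(m1, m2)
  # zero-gap adjacency fuses into one component
  fused <- motif(c("CAT", "PQR"), c(10, 7))
  expect_equal(fused$ems, "CATPQR")
  expect_equal(fused$offset, 10L)
  expect_equal(gap_count(fused), 0L)
})

test_that("matching is exact, position-specific, and bounds-safe", {
  # residues at CDR3-relative -14..-12 TNE, -6..-4 DTA, 0..2 CAR
  s <- paste0(strrep("L", 6), "TNE", strrep("L", 5), "DTA", "LLL",
              "CARDFDYW")
  cdr3 <- 20L
  prime <- parse_motif("(TNE, 14), (DTA, 6), (CAR, 0)")
  expect_true(motif_matches(prime, s, cdr3))
  s_mut <- s
  substr(s_mut, 8, 8) <- "Q"              # position -13: N -> Q
  expect_false(motif_matches(prime, s_mut, cdr3))
  # offsets reaching outside the sequence: no match, no error
  expect_false(motif_matches(parse_motif("(TNE, 40)"), s, cdr3))
  expect_false(motif_matches(parse_motif("(CAR, -25)"), s, cdr3))
})

test_that("vectorized matching equals the per-position oracle", {
  set.seed(7)
  for (rep in 1:15) {
    store <- random_store(n_records = 40, seed = rep)
    recs <- store$records
    for (j in 1:8) {
      m <- random_motif(store)
      expect_identical(
        motif_matches(m, recs$sequence_aa, recs$cdr3_start),
        oracle_match(m, recs$sequence_aa, recs$cdr3_start),
        info = sprintf("store %d motif %s", rep, format(m)))
    }
  }
})

test_that("EMS extension lengthens one endpoint with the documented offset shift", {
  expect_identical(ems_extend(motif("CAT", 14), 1, "C", "P"),
                   motif("CATP", 14))
  ext <- ems_extend(motif("SSD", 6), 1, "N", "R")
  expect_identical(ext, motif("RSSD", 7))
  # the occupied set grows by exactly the position left-adjacent to the
  # old start
  old <- -(6):(-(6) + 2)
  new <- -(7):(-(7) + 3)
  expect_setequal(setdiff(new, old), min(old) - 1L)
  expect_error(ems_extend(motif("CAT", 1), 1, "C", "BZ"), "single letter")
  expect_error(ems_extend(motif("CAT", 1), 5, "C", "P"), "out of range")
})

test_that("cardinality extension adds a gap and rejects overlap/adjacency", {
  m <- cardinality_extend(motif("CATP", 14), "SSD", 6)
  expect_equal(gap_count(m), 1L)
  expect_equal(m$ems, c("CATP", "SSD"))
  expect_error(cardinality_extend(motif("CATP", 14), "SSD", 13),
               class = "haystack_conflict")   # overlap
  expect_error(cardinality_extend(motif("CATP", 14), "SSD", 10),
               class = "haystack_conflict")   # adjacent, no gap
  # k cardinality extensions of an atomic give k gaps
  m <- motif("AAA", 20)
  for (k in 1:3) m <- cardinality_extend(m, "CCC", 20 - 5L * k)
  expect_equal(gap_count(m), 3L)
})

test_that("merging fuses consistent overlaps and rejects conflicts", {
  expect_identical(merge_motifs(motif("CATP", 14), motif("SSD", 6)),
                   motif(c("CATP", "SSD"), c(14, 6)))
  expect_identical(merge_motifs(motif("SSD", 6), motif("RSS", 7)),
                   motif("RSSD", 7))
  m <- parse_motif("(TNE, 14), (DTA, 6)")
  expect_identical(merge_motifs(m, m), m)
  expect_error(merge_motifs(motif("CAT", 10), motif("GGG", 9)),
               class = "haystack_conflict")
})

test_that("fast single-component merge agrees with the general merge", {
  set.seed(99)
  for (i in 1:300) {
    m <- random_motif()
    ems2 <- random_sequence(sample(3:4, 1))
    off2 <- sample(-5:20, 1)
    general <- haystack:::.merge_or_null(m, motif(ems2, off2))
    fast <- haystack:::.merge1(m, ems2, off2)
    expect_identical(fast, general,
                     info = sprintf("%s + (%s, %d)", format(m), ems2, off2))
  }
})

test_that("extension and merge operators never enlarge the match set", {
  set.seed(13)
  for (rep in 1:10) {
    store <- random_store(n_records = 50, seed = 100 + rep)
    recs <- store$records
    m <- random_motif(store)
    base <- motif_matches(m, recs$sequence_aa, recs$cdr3_start)
    ops <- list(
      function(m) ems_extend(m, sample(length(m$ems), 1),
                             sample(c("N", "C"), 1), sample(AA, 1)),
      function(m) cardinality_extend(m, random_sequence(3),
                                     max(m$offset) + nchar(m$ems[1]) + 5L),
      function(m) merge_motifs(m, motif(random_sequence(3),
                                        min(m$offset) - 8L))
    )
    for (op in ops) {
      m2 <- tryCatch(op(m), haystack_conflict = function(e) NULL,
                     haystack_parse_error = function(e) NULL)
      if (is.null(m2)) next
      after <- motif_matches(m2, recs$sequence_aa, recs$cdr3_start)
      expect_true(all(base[after]),
                  info = sprintf("%s -> %s", format(m), format(m2)))
    }
  }
})

test_that("motifs serialize to JSON and back", {
  m <- parse_motif("(TNE, 14), (DTA, 6), (CAR, 0)")
  expect_identical(motif_from_json(motif_to_json(m)), m)
})

test_that("the four-step construction pathway yields the two-gap 11-mer", {
  m <- motif("CAT", 15)
  m <- ems_extend(m, 1, "C", "P")
  m <- cardinality_extend(m, "SSD", 8)
  m <- ems_extend(m, 2, "N", "R")
  m <- cardinality_extend(m, "CAT", 0)
  expect_identical(m, parse_motif("(CATP, 15), (RSSD, 9), (CAT, 0)"))
  expect_equal(gap_count(m), 2L)
  expect_equal(explicit_length(m), 11L)
})
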