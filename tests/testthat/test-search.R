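# The breadth-first DOM search: thresholds, seeding, restriction,
# merging, stop policies, determinism.

test_that("the DOM count threshold is the floor of Dt * |A|", {
  expect_equal(dom_count_threshold(0.6, 51), 30L)
  expect_equal(dom_count_threshold(1.0, 10), 10L)
  expect_equal(dom_count_threshold(0.6, 10), 6L)
  expect_equal(dom_count_threshold(0.6, 20), 12L)  # guards 0.6 * 20 != 12
  expect_equal(dom_count_threshold(0.3, 7), 2L)
})

test_that("separation scores follow the configured objective", {
  cfg <- search_config()
  expect_equal(separation_score(list(a = 20, b = 3), cfg), 17)
  expect_equal(separation_score(list(a = 0, b = 0), cfg), 0)
  blind <- search_config(objective = "category_blind", st = -1e9,
                         blind_center = 51)
  expect_equal(separation_score(list(a = 30, b = 21), blind), 0)
  expect_equal(separation_score(list(a = 20, b = 21), blind), -100)
})

test_that("triplet tallies equal a per-subject 3-mer scan", {
  store <- sim_store(simulate_repertoire(generator_config(
    n_case = 10, n_control = 10, seqs_per_subject = 12, seed = 19)))
  cfg <- search_config(dt = 0.5, st = 3)
  tal <- tally_triplets(store, cfg)
  thr <- dom_count_threshold(0.5, store$size_a)
  by_subj <- oracle_subject_triplets(store)
  a_subjects <- store$subjects$subject_id[store$subjects$category == "A"]
  counts <- table(unlist(by_subj[a_subjects]))
  expected <- counts[counts >= thr]
  expect_setequal(names(tal), names(expected))
  expect_equal(unname(tal[names(expected)]), unname(as.integer(expected)))
  # alphabet closure
  expect_true(all(names(tal) %in% all_triplets()))
})

test_that("atomic vectors take the a-maximizing offset, ties to smallest", {
  # WWW at offset 3 in 4 case subjects, offset 9 in 2 case subjects
  mk <- function(id, subj, start0) {
    s <- strrep("G", 30)
    substr(s, start0 + 1, start0 + 3) <- "WWW"
    data.frame(sequence_id = id, subject_id = subj, diagnosis = "case",
               sequence_aa = s, cdr3_start = 20L, cdr3_end = 30L)
  }
  rows <- rbind(
    do.call(rbind, lapply(1:4, function(i) mk(paste0("x", i), paste0("A", i), 17L))),
    do.call(rbind, lapply(5:6, function(i) mk(paste0("x", i), paste0("A", i), 11L))),
    data.frame(sequence_id = "b1", subject_id = "B1", diagnosis = "ctrl",
               sequence_aa = strrep("G", 30), cdr3_start = 20L, cdr3_end = 30L))
  store <- repertoire_store(rows, "case")
  expect_identical(make_atomic_vector("WWW", store), motif("WWW", 3))
  # tie: GGG occurs at every offset in all subjects -> smallest offset
  ggg <- make_atomic_vector("GGG", store)
  expect_equal(ggg$ems, "GGG")
  expect_equal(ggg$offset, min(20L - (nchar(strrep("G", 30)) - 3L)))
  expect_null(make_atomic_vector("YYY", store))
})

test_that("non-gapped extension keeps supported one-residue growths", {
  # two case subjects whose sequences read ...CATP... at offset 14
  mk <- function(id, subj) {
    s <- strrep("L", 30)
    substr(s, 7, 10) <- "CATP"     # offsets 14..11 relative to CDR3 at 20
    data.frame(sequence_id = id, subject_id = subj, diagnosis = "case",
               sequence_aa = s, cdr3_start = 20L, cdr3_end = 30L)
  }
  store <- repertoire_store(rbind(mk("r1", "A1"), mk("r2", "A2")), "case")
  L <- extend_nongapped(motif("CAT", 14), store, search_config(st = 0))
  keys <- vapply(L, format, "")
  expect_true("(CAT, 14)" %in% keys)
  expect_true("(CATP, 14)" %in% keys)
  expect_true("(LCAT, 15)" %in% keys)
  # every extension matches a subset of the parent's records
  recs <- store$records
  parent <- motif_matches(motif("CAT", 14), recs$sequence_aa, recs$cdr3_start)
  for (m in L) {
    child <- motif_matches(m, recs$sequence_aa, recs$cdr3_start)
    expect_true(all(parent[child]))
  }
})

test_that("recursive restriction surfaces co-occurring components", {
  store <- decoy_store()
  cfg <- search_config(dt = 1.0, st = 3, gc = 2)
  lp <- recursive_restriction("(TNE, 14)", store, cfg)
  keys <- vapply(lp, format, "")
  expect_true("(DTA, 6)" %in% keys)
  expect_false(any(grepl("KKK", keys)))   # control-only decoy never tallies
  # restriction of a motif matching a single subject yields nothing
  # under any St >= 2
  one <- repertoire_store(store$records[1:2], "case")
  expect_length(recursive_restriction("(TNE, 14)", one,
                                      search_config(dt = 1, st = 2)), 0L)
})

test_that("a conjunction-only DOM is found via restriction and merging", {
  store <- decoy_store()
  res <- haystack_search(store, search_config(dt = 1.0, st = 3, gc = 2))
  expect_gt(length(res$doms), 0L)
  keys <- vapply(res$doms, function(d) format(d$motif), "")
  expect_true("(TNE, 14), (DTA, 6)" %in% keys)
  for (d in res$doms) {
    expect_equal(d$match$b, 0L)
    expect_gte(d$match$a, res$dom_threshold)
    expect_gt(d$level, 0L)   # no single component separates the cohorts
  }
  # the DOMs carry the run's own traversal count in their significance
  expect_equal(res$doms[[1]]$significance$c_motifs, res$c_traversed)
})

test_that("greedy separation pruning can miss an existing DOM", {
  store <- decoy_store()
  # the conjunction is a genuine DOM ...
  q <- query_motif(store, "(TNE, 14), (DTA, 6)")
  expect_equal(q$a, 6L)
  expect_equal(q$b, 0L)
  # ... but with St above the components' separation (3), every path to
  # it is pruned at the seed stage
  res <- haystack_search(store, search_config(dt = 1.0, st = 5, gc = 2))
  expect_length(res$doms, 0L)
})

test_that("the gap bound limits output dimensionality", {
  sim <- simulate_repertoire(generator_config(
    n_case = 8, n_control = 8, seqs_per_subject = 25,
    prevalence_case = 1, carrier_seq_fraction = 0.5, seed = 41))
  store <- sim_store(sim)
  res0 <- haystack_search(store, search_config(dt = 0.6, st = 4, gc = 0))
  expect_gt(length(res0$doms), 0L)
  for (d in res0$doms) expect_equal(gap_count(d$motif), 0L)
})

test_that("searches are deterministic and stop policies nest correctly", {
  store <- decoy_store()
  cfg <- search_config(dt = 1.0, st = 3, gc = 2)
  r1 <- haystack_search(store, cfg)
  r2 <- haystack_search(decoy_store(), cfg)
  expect_identical(dom_table(r1), dom_table(r2))
  expect_equal(r1$c_traversed, r2$c_traversed)

  first <- haystack_search(store, search_config(dt = 1.0, st = 3, gc = 2,
                                                stop_policy = "first_dom"))
  expect_length(first$doms, 1L)
  expect_true(format(first$doms[[1]]$motif) %in%
                vapply(r1$doms, function(d) format(d$motif), ""))

  exhaust <- haystack_search(store, search_config(dt = 1.0, st = 3, gc = 2,
                                                  stop_policy = "exhaust"))
  expect_gte(length(exhaust$doms), length(r1$doms))
  expect_gte(exhaust$c_traversed, r1$c_traversed)
})

test_that("both seed-stage code paths produce identical searches", {
  sim <- simulate_repertoire(generator_config(
    n_case = 6, n_control = 6, seqs_per_subject = 30, seed = 5))
  cfg <- search_config(dt = 0.6, st = 3, gc = 2)
  withr::local_options(haystack.seed_batch_rows = 0L)   # force data.table
  r_dt <- haystack_search(sim_store(sim), cfg)
  withr::local_options(haystack.seed_batch_rows = .Machine$integer.max)
  r_base <- haystack_search(sim_store(sim), cfg)
  expect_identical(dom_table(r_dt), dom_table(r_base))
  expect_equal(r_dt$c_traversed, r_base$c_traversed)
  expect_equal(r_dt$levels, r_base$levels)
})

test_that("a planted disease-only motif is recovered end to end", {
  sim <- simulate_repertoire(generator_config(
    n_case = 10, n_control = 10, seqs_per_subject = 60,
    prevalence_case = 0.8, carrier_seq_fraction = 0.2,
    point_mutation_rate = 0.005, seed = 11))
  store <- sim_store(sim)
  cfg <- search_config(dt = 0.5, st = 4, gc = 2)
  res <- haystack_search(store, cfg)
  expect_gt(length(res$doms), 0L)
  carriers <- sim$manifest$subjects$subject_id[sim$manifest$subjects$carrier]
  coverage <- vapply(res$doms, function(d) {
    mean(carriers %in% d$match$matched_subjects_a)
  }, numeric(1))
  expect_gte(max(coverage), 0.9)
  # swapped categories: the planted signal is one-sided, so anything
  # reported in the reverse direction is a multiple-testing artifact of
  # the small cohort, and the run's own Mev bound flags it as such
  rev_store <- repertoire_store(sim$records, "healthy")
  rev_res <- haystack_search(rev_store, cfg)
  for (d in rev_res$doms) expect_gt(d$significance$mev, 1)
})
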