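# toy corpus from the four-release missing-origin walk-through:
# lineage A holds s at v1-v2, B acquires it at v2, A loses it at v3,
# B retains it through v3-v4
missing_origin_toy <- function() {
  s <- "the sentence under scrutiny."
  toy_entries(
    toy_entry("v1", "A0001", s),
    toy_entry("v2", "A0001", s),
    toy_entry("v2", "B0001", s),
    toy_entry("v3", "A0001"),
    toy_entry("v3", "B0001", s),
    toy_entry("v4", "A0001"),
    toy_entry("v4", "B0001", s))
}

test_that("traces order releases by date and carry origin and terminal sets", {
  idx <- build_index(missing_origin_toy(), cal_sp4())
  tr <- build_trace(idx, "the sentence under scrutiny.")
  expect_equal(names(tr$timeline), c("v1", "v2", "v3", "v4"))
  expect_equal(tr$timeline$v2, c("A0001", "B0001"))
  expect_equal(tr$origin_set, "A0001")
  expect_equal(tr$terminal_set, "B0001")
  expect_error(build_trace(idx, "no such sentence."), "unknown sentence")
  # single occurrence: origin == terminal, timeline of length one
  idx1 <- build_index(toy_entry("v2", "X0001", "lonely."), cal_sp4())
  tr1 <- build_trace(idx1, "lonely.")
  expect_length(tr1$timeline, 1L)
  expect_equal(tr1$origin_set, tr1$terminal_set)
})

test_that("missing-origin detection requires disjoint origin and terminal sets", {
  idx <- build_index(missing_origin_toy(), cal_sp4())
  hits <- detect_missing_origin(idx)
  expect_equal(hits$sentence_text, "the sentence under scrutiny.")
  expect_true(hits$extant)
  ev <- hits$evidence[[1]]
  expect_true(all(ev$lineage_id == "B0001"))
  expect_true("v3" %in% ev$release_id)
  # a sentence persisting in its origin lineage is never flagged
  persistent <- toy_entries(
    toy_entry("v1", "A0001", "stable sentence."),
    toy_entry("v2", "A0001", "stable sentence."),
    toy_entry("v2", "B0001", "stable sentence."),
    toy_entry("v4", "A0001", "stable sentence."))
  expect_equal(nrow(detect_missing_origin(build_index(persistent, cal_sp4()))), 0L)
})

test_that("reappearing detection needs present/absent/present at existing releases", {
  gap <- toy_entries(
    toy_entry("v1", "A0001", "blinks."),
    toy_entry("v2", "A0001"),
    toy_entry("v3", "A0001", "blinks."))
  hits <- detect_reappearing(build_index(gap, cal_sp4()))
  expect_equal(hits$sentence_text, "blinks.")
  expect_equal(hits$evidence[[1]]$release_id, "v3")
  continuous <- toy_entries(
    toy_entry("v1", "A0001", "steady."),
    toy_entry("v2", "A0001", "steady."),
    toy_entry("v3", "A0001", "steady."))
  expect_equal(nrow(detect_reappearing(build_index(continuous, cal_sp4()))), 0L)
})

test_that("unsynchronised calendars do not fabricate absence (no striping)", {
  # sentence lives in a TrEMBL lineage continuously; Swiss-Prot releases
  # interleave between TrEMBL releases but carry "no data", not absence
  cal <- cal_mixed()
  ent <- toy_entries(
    toy_entry("TR_1", "Q0001", "trembl resident."),
    toy_entry("TR_2", "Q0001", "trembl resident."),
    toy_entry("UPKB_1_TR", "Q0001", "trembl resident."))
  idx <- build_index(ent, cal)
  expect_equal(nrow(detect_reappearing(idx)), 0L)
  expect_equal(nrow(detect_transient(idx)), 0L)
})

test_that("transient detection flags single-release appearances with an observable removal", {
  single <- toy_entries(
    toy_entry("v2", "A0001", "fleeting."),
    toy_entry("v3", "A0001"))
  hits <- detect_transient(build_index(single, cal_sp4()))
  expect_equal(hits$sentence_text, "fleeting.")
  expect_equal(hits$evidence[[1]],
               data.frame(lineage_id = "A0001", release_id = "v2",
                          stringsAsFactors = FALSE))
  # an appearance only in the final release is undetectable
  final_only <- toy_entry("v4", "A0001", "latecomer.")
  expect_equal(nrow(detect_transient(build_index(final_only, cal_sp4()))), 0L)
})

test_that("planted transient instances are recovered exactly", {
  k <- 4L
  corpus <- generate_corpus(generator_config(
    seed = 21, planted = c(missing_origin = 0L, reappearing = 0L,
                           transient = k, trembl_origin = 0L)))
  idx <- index_corpus(corpus)
  hits <- detect_transient(idx)
  expect_equal(nrow(hits), k)
  expect_setequal(hits$sentence_text, corpus$manifest$patterns$sentence_text)
})

test_that("TrEMBL-origin detection respects dates and synchronised ties", {
  cal <- cal_mixed()
  ent <- toy_entries(
    toy_entry("TR_1", "Q0001", "born unreviewed."),
    toy_entry("TR_2", "Q0001", "born unreviewed."),
    toy_entry("UPKB_1_TR", "Q0001", "born unreviewed."),
    toy_entry("SP_2", "P0001", "born unreviewed."),
    toy_entry("SP_3", "P0001", "born unreviewed."),
    toy_entry("UPKB_1_SP", "P0001", "born unreviewed."))
  hits <- detect_trembl_origin(build_index(ent, cal))
  expect_equal(hits$sentence_text, "born unreviewed.")
  expect_equal(hits$evidence[[1]]$release_id, "SP_2")
  # simultaneous first appearance in a synchronised pair is ambiguous
  tie <- toy_entries(
    toy_entry("UPKB_1_TR", "Q0001", "simultaneous."),
    toy_entry("UPKB_1_SP", "P0001", "simultaneous."))
  expect_equal(nrow(detect_trembl_origin(build_index(tie, cal))), 0L)
})

test_that("detectors equal brute-force enumeration on toy and generated corpora", {
  for (seed in c(101, 202, 303)) {
    corpus <- generate_corpus(generator_config(
      seed = seed, calendar = small_synthetic_calendar(),
      n_entries = c(SWISSPROT = 12L, TREMBL = 10L), n_merges = 1L))
    idx <- index_corpus(corpus)
    occ <- idx$occurrences
    cal <- idx$calendar
    expect_equal(detector_sentences(detect_missing_origin(idx)),
                 oracle_missing_origin(occ, cal))
    expect_equal(detector_sentences(detect_reappearing(idx)),
                 oracle_reappearing(occ, cal))
    expect_equal(detector_sentences(detect_transient(idx)),
                 oracle_transient(occ, cal))
    expect_equal(detector_sentences(detect_trembl_origin(idx)),
                 oracle_trembl_origin(occ, cal))
  }
})

test_that("relabelling a lineage's accessions changes no hit set", {
  corpus <- generate_corpus(generator_config(
    seed = 13, calendar = small_synthetic_calendar(),
    n_entries = c(SWISSPROT = 10L, TREMBL = 8L), n_merges = 1L))
  renamed <- lapply(corpus$files, function(lines) gsub("MOA001", "ZZZ901", lines))
  ent <- do.call(rbind, lapply(names(renamed), function(rid)
    parse_flatfile(renamed[[rid]], release_id = rid)))
  idx2 <- build_index(ent, corpus$config$calendar)
  idx1 <- index_corpus(corpus)
  h1 <- detect_patterns(idx1); h2 <- detect_patterns(idx2)
  expect_equal(sort(paste(h1$sentence_text, h1$pattern)),
               sort(paste(h2$sentence_text, h2$pattern)))
})

test_that("occurrence timelines count lineages per release and agree with traces", {
  idx <- build_index(missing_origin_toy(), cal_sp4())
  tl <- occurrence_timeline(idx, "the sentence under scrutiny.")
  expect_equal(tl$release_id, c("v1", "v2", "v3", "v4"))
  expect_equal(tl$n_entries, c(1L, 2L, 1L, 1L))
  tr <- build_trace(idx, "the sentence under scrutiny.")
  for (rel in names(tr$timeline))
    expect_equal(tl$n_entries[tl$release_id == rel],
                 length(tr$timeline[[rel]]))
  # single stable occurrence: constant series of one
  stable <- toy_entries(toy_entry("v1", "A0001", "s."),
                        toy_entry("v2", "A0001", "s."))
  tls <- occurrence_timeline(build_index(stable, cal_sp4()), "s.")
  expect_equal(tls$n_entries, c(1L, 1L))
  expect_error(occurrence_timeline(idx, "absent."), "unknown sentence")
})

test_that("every pattern hit satisfies its defining property", {
  corpus <- generate_corpus(generator_config(seed = 31))
  idx <- index_corpus(corpus)
  occ <- idx$occurrences
  mo <- detect_missing_origin(idx)
  for (i in seq_len(nrow(mo))) {
    rows <- occ[occ$sentence_text == mo$sentence_text[i], ]
    origin <- unique(rows$lineage_id[rows$date == min(rows$date)])
    terminal <- unique(rows$lineage_id[rows$date == max(rows$date)])
    expect_length(intersect(origin, terminal), 0L)
  }
  tx <- detect_transient(idx)
  for (i in seq_len(nrow(tx))) {
    ev <- tx$evidence[[i]]
    rows <- occ[occ$sentence_text == tx$sentence_text[i], ]
    for (j in seq_len(nrow(ev))) {
      db <- idx$calendar$database[idx$calendar$release_id == ev$release_id[j]]
      expect_equal(sum(rows$lineage_id == ev$lineage_id[j] &
                       rows$database == db), 1L)
    }
  }
})

test_that("pattern reports serialise hits with their occurrence spans", {
  idx <- build_index(missing_origin_toy(), cal_sp4())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_report(detect_patterns(idx), idx, path)
  rep <- read.delim(path, stringsAsFactors = FALSE)
  mo <- rep[rep$pattern == "MISSING_ORIGIN", ]
  expect_equal(mo$first_release, "v1")
  expect_equal(mo$last_release, "v4")
  expect_equal(mo$n_entries_ever, 2L)
  expect_true(mo$extant_flag)
})
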