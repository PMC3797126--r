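test_that("merged accessions collapse into one lineage across releases", {
  ent <- toy_entries(
    toy_entry("v1", "A0001", "shared sentence one."),
    toy_entry("v1", "B0001", "other sentence."),
    toy_entry("v2", "A0001", c("shared sentence one.", "other sentence."),
              secondaries = "B0001"))
  idx <- build_index(ent, cal_sp4())
  expect_equal(nrow(idx$lineages), 1L)
  expect_setequal(idx$lineages$accessions[[1]], c("A0001", "B0001"))
  # lineage id is stable: the smallest member accession
  expect_equal(idx$lineages$lineage_id, "A0001")
  # same sentence via either accession is one triple per release
  expect_equal(nrow(idx$occurrences), 4L)
})

test_that("lineage linking is transitive across release chains", {
  ent <- toy_entries(
    toy_entry("v1", "C0001", "s one."),
    toy_entry("v2", "B0001", "s one.", secondaries = "C0001"),
    toy_entry("v3", "A0001", "s one.", secondaries = "B0001"))
  idx <- build_index(ent, cal_sp4())
  expect_equal(idx$lineages$lineage_id, "A0001")
  expect_setequal(idx$lineages$accessions[[1]], c("A0001", "B0001", "C0001"))
})

test_that("an accession claimed by two concurrent entries is a conflict", {
  ent <- toy_entries(
    toy_entry("v1", "A0001", "s."),
    toy_entry("v1", "B0001", "t.", secondaries = "A0001"))
  expect_error(build_index(ent, cal_sp4()),
               "accession A0001 claimed by two entries \\(A0001 and B0001\\) in release v1")
})

test_that("an empty corpus yields an empty index", {
  ent <- parse_flatfile(character(0), release_id = character(0))
  idx <- build_index(ent, cal_sp4())
  expect_equal(nrow(idx$occurrences), 0L)
  expect_equal(unname(corpus_counts(idx, "v1")), c(0, 0, 0))
})

test_that("corpus counts match hand-derived totals and brute force", {
  # E1 = {s1, s2}, E2 = {s1}
  ent <- toy_entries(
    toy_entry("v1", "E0001", c("s one.", "s two.")),
    toy_entry("v1", "E0002", "s one."))
  idx <- build_index(ent, cal_sp4())
  expect_equal(corpus_counts(idx, "v1"),
               c(total = 3, unique = 2, singleton = 1))
  expect_equal(unname(corpus_counts(idx, "v2")), c(0, 0, 0))
  expect_error(corpus_counts(idx, "nope"), "unknown release")
  # brute-force agreement on a generated three-release corpus
  corpus <- generate_corpus(generator_config(
    seed = 11, calendar = cal_sp4(), n_entries = c(SWISSPROT = 10L, TREMBL = 0L),
    planted = c(missing_origin = 1L, reappearing = 1L, transient = 1L,
                trembl_origin = 0L), n_merges = 1L))
  idx2 <- index_corpus(corpus)
  for (rel in idx2$calendar$release_id)
    expect_equal(corpus_counts(idx2, rel),
                 oracle_counts(idx2$occurrences, rel))
})

test_that("entry statistics separate annotated from unannotated entries", {
  ent <- toy_entries(
    toy_entry("v1", "E0001", c("a.", "b.", "c.")),
    toy_entry("v1", "E0002", "a."),
    toy_entry("v1", "E0003"),
    toy_entry("v1", "E0004"))
  idx <- build_index(ent, cal_sp4())
  es <- entry_stats(idx, "v1")
  expect_equal(es$avg_sentences_per_entry, 2.0)
  expect_equal(es$pct_unannotated, 50)
  # all annotated
  ent2 <- toy_entries(toy_entry("v1", "E0001", "a."),
                      toy_entry("v1", "E0002", "b."))
  expect_equal(entry_stats(build_index(ent2, cal_sp4()), "v1")$pct_unannotated, 0)
  # empty release: both undefined
  es_empty <- entry_stats(idx, "v2")
  expect_true(is.na(es_empty$avg_sentences_per_entry))
  expect_true(is.na(es_empty$pct_unannotated))
})

test_that("average entries per sentence is the unweighted mean over unique sentences", {
  ent <- toy_entries(
    toy_entry("v1", "E0001", "s one."),
    toy_entry("v1", "E0002", "s one."),
    toy_entry("v1", "E0003", c("s one.", "s two.")))
  idx <- build_index(ent, cal_sp4())
  expect_equal(sentence_stats(idx, "v1"), 2.0)   # s1 in 3 entries, s2 in 1
  expect_true(is.na(sentence_stats(idx, "v2")))
  ent2 <- toy_entries(toy_entry("v1", "E0001", "only."))
  expect_equal(sentence_stats(build_index(ent2, cal_sp4()), "v1"), 1.0)
})

test_that("reuse histogram reconciles with the corpus counts", {
  ent <- toy_entries(
    toy_entry("v1", "E0001", "s one."),
    toy_entry("v1", "E0002", "s one."),
    toy_entry("v1", "E0003", c("s one.", "s two.")),
    toy_entry("v1", "E0004", "s three."))
  idx <- build_index(ent, cal_sp4())
  h <- reuse_histogram(idx, "v1")
  expect_equal(h, data.frame(occurrence_count = c(1L, 3L),
                             n_sentences = c(2L, 1L)))
  expect_equal(nrow(reuse_histogram(idx, "v2")), 0L)
  # conservation identities on generated corpora
  corpus <- generate_corpus(generator_config(seed = 5))
  idx2 <- index_corpus(corpus)
  for (rel in idx2$calendar$release_id) {
    cc <- corpus_counts(idx2, rel)
    h <- reuse_histogram(idx2, rel)
    expect_equal(sum(h$n_sentences), unname(cc["unique"]))
    expect_equal(sum(h$occurrence_count * h$n_sentences), unname(cc["total"]))
    expect_true(cc["singleton"] <= cc["unique"])
    expect_true(cc["unique"] <= cc["total"])
  }
})

test_that("per-entry sentence counts conserve the release totals", {
  # merge-free corpus: every record is its own lineage at each release
  corpus <- generate_corpus(generator_config(seed = 9, n_merges = 0L))
  idx <- index_corpus(corpus)
  for (rel in idx$calendar$release_id) {
    per_entry <- idx$entries$n_sentences[idx$entries$release_id == rel]
    expect_equal(sum(per_entry), unname(corpus_counts(idx, rel)["total"]))
  }
})

test_that("the statistics table covers every release and round-trips to TSV", {
  corpus <- generate_corpus(generator_config(seed = 2))
  idx <- index_corpus(corpus)
  tbl <- release_stats(idx)
  expect_equal(tbl$release_id, idx$calendar$release_id)
  expect_equal(tbl$total[tbl$release_id == "2012_05_TR"],
               unname(corpus_counts(idx, "2012_05_TR")["total"]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_release_stats(idx, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$unique, tbl$unique)
})
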