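flat <- function(...) c(...)

test_that("flat-file records are parsed into entries with accessions", {
  lines <- flat(
    "ID   GPX1_HUMAN   Reviewed; 203 AA.",
    "AC   P22352; O43787; Q86W78;",
    "DT   01-MAR-1992, integrated into UniProtKB/Swiss-Prot.",
    "CC   -!- FUNCTION: Protects cells against oxidative damage.",
    "//",
    "ID   YFGA_ECOLI   Unreviewed; 120 AA.",
    "AC   Q46223;",
    "CC   -!- FUNCTION: May have an essential function in",
    "CC       lipopolysaccharides biosynthesis.",
    "//",
    "ID   EMPTY_ENTRY  Reviewed; 88 AA.",
    "AC   P99999;",
    "//")
  ent <- parse_flatfile(lines, release_id = "SP_9")
  expect_equal(nrow(ent), 3L)
  expect_equal(ent$primary_accession, c("P22352", "Q46223", "P99999"))
  expect_equal(ent$secondary_accessions[[1]], c("O43787", "Q86W78"))
  expect_equal(ent$secondary_accessions[[2]], character(0))
  expect_equal(ent$sentences[[2]],
               "may have an essential function in lipopolysaccharides biosynthesis.")
  # absent CC payload
  expect_identical(ent$comment_text[3], "")
  expect_identical(ent$sentences[[3]], character(0))
  # the accession multiset of the input is fully captured
  expect_setequal(
    c(ent$primary_accession, unlist(ent$secondary_accessions)),
    c("P22352", "O43787", "Q86W78", "Q46223", "P99999"))
})

test_that("malformed records are skipped with a warning, or abort in strict mode", {
  lines <- flat("ID   ONLY_ID  Reviewed; 1 AA.", "//",
                "ID   GOOD_ENTRY  Reviewed; 1 AA.", "AC   P00001;", "//")
  expect_warning(ent <- parse_flatfile(lines, "v1"), "malformed record at lines 1-2")
  expect_equal(ent$primary_accession, "P00001")
  expect_error(suppressWarnings(parse_flatfile(lines, "v1", strict = TRUE)),
               "malformed record")
})

test_that("comment cleaning strips headings, properties and the licence block", {
  expect_equal(extract_comment_text("CC   -!- FUNCTION: Inactivated by cyanide."),
               "Inactivated by cyanide.")
  # copyright-only payload vanishes
  copyright_only <- paste(
    "CC   -----------------------------------------------------------------",
    "CC   Copyrighted by the UniProt Consortium.",
    "CC   Distributed under the Creative Commons Attribution License",
    "CC   -----------------------------------------------------------------",
    sep = "\n")
  expect_identical(extract_comment_text(copyright_only), "")
  # two topic blocks joined in order with a single space
  two_blocks <- paste("CC   -!- FUNCTION: Binds calcium ions.",
                      "CC   -!- SUBUNIT: Homodimer of alpha chains.",
                      sep = "\n")
  expect_equal(extract_comment_text(two_blocks),
               "Binds calcium ions. Homodimer of alpha chains.")
  # property keys are dropped, their values survive
  expect_equal(
    extract_comment_text("CC   -!- INTERACTION: Self; NbExp=2; IntAct=EBI-311928, EBI-311928;"),
    "Self; 2; EBI-311928, EBI-311928;")
  # equations with spaced '=' are untouched
  expect_equal(
    extract_comment_text("CC   -!- CATALYTIC ACTIVITY: ATP + undecaprenol = ADP + undecaprenyl phosphate."),
    "ATP + undecaprenol = ADP + undecaprenyl phosphate.")
  # wrapped lines rejoin with single spaces
  wrapped <- paste("CC   -!- FUNCTION: May have an essential function in",
                   "CC       lipopolysaccharides biosynthesis.", sep = "\n")
  expect_equal(extract_comment_text(wrapped),
               "May have an essential function in lipopolysaccharides biosynthesis.")
})

test_that("sentence segmentation honours stops, fragments and abbreviations", {
  two <- split_sentences(paste(
    "The active-site selenocysteine is encoded by the opal codon, uga.",
    "The active-site is not encoded by the opal codon uga but by ugc."))
  expect_length(two, 2L)
  expect_identical(split_sentences(""), character(0))
  expect_equal(split_sentences("Belongs to the ycf50 family"),
               "Belongs to the ycf50 family")
  # abbreviations and decimals do not split
  expect_length(split_sentences("Binds e.g. calcium. Requires 1.5 mM zinc."), 2L)
  expect_length(split_sentences("Described by Smith et al. in liver tissue."), 1L)
  expect_length(split_sentences("Binds approx. two ions per subunit."), 1L)
  expect_length(split_sentences("Found in B. subtilis only."), 1L)
  # vector input: each element is its own block
  expect_equal(
    split_sentences(c("Self; 2; EBI-1, EBI-1;", "Belongs to the ycf50 family")),
    c("Self; 2; EBI-1, EBI-1;", "Belongs to the ycf50 family"))
})

test_that("normalisation lowercases, squeezes whitespace and is idempotent", {
  expect_equal(normalize_sentence("  Heme-thiolate.  "), "heme-thiolate.")
  expect_equal(
    normalize_sentence("May have an essential function in lipopolysaccharides biosynthesis."),
    "may have an essential function in lipopolysaccharides biosynthesis.")
  x <- c("Two  spaces   here.", "already normalised.")
  expect_identical(normalize_sentence(normalize_sentence(x)),
                   normalize_sentence(x))
  expect_error(normalize_sentence("   "), "whitespace-only")
})

test_that("segmentation conserves every non-heading word in order", {
  texts <- c(
    "Binds calcium. Requires e.g. 1.5 mM zinc for activity. Belongs to the ycf50 family",
    "Heme-thiolate. Composed of 14 different subunits.",
    "Self; 2; EBI-1, EBI-1;")
  for (txt in texts) {
    sent <- split_sentences(txt)
    expect_identical(strsplit(paste(sent, collapse = " "), " ")[[1]],
                     strsplit(txt, " ")[[1]])
  }
})

test_that("per-release sentence TSVs carry one ranked row per occurrence", {
  lines <- flat("ID   A_TEST  Reviewed; 1 AA.", "AC   P00001;",
                "CC   -!- FUNCTION: First point. Second point.", "//")
  ent <- parse_flatfile(lines, "v1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sentence_tsv(ent, path)
  tsv <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(tsv$sentence_text, c("first point.", "second point."))
  expect_equal(tsv$sentence_rank, 1:2)
  expect_equal(unique(tsv$primary_accession), "P00001")
})
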