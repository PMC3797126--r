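# Hand-built toy corpora used across the unit tests.

# a parsed-entries row without going through flat-file text
toy_entry <- function(release_id, acc, sentences = character(0),
                      secondaries = character(0)) {
  out <- data.frame(release_id = release_id, primary_accession = acc,
                    stringsAsFactors = FALSE)
  out$secondary_accessions <- list(secondaries)
  out$raw_cc <- ""
  out$comment_text <- paste(sentences, collapse = " ")
  out$sentences <- list(sentences)
  out
}

toy_entries <- function(...) do.call(rbind, list(...))

# four yearly Swiss-Prot releases
cal_sp4 <- function() {
  release_calendar(paste0("v", 1:4), "SWISSPROT",
                   as.Date("1990-01-01") + (0:3) * 365, "PRE_CONSORTIUM")
}

# unsynchronised two-database calendar ending in a synchronised pair
cal_mixed <- function() small_synthetic_calendar()

occ_triples <- function(index) {
  got <- index$occurrences[, c("sentence_text", "lineage_id", "release_id")]
  got <- got[order(got$sentence_text, got$release_id, got$lineage_id), ]
  rownames(got) <- NULL
  got
}
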