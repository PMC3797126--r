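# Brute-force reference implementations of the pattern definitions and the
# corpus counts, written as direct nested-loop translations of the logical
# definitions. They operate on a plain occurrence table
# (sentence_text, lineage_id, release_id) plus a calendar, independently of
# the package's index structures, and are only usable at toy scale.

oracle_counts <- function(occ, release_id) {
  rows <- occ[occ$release_id == release_id, , drop = FALSE]
  per_sentence <- integer(0)
  for (s in unique(rows$sentence_text))
    per_sentence <- c(per_sentence, sum(rows$sentence_text == s))
  c(total = nrow(rows),
    unique = length(per_sentence),
    singleton = sum(per_sentence == 1L))
}

.o_date <- function(cal, release_id) cal$date[match(release_id, cal$release_id)]
.o_db <- function(cal, release_id) cal$database[match(release_id, cal$release_id)]

oracle_missing_origin <- function(occ, cal) {
  flagged <- character(0)
  for (s in unique(occ$sentence_text)) {
    rows <- occ[occ$sentence_text == s, , drop = FALSE]
    dates <- .o_date(cal, rows$release_id)
    origin <- unique(rows$lineage_id[dates == min(dates)])
    terminal <- unique(rows$lineage_id[dates == max(dates)])
    if (length(intersect(origin, terminal)) > 0L) next
    last_origin <- max(dates[rows$lineage_id %in% origin])
    retained <- FALSE
    for (i in seq_len(nrow(rows)))
      if (!(rows$lineage_id[i] %in% origin) && dates[i] > last_origin)
        retained <- TRUE
    if (retained) flagged <- c(flagged, s)
  }
  sort(flagged)
}

oracle_reappearing <- function(occ, cal) {
  flagged <- character(0)
  for (s in unique(occ$sentence_text)) {
    rows <- occ[occ$sentence_text == s, , drop = FALSE]
    hit <- FALSE
    for (db in c("SWISSPROT", "TREMBL")) {
      rels <- cal$release_id[cal$database == db]
      rels <- rels[order(.o_date(cal, rels))]
      for (lin in unique(rows$lineage_id)) {
        present <- logical(length(rels))
        for (r in seq_along(rels))
          present[r] <- any(rows$release_id == rels[r] & rows$lineage_id == lin)
        for (i in seq_along(rels)) for (j in seq_along(rels)) for (k in seq_along(rels))
          if (i < j && j < k && present[i] && !present[j] && present[k])
            hit <- TRUE
      }
    }
    if (hit) flagged <- c(flagged, s)
  }
  sort(flagged)
}

oracle_transient <- function(occ, cal) {
  flagged <- character(0)
  for (s in unique(occ$sentence_text)) {
    rows <- occ[occ$sentence_text == s, , drop = FALSE]
    hit <- FALSE
    for (db in c("SWISSPROT", "TREMBL")) {
      rels <- cal$release_id[cal$database == db]
      dts <- .o_date(cal, rels)
      for (lin in unique(rows$lineage_id)) {
        at <- rels[rels %in% rows$release_id[rows$lineage_id == lin &
                                             .o_db(cal, rows$release_id) == db]]
        if (length(at) == 1L && any(dts > .o_date(cal, at)))
          hit <- TRUE
      }
    }
    if (hit) flagged <- c(flagged, s)
  }
  sort(flagged)
}

oracle_trembl_origin <- function(occ, cal) {
  flagged <- character(0)
  for (s in unique(occ$sentence_text)) {
    rows <- occ[occ$sentence_text == s, , drop = FALSE]
    dates <- .o_date(cal, rows$release_id)
    dbs <- .o_db(cal, rows$release_id)
    first_all_trembl <- all(dbs[dates == min(dates)] == "TREMBL")
    ever_swissprot <- any(dbs == "SWISSPROT")
    if (first_all_trembl && ever_swissprot) flagged <- c(flagged, s)
  }
  sort(flagged)
}

# convenience: detector output and oracle output as comparable sorted vectors
detector_sentences <- function(hits) sort(hits$sentence_text)
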