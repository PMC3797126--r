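# Propagation-pattern detection.
#
# Four patterns are detected by set operations over a sentence's occurrence
# triples:
#   MISSING_ORIGIN   first-occurrence lineages and last-occurrence lineages
#                    are disjoint, and some non-origin lineage still holds
#                    the sentence at a release after every origin lost it;
#   REAPPEARING_ENTRY a lineage holds the sentence, loses it at an existing
#                    release of the same database, and later holds it again;
#   TRANSIENT        a lineage holds the sentence for exactly one release of
#                    a database that has a subsequent release (so removal is
#                    observable); occurrences confined to a database's final
#                    release are never flagged;
#   TREMBL_ORIGIN    every earliest-dated occurrence is in TrEMBL and the
#                    sentence later appears in a Swiss-Prot entry.
#
# All patterns are resolved at lineage level, so entry merges do not create
# spurious removals, and absence is only counted at releases that exist: a
# database with no release at some date contributes "no data", which
# prevents the striping artefact of the unsynchronised early calendars from
# generating false transient or reappearing hits.

.sentence_rows <- function(index, sentence) {
  occ <- index$occurrences
  if (is.numeric(sentence)) {
    rows <- occ[occ$sentence_id == sentence, , drop = FALSE]
  } else {
    rows <- occ[occ$sentence_text == sentence, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("unknown sentence: ", sentence)
  rows
}

#' Build the propagation trace of one sentence
#'
#' @param index an [build_index()] result.
#' @param sentence a sentence id or its normalised text.
#' @return An object of class \code{"propagation_trace"}: the sentence's
#'   occurrence rows ordered by release date, the per-release sets of
#'   lineages (\code{timeline}), and the \code{origin_set} /
#'   \code{terminal_set} of lineages at the earliest and latest occurrence
#'   dates. Multiple origin lineages are possible when a sentence first
#'   appears in several entries within one release.
#' @export
build_trace <- function(index, sentence) {
  rows <- .sentence_rows(index, sentence)
  rows <- rows[order(rows$date, rows$database, rows$lineage_id), , drop = FALSE]
  timeline <- lapply(split(rows$lineage_id, rows$release_id), function(x) sort(unique(x)))
  rel_order <- unique(rows$release_id)
  timeline <- timeline[rel_order]
  structure(list(
    sentence_id = rows$sentence_id[1L],
    sentence_text = rows$sentence_text[1L],
    occurrences = rows,
    timeline = timeline,
    origin_set = sort(unique(rows$lineage_id[rows$date == min(rows$date)])),
    terminal_set = sort(unique(rows$lineage_id[rows$date == max(rows$date)]))
  ), class = "propagation_trace")
}

#' @export
print.propagation_trace <- function(x, ...) {
  cat("propagation_trace for:", substr(x$sentence_text, 1, 60), "\n")
  cat("  releases:", length(x$timeline),
      " lineages:", length(unique(x$occurrences$lineage_id)), "\n")
  cat("  origin:", paste(x$origin_set, collapse = ", "), "\n")
  cat("  terminal:", paste(x$terminal_set, collapse = ", "), "\n")
  invisible(x)
}

.empty_hits <- function() {
  h <- data.frame(sentence_id = integer(0), sentence_text = character(0),
                  pattern = character(0), extant = logical(0),
                  stringsAsFactors = FALSE)
  h$evidence <- list()
  h
}

.hit_row <- function(rows, pattern, extant, evidence) {
  h <- data.frame(sentence_id = rows$sentence_id[1L],
                  sentence_text = rows$sentence_text[1L],
                  pattern = pattern, extant = extant,
                  stringsAsFactors = FALSE)
  h$evidence <- list(evidence)
  h
}

.bind_hits <- function(hits) {
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) return(.empty_hits())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

.is_extant <- function(index, rows) {
  max(rows$date) == max(index$calendar$date)
}

#' Detect sentences missing their root origin
#'
#' Flags every sentence whose origin lineages (those holding it at its
#' earliest occurrence date) are disjoint from its terminal lineages (those
#' holding it at its latest occurrence date), provided some non-origin
#' lineage retains the sentence at a release after every origin lineage has
#' lost it. Sentences still present in the corpus's final release carry
#' \code{extant = TRUE}; historical and extant cases are flagged alike.
#'
#' @param index an [build_index()] result.
#' @return \code{data.frame} of hits with columns \code{sentence_id},
#'   \code{sentence_text}, \code{pattern}, \code{extant} and a list column
#'   \code{evidence} of supporting \code{(lineage_id, release_id)} pairs
#'   (the retaining occurrences after origin loss).
#' @export
detect_missing_origin <- function(index) {
  hits <- lapply(split(index$occurrences, index$occurrences$sentence_id),
                 function(rows) {
    origin <- unique(rows$lineage_id[rows$date == min(rows$date)])
    terminal <- unique(rows$lineage_id[rows$date == max(rows$date)])
    if (length(intersect(origin, terminal)) > 0L) return(NULL)
    last_origin <- max(rows$date[rows$lineage_id %in% origin])
    keep <- !(rows$lineage_id %in% origin) & rows$date > last_origin
    if (!any(keep)) return(NULL)
    ev <- rows[keep, c("lineage_id", "release_id"), drop = FALSE]
    rownames(ev) <- NULL
    .hit_row(rows, "MISSING_ORIGIN", .is_extant(index, rows), ev)
  })
  .bind_hits(hits)
}

#' Detect sentences re-added to an entry after removal
#'
#' A hit requires, for some lineage and database, three existing releases
#' r1 < r2 < r3 of that database with the sentence present, absent and
#' present again. Gaps in the other database's calendar are "no data", not
#' absence.
#'
#' @inheritParams detect_missing_origin
#' @return hits \code{data.frame} as in [detect_missing_origin()]; evidence
#'   lists the re-addition occurrences (first presence after a gap).
#' @export
detect_reappearing <- function(index) {
  cal <- index$calendar
  hits <- lapply(split(index$occurrences, index$occurrences$sentence_id),
                 function(rows) {
    ev <- NULL
    for (db in unique(rows$database)) {
      db_rel <- cal$release_id[cal$database == db]   # calendar order = date order
      for (lin in unique(rows$lineage_id[rows$database == db])) {
        pres <- db_rel %in% rows$release_id[rows$database == db &
                                            rows$lineage_id == lin]
        on <- which(pres)
        if (length(on) >= 2L) {
          gaps <- on[-1L][diff(on) > 1L]   # presence directly after a gap
          if (length(gaps))
            ev <- rbind(ev, data.frame(lineage_id = lin,
                                       release_id = db_rel[gaps],
                                       stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(ev)) return(NULL)
    rownames(ev) <- NULL
    .hit_row(rows, "REAPPEARING_ENTRY", .is_extant(index, rows), ev)
  })
  .bind_hits(hits)
}

#' Detect transient sentences
#'
#' Flags sentences with some (lineage, database) appearance confined to a
#' single release, where the database has at least one later release (so the
#' removal is observable). An appearance whose only release is the
#' database's most recent one is never flagged.
#'
#' @inheritParams detect_missing_origin
#' @return hits \code{data.frame}; evidence lists the single-release
#'   appearances.
#' @export
detect_transient <- function(index) {
  cal <- index$calendar
  last_date <- vapply(split(cal$date, cal$database), max, as.Date(NA))
  hits <- lapply(split(index$occurrences, index$occurrences$sentence_id),
                 function(rows) {
    ev <- NULL
    key <- paste(rows$lineage_id, rows$database)
    for (k in unique(key)) {
      sub <- rows[key == k, , drop = FALSE]
      if (nrow(sub) == 1L &&
          sub$date < last_date[[sub$database]]) {
        ev <- rbind(ev, data.frame(lineage_id = sub$lineage_id,
                                   release_id = sub$release_id,
                                   stringsAsFactors = FALSE))
      }
    }
    if (is.null(ev)) return(NULL)
    rownames(ev) <- NULL
    .hit_row(rows, "TRANSIENT", .is_extant(index, rows), ev)
  })
  .bind_hits(hits)
}

#' Detect sentences originating in TrEMBL
#'
#' Flags sentences whose earliest-dated occurrences all lie in TrEMBL
#' releases and that later occur in a Swiss-Prot entry. A first appearance
#' in both halves of a synchronised release pair is ambiguous and not
#' flagged.
#'
#' @inheritParams detect_missing_origin
#' @return hits \code{data.frame}; evidence lists the earliest Swiss-Prot
#'   occurrences.
#' @export
detect_trembl_origin <- function(index) {
  hits <- lapply(split(index$occurrences, index$occurrences$sentence_id),
                 function(rows) {
    d0 <- min(rows$date)
    first <- rows[rows$date == d0, , drop = FALSE]
    if (any(first$database != "TREMBL")) return(NULL)
    sp <- rows[rows$database == "SWISSPROT", , drop = FALSE]
    if (nrow(sp) == 0L) return(NULL)
    ev <- sp[sp$date == min(sp$date), c("lineage_id", "release_id"), drop = FALSE]
    rownames(ev) <- NULL
    .hit_row(rows, "TREMBL_ORIGIN", .is_extant(index, rows), ev)
  })
  .bind_hits(hits)
}

#' Run all four propagation-pattern detectors
#'
#' @inheritParams detect_missing_origin
#' @return combined hits \code{data.frame}, one row per (sentence, pattern).
#' @export
detect_patterns <- function(index) {
  out <- rbind(detect_missing_origin(index),
               detect_reappearing(index),
               detect_transient(index),
               detect_trembl_origin(index))
  rownames(out) <- NULL
  out
}

#' Per-release entry counts for one sentence
#'
#' The number of lineages containing the sentence at every release between
#' its first and last occurrence (zero where absent), ordered by date. Only
#' releases that exist in the calendar appear.
#'
#' @inheritParams build_trace
#' @return \code{data.frame} with columns \code{release_id},
#'   \code{database}, \code{date}, \code{version} and \code{n_entries}.
#' @export
occurrence_timeline <- function(index, sentence) {
  rows <- .sentence_rows(index, sentence)
  cal <- index$calendar
  span <- cal[cal$date >= min(rows$date) & cal$date <= max(rows$date), ,
              drop = FALSE]
  n <- vapply(span$release_id, function(rel)
    length(unique(rows$lineage_id[rows$release_id == rel])), integer(1))
  out <- data.frame(release_id = span$release_id, database = span$database,
                    date = span$date, version = span$version,
                    n_entries = unname(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Number of distinct lineages a sentence has ever appeared in
#'
#' This is the entry count consulted by the classification protocol's first
#' question (counting lineages over the whole history, not concurrently).
#'
#' @inheritParams build_trace
#' @return an integer.
#' @export
sentence_entry_count <- function(index, sentence) {
  rows <- .sentence_rows(index, sentence)
  length(unique(rows$lineage_id))
}

#' Write a pattern report TSV
#'
#' @param hits output of [detect_patterns()] or a single detector.
#' @param index the index the hits were computed from.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pattern_report <- function(hits, index, path) {
  if (nrow(hits)) {
    span <- lapply(hits$sentence_id, function(sid) {
      rows <- index$occurrences[index$occurrences$sentence_id == sid, ]
      rows <- rows[order(rows$date), ]
      list(n = length(unique(rows$lineage_id)),
           first = rows$release_id[1L],
           last = rows$release_id[nrow(rows)])
    })
    out <- data.frame(
      sentence_text = hits$sentence_text,
      pattern = hits$pattern,
      n_entries_ever = vapply(span, `[[`, integer(1), "n"),
      first_release = vapply(span, `[[`, character(1), "first"),
      last_release = vapply(span, `[[`, character(1), "last"),
      extant_flag = hits$extant,
      evidence = vapply(hits$evidence, function(e)
        as.character(jsonlite::toJSON(e, dataframe = "rows")), character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(sentence_text = character(0), pattern = character(0),
                      n_entries_ever = integer(0), first_release = character(0),
                      last_release = character(0), extant_flag = logical(0),
                      evidence = character(0), stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
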