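# The occurrence index is the central store: one row per
# (sentence, lineage, release) triple, where a lineage groups every accession
# an entry has ever carried (entry merges make one primary accession absorb
# the others as secondaries; tracking accessions individually would make a
# merge look like a removal).

# union-find over accession strings; returns named vector acc -> lineage id,
# where the lineage id is the lexicographically smallest member accession
.lineage_map <- function(accession_sets) {
  accs <- sort(unique(unlist(accession_sets, use.names = FALSE)))
  if (length(accs) == 0L)
    return(stats::setNames(character(0), character(0)))
  parent <- seq_along(accs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- match(unlist(accession_sets, use.names = FALSE), accs)
  sizes <- lengths(accession_sets)
  off <- 0L
  for (s in sizes) {
    if (s > 1L) {
      r0 <- find(idx[off + 1L])
      for (j in 2L:s) {
        r <- find(idx[off + j])
        if (r != r0) parent[r] <- r0
      }
    }
    off <- off + s
  }
  roots <- vapply(seq_along(accs), find, integer(1))
  # canonical id: smallest accession in the component (accs is sorted)
  canon <- accs[ave(seq_along(accs), roots, FUN = min)]
  stats::setNames(canon, accs)
}

#' Build an occurrence index from parsed releases
#'
#' Combines the parsed entries of one or more releases into an index of
#' unique (sentence, lineage, release) occurrence triples. Lineages are the
#' transitive closure of shared-accession links across all releases: if an
#' entry ever lists another entry's accession among its accessions, the two
#' belong to one lineage. A sentence occurring twice in one entry's text
#' still contributes a single triple.
#'
#' @param entries a \code{data.frame} as returned by [parse_flatfile()]
#'   (rows from several releases may be concatenated with \code{rbind}).
#' @param calendar a [release_calendar()] covering every release referenced
#'   by \code{entries}.
#'
#' @return An object of class \code{"occurrence_index"}: a list with
#'   elements \code{occurrences} (triples with database and date),
#'   \code{sentences} (id to text), \code{lineages} (id to accession set and
#'   first release), \code{entries} (per-record sentence counts),
#'   \code{entry_counts} (per-release totals) and \code{calendar}.
#' @export
build_index <- function(entries, calendar) {
  calendar <- validate_calendar(calendar)
  unknown <- setdiff(unique(entries$release_id), calendar$release_id)
  if (length(unknown))
    stop("entries reference releases absent from the calendar: ",
         paste(unknown, collapse = ", "))
  acc_sets <- Map(function(p, s) unique(c(p, s)),
                  entries$primary_accession, entries$secondary_accessions)
  # an accession may belong to only one entry within a release
  for (rel in unique(entries$release_id)) {
    in_rel <- which(entries$release_id == rel)
    accs <- unlist(acc_sets[in_rel], use.names = FALSE)
    if (anyDuplicated(accs)) {
      dup <- unique(accs[duplicated(accs)])[1L]
      owners <- entries$primary_accession[in_rel][
        vapply(acc_sets[in_rel], function(a) dup %in% a, logical(1))]
      stop(sprintf(
        "accession %s claimed by two entries (%s) in release %s",
        dup, paste(owners, collapse = " and "), rel))
    }
  }
  lin <- .lineage_map(acc_sets)
  entry_lineage <- unname(lin[entries$primary_accession])

  n_sent <- vapply(entries$sentences, function(s) length(unique(s)), integer(1))
  texts <- unlist(lapply(entries$sentences, unique), use.names = FALSE)
  occ <- data.frame(
    sentence_text = if (is.null(texts)) character(0) else texts,
    lineage_id = rep(entry_lineage, n_sent),
    release_id = rep(entries$release_id, n_sent),
    stringsAsFactors = FALSE
  )
  occ <- unique(occ)
  sent_texts <- sort(unique(occ$sentence_text))
  sentences <- data.frame(sentence_id = seq_along(sent_texts),
                          sentence_text = sent_texts,
                          stringsAsFactors = FALSE)
  occ$sentence_id <- match(occ$sentence_text, sent_texts)
  ci <- match(occ$release_id, calendar$release_id)
  occ$database <- calendar$database[ci]
  occ$date <- calendar$date[ci]
  occ <- occ[order(occ$sentence_id, occ$date, occ$database, occ$lineage_id), ,
             drop = FALSE]
  rownames(occ) <- NULL

  lin_ids <- sort(unique(unname(lin)))
  lin_accs <- split(names(lin), unname(lin))[lin_ids]
  e_date <- calendar$date[match(entries$release_id, calendar$release_id)]
  first_rel <- vapply(lin_ids, function(l) {
    i <- which(entry_lineage == l)
    entries$release_id[i][which.min(e_date[i])]
  }, character(1))
  lineages <- data.frame(lineage_id = lin_ids, first_release = first_rel,
                         stringsAsFactors = FALSE)
  lineages$accessions <- lapply(lin_accs, sort)

  entry_tbl <- data.frame(release_id = entries$release_id,
                          primary_accession = entries$primary_accession,
                          lineage_id = entry_lineage,
                          n_sentences = n_sent,
                          stringsAsFactors = FALSE)
  entry_counts <- do.call(rbind, lapply(calendar$release_id, function(rel) {
    i <- entry_tbl$release_id == rel
    data.frame(release_id = rel,
               entries_total = sum(i),
               entries_annotated = sum(i & entry_tbl$n_sentences > 0L),
               stringsAsFactors = FALSE)
  }))

  structure(list(occurrences = occ[, c("sentence_id", "sentence_text",
                                       "lineage_id", "release_id",
                                       "database", "date")],
                 sentences = sentences,
                 lineages = lineages,
                 entries = entry_tbl,
                 entry_counts = entry_counts,
                 calendar = calendar),
            class = "occurrence_index")
}

#' @export
print.occurrence_index <- function(x, ...) {
  cat("occurrence_index:",
      nrow(x$sentences), "unique sentences,",
      nrow(x$lineages), "lineages,",
      nrow(x$calendar), "database releases,",
      nrow(x$occurrences), "occurrence triples\n")
  invisible(x)
}

.check_release <- function(index, release_id) {
  if (!release_id %in% index$calendar$release_id)
    stop("unknown release: ", release_id)
  release_id
}

#' Total, unique and singleton sentence counts at a release
#'
#' \code{total} counts the redundant multiset of sentence occurrences (one
#' per sentence-lineage pair); \code{unique} counts distinct sentences;
#' \code{singleton} counts sentences occurring exactly once in the release.
#'
#' @param index an [build_index()] result.
#' @param release_id a release present in the index's calendar.
#' @return named numeric vector \code{c(total, unique, singleton)}.
#' @export
corpus_counts <- function(index, release_id) {
  .check_release(index, release_id)
  occ <- index$occurrences[index$occurrences$release_id == release_id, ]
  tab <- table(occ$sentence_id)
  c(total = nrow(occ), unique = length(tab),
    singleton = sum(tab == 1L))
}

#' Per-entry annotation statistics at a release
#'
#' The average number of sentences per entry considers annotated entries
#' only; the percentage of entries without any textual annotation is over
#' all entries of the release.
#'
#' @inheritParams corpus_counts
#' @return list with \code{avg_sentences_per_entry} and
#'   \code{pct_unannotated}, each \code{NA} when undefined (no annotated
#'   entries / no entries).
#' @export
entry_stats <- function(index, release_id) {
  .check_release(index, release_id)
  e <- index$entries[index$entries$release_id == release_id, ]
  n_all <- nrow(e)
  annotated <- e$n_sentences > 0L
  list(
    avg_sentences_per_entry =
      if (any(annotated)) sum(e$n_sentences[annotated]) / sum(annotated)
      else NA_real_,
    pct_unannotated =
      if (n_all > 0L) 100 * sum(!annotated) / n_all else NA_real_
  )
}

#' Average number of entries each sentence appears in at a release
#'
#' Mean, over the release's unique sentences, of the number of lineages the
#' sentence occurs in (unweighted).
#'
#' @inheritParams corpus_counts
#' @return a single number, \code{NA} if the release has no sentences.
#' @export
sentence_stats <- function(index, release_id) {
  cc <- corpus_counts(index, release_id)
  if (cc[["unique"]] == 0L) return(NA_real_)
  cc[["total"]] / cc[["unique"]]
}

#' Sentence reuse histogram at a release
#'
#' @inheritParams corpus_counts
#' @return \code{data.frame} with columns \code{occurrence_count} and
#'   \code{n_sentences}; the \code{n_sentences} column sums to the unique
#'   count and \code{sum(occurrence_count * n_sentences)} equals the total.
#' @export
reuse_histogram <- function(index, release_id) {
  .check_release(index, release_id)
  occ <- index$occurrences[index$occurrences$release_id == release_id, ]
  if (nrow(occ) == 0L)
    return(data.frame(occurrence_count = integer(0), n_sentences = integer(0)))
  tab <- table(table(occ$sentence_id))
  data.frame(occurrence_count = as.integer(names(tab)),
             n_sentences = as.integer(tab))
}

#' Per-release statistics table
#'
#' One row per release of the calendar with the corpus-level statistics that
#' the reuse figures are drawn from.
#'
#' @param index an [build_index()] result.
#' @return \code{data.frame} with columns \code{release_id},
#'   \code{database}, \code{date}, \code{total}, \code{unique},
#'   \code{singleton}, \code{pct_unique}, \code{pct_singleton},
#'   \code{avg_sentences_per_entry}, \code{avg_entries_per_sentence},
#'   \code{pct_unannotated}.
#' @export
release_stats <- function(index) {
  cal <- index$calendar
  rows <- lapply(cal$release_id, function(rel) {
    cc <- corpus_counts(index, rel)
    es <- entry_stats(index, rel)
    data.frame(
      release_id = rel,
      database = cal$database[cal$release_id == rel],
      date = cal$date[cal$release_id == rel],
      total = unname(cc["total"]),
      unique = unname(cc["unique"]),
      singleton = unname(cc["singleton"]),
      pct_unique = if (cc[["total"]] > 0) 100 * cc[["unique"]] / cc[["total"]] else NA_real_,
      pct_singleton = if (cc[["total"]] > 0) 100 * cc[["singleton"]] / cc[["total"]] else NA_real_,
      avg_sentences_per_entry = es$avg_sentences_per_entry,
      avg_entries_per_sentence = sentence_stats(index, rel),
      pct_unannotated = es$pct_unannotated,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the per-release statistics table to TSV
#' @param index an [build_index()] result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_release_stats <- function(index, path) {
  out <- release_stats(index)
  out$date <- format(out$date)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
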