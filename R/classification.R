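# The erroneous-annotation classification protocol.
#
# Missing-origin sentences are classified into five quality classes by a
# decision tree over four questions:
#   Q1  how many entries has the sentence ever propagated to?  More than the
#       feasibility threshold (default 100) -> TOO MANY RESULTS.
#   Q2  does the context suggest the sentence was propagated between the
#       entries (rather than coinciding by chance)?  NO -> ACCURATE.
#   Q3  is the update/removal in the origin entry relevant to the secondary
#       entry?  NO -> ACCURATE.
#   Q4  does the update in the origin affect the accuracy of the secondary
#       entry?  YES -> ERRONEOUS, NO -> INCONSISTENT.
# An UNSURE at any consulted question yields POSSIBLY ERRONEOUS. Q2-Q4 are
# human judgements (they require reading the entries' historical context);
# this module automates the entry count and the tree logic and reads the
# judgements from an answers table.

#' The five annotation quality classes
#' @return character vector of class labels in canonical (reporting) order.
#' @export
annotation_classes <- function() {
  c("erroneous", "inconsistent", "accurate", "too_many_results",
    "possibly_erroneous")
}

#' Round half away from zero
#'
#' Plain decimal rounding where exact halves round up, as used for the
#' report percentages and extrapolations (base R's [round()] rounds halves
#' to even).
#'
#' @param x numeric vector (non-negative in this package's use).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify one analysed sentence
#'
#' Applies the decision tree to the protocol answers. Questions beyond the
#' first decisive one need not be answered; a consulted question left
#' unanswered (neither YES/NO nor UNSURE) is an error.
#'
#' @param n_entries number of entries (lineages) the sentence has ever
#'   propagated to; see [sentence_entry_count()].
#' @param q2 was the sentence propagated between the entries? One of
#'   \code{"YES"}, \code{"NO"}, \code{"UNSURE"} or \code{NA} (unconsulted).
#' @param q3 is the origin update relevant to the secondary entry?
#' @param q4 does the origin update affect the secondary entry's accuracy?
#' @param too_many_threshold entry count above which analysis is infeasible.
#' @return one of [annotation_classes()].
#' @export
#' @examples
#' classify_sentence(150)                       # "too_many_results"
#' classify_sentence(2, "YES", "YES", "YES")    # "erroneous"
#' classify_sentence(2, "NO")                   # "accurate"
classify_sentence <- function(n_entries, q2 = NA, q3 = NA, q4 = NA,
                              too_many_threshold = 100) {
  stopifnot(length(n_entries) == 1L, n_entries >= 1L, too_many_threshold > 0)
  if (n_entries > too_many_threshold) return("too_many_results")
  ans <- function(a, q) {
    if (is.na(a)) stop("question ", q, " consulted but unanswered")
    a <- toupper(as.character(a))
    if (!a %in% c("YES", "NO", "UNSURE"))
      stop("invalid answer for question ", q, ": ", a)
    a
  }
  a2 <- ans(q2, "Q2")
  if (a2 == "NO") return("accurate")
  if (a2 == "UNSURE") return("possibly_erroneous")
  a3 <- ans(q3, "Q3")
  if (a3 == "NO") return("accurate")
  if (a3 == "UNSURE") return("possibly_erroneous")
  a4 <- ans(q4, "Q4")
  if (a4 == "YES") return("erroneous")
  if (a4 == "NO") return("inconsistent")
  "possibly_erroneous"
}

#' Classify a table of answered sentences
#'
#' @param answers \code{data.frame} with columns \code{n_entries},
#'   \code{q2}, \code{q3}, \code{q4} (and typically \code{sentence_text}).
#' @inheritParams classify_sentence
#' @return \code{answers} with a \code{classification} column appended.
#' @export
classify_sentences <- function(answers, too_many_threshold = 100) {
  answers$classification <- vapply(seq_len(nrow(answers)), function(i)
    classify_sentence(answers$n_entries[i], answers$q2[i], answers$q3[i],
                      answers$q4[i], too_many_threshold), character(1))
  answers
}

#' Length-stratified subsample of sentences for analysis
#'
#' Removes short sentences, sorts the survivors by length (ties broken by
#' the normalised text) and keeps every \code{step}-th sentence, starting at
#' rank \code{step}. The sampling is deterministic and invariant to the
#' input order.
#'
#' @param sentences character vector of normalised sentences (for a hits
#'   \code{data.frame}, pass its \code{sentence_text} column).
#' @param min_len minimum length in characters; only sentences strictly
#'   longer qualify.
#' @param step sampling period in ranks.
#' @return character vector of selected sentences, ordered by rank; empty
#'   when fewer than \code{step} sentences qualify.
#' @export
sample_for_analysis <- function(sentences, min_len = 20, step = 100) {
  stopifnot(step >= 1)
  keep <- sentences[nchar(sentences) > min_len]
  if (length(keep) < step) return(character(0))
  keep <- keep[order(nchar(keep), keep)]
  keep[seq.int(step, length(keep), by = step)]
}

#' Tally classifications into a report
#'
#' Counts each quality class, derives one-decimal percentages and, when a
#' base population size is supplied, extrapolates each class count to the
#' full population with [extrapolate()].
#'
#' @param classes character vector of class labels (one per analysed
#'   sentence), each one of [annotation_classes()].
#' @param base_total optional size of the population the analysed sentences
#'   were sampled from.
#' @return object of class \code{"class_tally"}: list with \code{counts},
#'   \code{n_analysed}, \code{percentages} (absent for an empty input) and
#'   \code{extrapolations} (when \code{base_total} given).
#' @export
tally_classes <- function(classes, base_total = NULL) {
  bad <- setdiff(unique(classes), annotation_classes())
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(annotation_classes(), function(k) sum(classes == k),
                   integer(1))
  n <- length(classes)
  out <- list(counts = counts, n_analysed = n,
              percentages = if (n > 0) round_half_up(100 * counts / n, 1),
              extrapolations = if (!is.null(base_total) && n > 0)
                vapply(counts, extrapolate, numeric(1),
                       n_analysed = n, base_total = base_total),
              base_total = base_total)
  class(out) <- "class_tally"
  out
}

#' @export
print.class_tally <- function(x, ...) {
  m <- rbind(Absolute = x$counts)
  if (!is.null(x$percentages))
    m <- rbind(m, Percentage = x$percentages)
  if (!is.null(x$extrapolations))
    m <- rbind(m, `Potentially erroneous` = x$extrapolations)
  colnames(m) <- annotation_classes()
  cat("Classification tally of", x$n_analysed, "sentences")
  if (!is.null(x$base_total)) cat(" (population:", x$base_total, "sentences)")
  cat("\n")
  print(m)
  invisible(x)
}

#' Extrapolate a class count to the full population
#'
#' Scales \code{count / n_analysed} to \code{base_total} and rounds half up
#' to the nearest integer.
#'
#' @param count sentences of the class among those analysed.
#' @param n_analysed total sentences analysed (must be positive).
#' @param base_total size of the population being extrapolated to.
#' @return integer-valued numeric.
#' @export
#' @examples
#' extrapolate(36, 122, 8355)   # 2465
extrapolate <- function(count, n_analysed, base_total) {
  if (length(n_analysed) != 1L || n_analysed < 1)
    stop("n_analysed must be a positive count")
  stopifnot(all(count >= 0), all(count <= n_analysed))
  round_half_up(count * base_total / n_analysed)
}

#' Read a protocol answers table
#'
#' Tab-separated with columns \code{sentence_text}, \code{q2}, \code{q3},
#' \code{q4} and optionally \code{n_entries}; when \code{n_entries} is
#' absent an index must be supplied so it can be computed with
#' [sentence_entry_count()].
#'
#' @param path path to the TSV.
#' @param index optional [build_index()] result for entry counts.
#' @return \code{data.frame} of answers with \code{n_entries} filled in.
#' @export
read_answers <- function(path, index = NULL) {
  ans <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(ans$n_entries)) {
    if (is.null(index))
      stop("answers file lacks n_entries and no index was supplied")
    ans$n_entries <- vapply(ans$sentence_text, sentence_entry_count,
                            integer(1), index = index)
  }
  for (q in c("q2", "q3", "q4")) if (is.null(ans[[q]])) ans[[q]] <- NA
  ans
}

#' Write a classification report TSV
#' @param records a classified \code{data.frame} from [classify_sentences()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_classification_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tally report as JSON
#' @param tally a [tally_classes()] result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tally_json <- function(tally, path) {
  jsonlite::write_json(unclass(tally), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
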