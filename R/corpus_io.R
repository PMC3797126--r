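# Flat-file reading and sentence extraction.
#
# The corpus format is the UniProtKB flat-file dialect: records terminated by
# a "//" line, an "ID" line naming the entry, "AC" lines listing the primary
# accession first followed by any secondary (merged-in) accessions, and "CC"
# lines carrying the free-text comment annotation this package analyses.

#' Default abbreviation lexicon for sentence segmentation
#'
#' Periods ending one of these tokens do not terminate a sentence when more
#' text follows. The set covers the abbreviations common in biomedical
#' annotation text; extend it via the \code{abbreviations} argument of
#' [split_sentences()].
#'
#' @return character vector of abbreviations, each ending in a period.
#' @export
default_abbreviations <- function() {
  c("e.g.", "i.e.", "et al.", "cf.", "ca.", "vs.", "approx.", "sp.",
    "spp.", "subsp.", "var.", "str.", "nov.", "fig.", "no.")
}

#' Parse one flat-file release into entry versions
#'
#' Reads a flat file (or a character vector of its lines) and returns one row
#' per entry record: accessions, the verbatim comment-line payload, the
#' cleaned comment text and its normalised sentences.
#'
#' @param x a file path or a character vector of flat-file lines.
#' @param release_id identifier of the release the file belongs to.
#' @param strict if \code{TRUE}, a malformed record (missing ID or AC line)
#'   aborts parsing; otherwise it is reported as a warning naming the line
#'   number and skipped.
#' @param abbreviations abbreviation lexicon passed to [split_sentences()].
#'
#' @return A \code{data.frame} with columns \code{release_id},
#'   \code{primary_accession}, \code{secondary_accessions} (list column),
#'   \code{raw_cc} (verbatim CC payload), \code{comment_text} and
#'   \code{sentences} (list column of normalised sentences). Entries with no
#'   CC lines get \code{comment_text == ""} and zero sentences.
#' @export
#' @examples
#' rec <- c("ID   TEST_ENTRY  Reviewed; 100 AA.",
#'          "AC   P12345; Q67890;",
#'          "CC   -!- FUNCTION: Inactivated by cyanide.",
#'          "//")
#' parse_flatfile(rec, release_id = "SP_1")
parse_flatfile <- function(x, release_id, strict = FALSE,
                           abbreviations = default_abbreviations()) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else x
  term <- which(lines == "//")
  starts <- c(1L, utils::head(term, -1L) + 1L)
  if (length(term) == 0L && length(lines) > 0L && any(nzchar(trimws(lines))))
    stop("no record terminator ('//') found")
  prim <- character(0); secs <- list(); raws <- character(0)
  for (k in seq_along(term)) {
    idx <- starts[k]:term[k]
    rec <- lines[idx]
    has_id <- any(grepl("^ID\\s", rec))
    ac_lines <- grep("^AC\\s", rec, value = TRUE)
    if (!has_id || length(ac_lines) == 0L) {
      msg <- sprintf("malformed record at lines %d-%d (missing %s line)",
                     idx[1L], idx[length(idx)],
                     if (!has_id) "ID" else "AC")
      if (strict) stop(msg)
      warning(msg, call. = FALSE)
      next
    }
    acc <- unlist(strsplit(sub("^AC\\s+", "", ac_lines), ";"))
    acc <- trimws(acc)
    acc <- acc[nzchar(acc)]
    cc <- grep("^CC( |$)", rec, value = TRUE)
    prim <- c(prim, acc[1L])
    secs <- c(secs, list(unique(acc[-1L])))
    raws <- c(raws, paste(cc, collapse = "\n"))
  }
  blocks <- lapply(raws, .comment_blocks)
  comment <- vapply(blocks, paste, character(1), collapse = " ")
  sent <- lapply(blocks, function(b) {
    raw <- split_sentences(b, abbreviations = abbreviations)
    if (length(raw)) normalize_sentence(raw) else character(0)
  })
  out <- data.frame(release_id = rep(as.character(release_id), length(prim)),
                    primary_accession = prim,
                    stringsAsFactors = FALSE)
  out$secondary_accessions <- secs
  out$raw_cc <- raws
  out$comment_text <- comment
  out$sentences <- sent
  out
}

#' Clean the comment-line payload of one entry
#'
#' Strips the structure that the flat-file format wraps around the free text:
#' the \code{"CC"} line prefix, the copyright/licence block, topic headings
#' (\code{"-!- FUNCTION:"} and kin) and property keys (\code{Key=} tokens),
#' and rejoins wrapped lines with single spaces. Sentence text itself is
#' preserved, including its case.
#'
#' @param raw_cc verbatim CC payload of one entry: the CC lines joined with
#'   newlines (the \code{"CC"} prefix may be present or already removed).
#' @param copyright_markers phrases identifying the licence block; any run of
#'   lines bounded by dashed rule lines and containing one of these phrases
#'   is removed entirely, as is any stray line containing one.
#'
#' @return a single cleaned text string (possibly empty).
#' @export
#' @examples
#' extract_comment_text("CC   -!- FUNCTION: Inactivated by cyanide.")
extract_comment_text <- function(raw_cc,
                                 copyright_markers = c("Copyright",
                                                       "Distributed under")) {
  paste(.comment_blocks(raw_cc, copyright_markers), collapse = " ")
}

# cleaned topic blocks of one entry's CC payload; block boundaries matter
# for segmentation because topic blocks need not end in a full stop
.comment_blocks <- function(raw_cc,
                            copyright_markers = c("Copyright",
                                                  "Distributed under")) {
  if (length(raw_cc) == 1L) raw_cc <- strsplit(raw_cc, "\n", fixed = TRUE)[[1L]]
  ln <- sub("^CC( |$)", "", raw_cc)
  ln <- trimws(ln)
  # --- copyright / licence block ------------------------------------------
  dash <- grepl("^-{10,}$", ln)
  marker <- if (length(ln))
    Reduce(`|`, lapply(copyright_markers, function(m)
      grepl(m, ln, fixed = TRUE))) else logical(0)
  drop <- rep(FALSE, length(ln))
  di <- which(dash)
  if (length(di) >= 2L) {
    for (j in seq_len(length(di) - 1L)) {
      span <- di[j]:di[j + 1L]
      if (any(marker[span])) drop[span] <- TRUE
    }
  }
  drop <- drop | marker | dash
  ln <- ln[!drop]
  txt <- paste(ln[nzchar(ln)], collapse = " ")
  # --- split at topic headings, then strip them ---------------------------
  heading <- "-!- [A-Z][A-Z0-9 ,/()-]*:"
  marked <- gsub(paste0("(", heading, ")"), "\u0001\\1", txt)
  blocks <- strsplit(marked, "\u0001", fixed = TRUE)[[1L]]
  blocks <- sub(heading, "", blocks)
  blocks <- gsub("-!-", "", blocks, fixed = TRUE)
  # --- property keys: Key= immediately followed by its value --------------
  blocks <- gsub("(^|[ (;])([A-Za-z][A-Za-z0-9_-]*)=", "\\1", blocks, perl = TRUE)
  blocks <- trimws(gsub("\\s+", " ", blocks))
  blocks[nzchar(blocks)]
}

#' Split cleaned comment text into sentences
#'
#' A sentence ends at a full stop followed by whitespace or the end of the
#' text, except when the stop terminates a known abbreviation or a single
#' initial. Decimal points never split because they are not followed by
#' whitespace. A trailing fragment with no terminal stop (common for topic
#' blocks and list items in annotation text) counts as one sentence.
#'
#' @param clean_text cleaned comment text as returned by
#'   [extract_comment_text()]. A vector is segmented element-wise (topic
#'   blocks are natural sentence boundaries), with the results concatenated
#'   in order.
#' @param abbreviations abbreviation lexicon; see [default_abbreviations()].
#' @return character vector of raw (un-normalised) sentences; empty input
#'   yields \code{character(0)}.
#' @export
#' @examples
#' split_sentences("Heme-thiolate. Belongs to the ycf50 family")
split_sentences <- function(clean_text, abbreviations = default_abbreviations()) {
  if (length(clean_text) == 0L) return(character(0))
  if (length(clean_text) != 1L)
    return(unlist(lapply(clean_text, split_sentences,
                         abbreviations = abbreviations), use.names = FALSE))
  txt <- trimws(clean_text)
  if (!nzchar(txt)) return(character(0))
  cand <- gregexpr("\\.(?=\\s|$)", txt, perl = TRUE)[[1L]]
  if (cand[1L] == -1L) cand <- integer(0)
  nc <- nchar(txt)
  is_boundary <- vapply(cand, function(pos) {
    if (pos == nc) return(TRUE)              # end of text always terminates
    for (abb in abbreviations) {
      w <- nchar(abb)
      if (pos >= w &&
          tolower(substr(txt, pos - w + 1L, pos)) == tolower(abb)) {
        before <- if (pos - w >= 1L) substr(txt, pos - w, pos - w) else ""
        if (before %in% c("", " ", "(")) return(FALSE)
      }
    }
    # single-letter initial, e.g. "j. smith"
    if (pos >= 2L && grepl("^[A-Za-z]$", substr(txt, pos - 1L, pos - 1L))) {
      before <- if (pos >= 3L) substr(txt, pos - 2L, pos - 2L) else ""
      if (before %in% c("", " ", "(")) return(FALSE)
    }
    TRUE
  }, logical(1))
  cuts <- cand[is_boundary]
  pieces <- substring(txt, c(1L, cuts + 1L), c(cuts, nc))
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Normalise a sentence for case-insensitive comparison
#'
#' Sentences are stored in their normalised form only: lower-cased, internal
#' whitespace runs collapsed to single spaces, and trimmed. The operation is
#' idempotent. Whitespace-only input is rejected, since it signals a
#' segmentation bug upstream.
#'
#' @param x character vector of raw sentences.
#' @return character vector of normalised sentences.
#' @export
#' @examples
#' normalize_sentence("  Heme-thiolate.  ")
normalize_sentence <- function(x) {
  out <- trimws(tolower(x))
  out <- gsub("\\s+", " ", out)
  if (any(!nzchar(out)))
    stop("whitespace-only sentence passed to normalize_sentence()")
  out
}

#' Write extracted sentences to a per-release TSV
#'
#' One row per (entry, sentence) with the sentence's rank within the entry,
#' in the layout \code{release_id, primary_accession, sentence_text,
#' sentence_rank}.
#'
#' @param entries output of [parse_flatfile()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sentence_tsv <- function(entries, path) {
  n <- lengths(entries$sentences)
  out <- data.frame(
    release_id = rep(entries$release_id, n),
    primary_accession = rep(entries$primary_accession, n),
    sentence_text = unlist(entries$sentences, use.names = FALSE),
    sentence_rank = unlist(lapply(n, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L)
    out <- data.frame(release_id = character(0), primary_accession = character(0),
                      sentence_text = character(0), sentence_rank = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
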