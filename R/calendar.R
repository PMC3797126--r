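#' Build a validated release calendar
#'
#' A release calendar lists every archived database release that a corpus
#' spans: its identifier, which database section it belongs to (the manually
#' reviewed \code{SWISSPROT} or the automatically annotated \code{TREMBL}),
#' its release date, and the naming era. Three eras are distinguished:
#' \code{PRE_CONSORTIUM} releases of Swiss-Prot and TrEMBL were published on
#' independent, unsynchronised schedules; \code{UPKB_MAJOR} and
#' \code{UPKB_MONTHLY} releases come as synchronised Swiss-Prot + TrEMBL
#' pairs sharing one date and one version label.
#'
#' @param release_id character vector of unique release identifiers, one per
#'   database-release (a synchronised pair occupies two rows, e.g.
#'   \code{"2012_05_SP"} and \code{"2012_05_TR"}).
#' @param database character vector, each \code{"SWISSPROT"} or
#'   \code{"TREMBL"}.
#' @param date release dates (coerced with [as.Date()]).
#' @param era character vector of \code{"PRE_CONSORTIUM"}, \code{"UPKB_MAJOR"}
#'   or \code{"UPKB_MONTHLY"}.
#' @param version optional shared display label tying the two halves of a
#'   synchronised pair together (defaults to \code{release_id}).
#'
#' @return A \code{data.frame} of class \code{"release_calendar"}, ordered by
#'   date (Swiss-Prot before TrEMBL within a shared date).
#' @export
#' @examples
#' release_calendar(
#'   release_id = c("SP_1", "TR_1", "SP_2"),
#'   database   = c("SWISSPROT", "TREMBL", "SWISSPROT"),
#'   date       = c("1990-01-15", "1990-06-15", "1991-01-15"),
#'   era        = "PRE_CONSORTIUM"
#' )
release_calendar <- function(release_id, database, date, era, version = NULL) {
  database <- match.arg(database, c("SWISSPROT", "TREMBL"), several.ok = TRUE)
  n <- length(release_id)
  if (length(database) == 1L) database <- rep(database, n)
  if (length(era) == 1L) era <- rep(era, n)
  if (is.null(version)) version <- release_id
  cal <- data.frame(
    release_id = as.character(release_id),
    database = database,
    date = as.Date(date),
    era = era,
    version = as.character(version),
    stringsAsFactors = FALSE
  )
  validate_calendar(cal)
}

#' @rdname release_calendar
#' @param cal a candidate calendar data frame.
#' @export
validate_calendar <- function(cal) {
  required <- c("release_id", "database", "date", "era")
  missing_cols <- setdiff(required, names(cal))
  if (length(missing_cols))
    stop("calendar lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(cal$version)) cal$version <- cal$release_id
  cal$date <- as.Date(cal$date)
  if (anyNA(cal$date)) stop("calendar contains unparseable dates")
  if (anyDuplicated(cal$release_id))
    stop("duplicate release_id in calendar: ",
         paste(unique(cal$release_id[duplicated(cal$release_id)]), collapse = ", "))
  bad_db <- setdiff(unique(cal$database), c("SWISSPROT", "TREMBL"))
  if (length(bad_db)) stop("unknown database: ", paste(bad_db, collapse = ", "))
  bad_era <- setdiff(unique(cal$era),
                     c("PRE_CONSORTIUM", "UPKB_MAJOR", "UPKB_MONTHLY"))
  if (length(bad_era)) stop("unknown era: ", paste(bad_era, collapse = ", "))
  for (db in unique(cal$database)) {
    d <- cal$date[cal$database == db]
    if (any(duplicated(d)))
      stop("two ", db, " releases share one date")
  }
  # post-consortium releases must come as SWISSPROT+TREMBL pairs on one date
  post <- cal[cal$era != "PRE_CONSORTIUM", , drop = FALSE]
  if (nrow(post)) {
    for (v in unique(post$version)) {
      half <- post[post$version == v, , drop = FALSE]
      if (!setequal(half$database, c("SWISSPROT", "TREMBL")) ||
          length(unique(half$date)) != 1L)
        stop("post-consortium version ", v,
             " is not a SWISSPROT+TREMBL pair sharing one date")
    }
  }
  ord <- order(cal$date, match(cal$database, c("SWISSPROT", "TREMBL")))
  cal <- cal[ord, , drop = FALSE]
  rownames(cal) <- NULL
  class(cal) <- c("release_calendar", "data.frame")
  cal
}

#' Read a release calendar from a TSV file
#'
#' Columns: \code{release_id}, \code{database}, \code{date}, \code{era} and
#' optionally \code{version}.
#'
#' @param path path to a tab-separated calendar file.
#' @return a validated \code{release_calendar}.
#' @export
read_release_calendar <- function(path) {
  cal <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_calendar(cal)
}

#' Write a release calendar to TSV
#' @param cal a \code{release_calendar}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_release_calendar <- function(cal, path) {
  out <- as.data.frame(cal)
  out$date <- format(out$date)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
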