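# Synthetic multi-release corpus generator.
#
# Emits flat files in the same dialect the parser reads, together with a
# ground-truth manifest (occurrence triples, planted pattern labels,
# per-release counts, merge map), so the whole pipeline is testable without
# the historical archives. Background annotation is deliberately
# pattern-free: background sentences persist from acquisition to the end of
# their database and never cross databases, so every pattern hit a detector
# reports must be a planted one.

#' Default synthetic release calendar
#'
#' Ten release events spanning the three naming eras: six unsynchronised
#' early Swiss-Prot/TrEMBL releases, two synchronised major versions and two
#' monthly versions. Both databases share the final release date, as in the
#' real archives.
#'
#' @return a [release_calendar()].
#' @export
default_synthetic_calendar <- function() {
  release_calendar(
    release_id = c("SP_1", "TR_1", "SP_2", "TR_2", "SP_3", "TR_3",
                   "UPKB_2_SP", "UPKB_2_TR", "UPKB_3_SP", "UPKB_3_TR",
                   "2010_01_SP", "2010_01_TR", "2012_05_SP", "2012_05_TR"),
    database = c("SWISSPROT", "TREMBL", "SWISSPROT", "TREMBL", "SWISSPROT",
                 "TREMBL", "SWISSPROT", "TREMBL", "SWISSPROT", "TREMBL",
                 "SWISSPROT", "TREMBL", "SWISSPROT", "TREMBL"),
    date = c("1990-01-15", "1990-06-15", "1991-01-15", "1991-06-15",
             "1992-01-15", "1992-06-15", "2004-07-19", "2004-07-19",
             "2005-02-01", "2005-02-01", "2010-01-19", "2010-01-19",
             "2012-05-16", "2012-05-16"),
    era = c(rep("PRE_CONSORTIUM", 6), rep("UPKB_MAJOR", 4),
            rep("UPKB_MONTHLY", 4)),
    version = c("SP_1", "TR_1", "SP_2", "TR_2", "SP_3", "TR_3",
                "UPKB_2", "UPKB_2", "UPKB_3", "UPKB_3",
                "2010_01", "2010_01", "2012_05", "2012_05")
  )
}

#' Compact synthetic calendar (six release events)
#'
#' Four Swiss-Prot and three TrEMBL releases: five unsynchronised early
#' releases plus one synchronised pair closing both databases on the same
#' date. Large enough to plant every pattern, small enough for exhaustive
#' brute-force checking.
#'
#' @return a [release_calendar()].
#' @export
small_synthetic_calendar <- function() {
  release_calendar(
    release_id = c("SP_1", "TR_1", "SP_2", "TR_2", "SP_3",
                   "UPKB_1_SP", "UPKB_1_TR"),
    database = c("SWISSPROT", "TREMBL", "SWISSPROT", "TREMBL", "SWISSPROT",
                 "SWISSPROT", "TREMBL"),
    date = c("1990-01-15", "1990-06-15", "1991-01-15", "1991-06-15",
             "1992-01-15", "1993-01-15", "1993-01-15"),
    era = c(rep("PRE_CONSORTIUM", 5), "UPKB_MAJOR", "UPKB_MAJOR"),
    version = c("SP_1", "TR_1", "SP_2", "TR_2", "SP_3", "UPKB_1", "UPKB_1")
  )
}

#' Configuration for the synthetic corpus generator
#'
#' The defaults describe a small but structurally realistic corpus:
#' background entries acquire sentences from a shared per-database pool
#' (sentence copying is how reuse arises in curation practice), a fraction
#' of entries carry no annotation, some entries merge, and a handful of
#' instances of each propagation pattern are planted with dedicated
#' sentences and entries.
#'
#' @param seed integer seed; the same configuration always produces
#'   byte-identical files and manifest.
#' @param calendar a [release_calendar()].
#' @param n_entries named count of background entries per database.
#' @param sentence_pool_size size of the background sentence pool (split
#'   between the databases; pools are disjoint across databases).
#' @param copy_probability per-release probability that an annotated entry
#'   acquires one further pool sentence, mimicking rising reuse.
#' @param n_merges number of Swiss-Prot entry merges to stage.
#' @param planted named counts of pattern instances to plant
#'   (\code{missing_origin}, \code{reappearing}, \code{transient},
#'   \code{trembl_origin}).
#' @param p_unannotated named per-database probability that a background
#'   entry carries no textual annotation.
#' @return validated list of class \code{"generator_config"}.
#' @export
generator_config <- function(seed = 1L,
                             calendar = default_synthetic_calendar(),
                             n_entries = c(SWISSPROT = 25L, TREMBL = 25L),
                             sentence_pool_size = 60L,
                             copy_probability = 0.15,
                             n_merges = 2L,
                             planted = c(missing_origin = 3L, reappearing = 2L,
                                         transient = 3L, trembl_origin = 2L),
                             p_unannotated = c(SWISSPROT = 0.1, TREMBL = 0.5)) {
  calendar <- validate_calendar(calendar)
  pl <- c(missing_origin = 0L, reappearing = 0L, transient = 0L,
          trembl_origin = 0L)
  pl[names(planted)] <- as.integer(planted)
  n_sp <- sum(calendar$database == "SWISSPROT")
  n_tr <- sum(calendar$database == "TREMBL")
  if (pl["transient"] > 0L && max(n_sp, n_tr) < 2L)
    stop("planting TRANSIENT requires a database with >= 2 releases")
  if (pl["reappearing"] > 0L && max(n_sp, n_tr) < 3L)
    stop("planting REAPPEARING_ENTRY requires a database with >= 3 releases")
  if (pl["missing_origin"] > 0L && max(n_sp, n_tr) < 3L)
    stop("planting MISSING_ORIGIN requires a database with >= 3 releases")
  if (pl["trembl_origin"] > 0L) {
    if (n_sp == 0L || n_tr == 0L)
      stop("planting TREMBL_ORIGIN requires releases of both databases")
    tr1 <- min(calendar$date[calendar$database == "TREMBL"])
    if (!any(calendar$database == "SWISSPROT" & calendar$date > tr1))
      stop("planting TREMBL_ORIGIN requires a Swiss-Prot release after the first TrEMBL release")
    if (max(calendar$date[calendar$database == "TREMBL"]) !=
        max(calendar$date[calendar$database == "SWISSPROT"]))
      stop("planting TREMBL_ORIGIN requires both databases to share the final release date")
  }
  if (n_merges > 0L && n_entries[["SWISSPROT"]] < 2L * n_merges + 2L)
    stop("n_merges too large for the number of Swiss-Prot entries")
  stopifnot(sentence_pool_size >= 8L, copy_probability >= 0,
            copy_probability <= 1)
  structure(list(seed = as.integer(seed), calendar = calendar,
                 n_entries = n_entries,
                 sentence_pool_size = as.integer(sentence_pool_size),
                 copy_probability = copy_probability,
                 n_merges = as.integer(n_merges), planted = pl,
                 p_unannotated = p_unannotated),
            class = "generator_config")
}

# background sentence pool; at most one unterminated template per database
# pool so that at most one fragment can end an entry's comment text
.sentence_pool <- function(n, db) {
  templates <- c(
    "belongs to the %s family.",
    "may have an essential function in %s biosynthesis.",
    "interacts with %s (by similarity).",
    "binds approx. 1.5 mg of %s per subunit, e.g. under assay conditions.",
    "catalyzes the conversion of %s to %s-phosphate.",
    "this enzyme, i.e. the %s-specific isoform, is inhibited by cyanide.",
    "composed of two %s subunits and one regulatory chain."
  )
  frag <- "involved in the regulation of %s"     # unterminated topic block
  words <- sprintf("%s%03d", tolower(substr(db, 1, 2)), seq_len(n))
  text <- character(n)
  for (i in seq_len(n)) {
    if (i == 1L) text[i] <- sprintf(frag, words[i])
    else {
      tpl <- templates[1L + (i %% length(templates))]
      text[i] <- if (grepl("conversion", tpl)) sprintf(tpl, words[i], words[i])
                 else sprintf(tpl, words[i])
    }
  }
  emit <- paste0(toupper(substr(text, 1, 1)), substr(text, 2, nchar(text)))
  # one property-style interaction comment per pool: stored text keeps the
  # property values but not the keys
  if (n >= 3L) {
    code <- if (db == "SWISSPROT") 311928L else 86215L
    text[3L] <- sprintf("self; 2; ebi-%d, ebi-%d;", code, code)
    emit[3L] <- sprintf("Self; NbExp=2; IntAct=EBI-%d, EBI-%d;", code, code)
  }
  data.frame(text = text, emit = emit, stringsAsFactors = FALSE)
}

.capitalise <- function(x) paste0(toupper(substr(x, 1, 1)),
                                  substr(x, 2, nchar(x)))

# format one record's lines
.format_record <- function(acc, secondaries, date, db, pool_emit, sentences) {
  reviewed <- if (db == "SWISSPROT") "Reviewed" else "Unreviewed"
  lines <- c(
    sprintf("ID   %s_SYN               %s;       %d AA.", acc, reviewed,
            100L + nchar(acc)),
    sprintf("AC   %s;", paste(c(acc, secondaries), collapse = "; ")),
    sprintf("DT   %s, integrated into UniProtKB/%s.",
            toupper(format(date, "%d-%b-%Y")),
            if (db == "SWISSPROT") "Swiss-Prot" else "TrEMBL")
  )
  if (length(sentences)) {
    # unterminated fragments must close the comment block
    frag <- !grepl("[.;]$", sentences)
    sentences <- c(sort(sentences[!frag]), sort(sentences[frag]))
    topics <- c("FUNCTION", "SUBUNIT", "INTERACTION", "MISCELLANEOUS",
                "SIMILARITY")
    cc <- character(0)
    for (k in seq_along(sentences)) {
      s <- sentences[k]
      emit <- if (s %in% names(pool_emit)) pool_emit[[s]] else .capitalise(s)
      topic <- if (grepl("^Self; NbExp", emit)) "INTERACTION"
               else topics[1L + ((k - 1L) %% 2L)]
      body <- strwrap(sprintf("-!- %s: %s", topic, emit), width = 64L)
      cc <- c(cc, paste0("CC   ", body[1L]),
              if (length(body) > 1L) paste0("CC       ", body[-1L]))
    }
    lines <- c(lines,
               "CC   -----------------------------------------------------------------------",
               "CC   Copyrighted by the UniProt Consortium, see https://www.uniprot.org/terms",
               "CC   Distributed under the Creative Commons Attribution License",
               "CC   -----------------------------------------------------------------------",
               cc)
  }
  c(lines, "//")
}

#' Generate a synthetic multi-release corpus with ground truth
#'
#' Realises the configuration as one flat file per database release plus a
#' manifest holding the true occurrence triples (at lineage level), the
#' planted pattern labels, per-release total/unique/singleton counts and the
#' merge map. The same configuration (including seed) always yields
#' byte-identical output.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, writes
#'   \code{<release_id>.dat} files, \code{calendar.tsv} and
#'   \code{manifest.json} there.
#' @return object of class \code{"synthetic_corpus"}: list with
#'   \code{files} (named list of flat-file line vectors), \code{manifest}
#'   and \code{config}.
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister")

  cal <- config$calendar
  dbs <- c("SWISSPROT", "TREMBL")
  rel <- lapply(dbs, function(db) cal$release_id[cal$database == db])
  names(rel) <- dbs
  n_rel <- lengths(rel)

  pool <- list(
    SWISSPROT = .sentence_pool(ceiling(config$sentence_pool_size / 2), "SWISSPROT"),
    TREMBL = .sentence_pool(floor(config$sentence_pool_size / 2), "TREMBL"))
  pool_emit <- stats::setNames(
    c(pool$SWISSPROT$emit, pool$TREMBL$emit),
    c(pool$SWISSPROT$text, pool$TREMBL$text))

  # --- background entries -------------------------------------------------
  # entry-level presence: acc -> list(db, birth index, sentence -> acquired-at)
  entries <- list()
  for (db in dbs) {
    n <- config$n_entries[[db]]
    if (n == 0L || n_rel[[db]] == 0L) next
    prefix <- if (db == "SWISSPROT") "P" else "Q"
    births <- sort(c(rep(1L, ceiling(n / 2)),
                     sample.int(n_rel[[db]], floor(n / 2), replace = TRUE)))
    for (i in seq_len(n)) {
      acc <- sprintf("%s%05d", prefix, i)
      annotated <- stats::runif(1) >= config$p_unannotated[[db]]
      held <- integer(0)
      if (annotated) {
        k <- sample.int(min(4L, nrow(pool[[db]])), 1L)
        texts <- pool[[db]]$text[sample.int(nrow(pool[[db]]), k)]
        # at most one sentence without a terminal stop per entry: a second
        # fragment would fuse with it when the comment block is re-split
        nd <- !grepl("\\.$", texts)
        if (sum(nd) > 1L) texts <- c(texts[!nd], texts[nd][1L])
        held <- stats::setNames(rep(births[i], length(texts)), texts)
        if (births[i] < n_rel[[db]] && config$copy_probability > 0) {
          for (j in (births[i] + 1L):n_rel[[db]]) {
            if (stats::runif(1) < config$copy_probability) {
              free <- setdiff(pool[[db]]$text, names(held))
              if (any(!grepl("\\.$", names(held))))
                free <- free[grepl("\\.$", free)]
              if (length(free))
                held <- c(held, stats::setNames(j, free[sample.int(length(free), 1L)]))
            }
          }
        }
      }
      entries[[acc]] <- list(acc = acc, db = db, birth = births[i],
                             held = held, secondaries = character(0),
                             absorbed_at = NA_integer_, role = "background")
    }
  }

  # --- merges (within Swiss-Prot) -----------------------------------------
  merges <- data.frame(absorber = character(0), absorbed = character(0),
                       release_id = character(0), stringsAsFactors = FALSE)
  if (config$n_merges > 0L && n_rel[["SWISSPROT"]] >= 2L) {
    sp_accs <- names(entries)[vapply(entries, function(e)
      e$db == "SWISSPROT" && e$birth == 1L, logical(1))]
    need <- 2L * config$n_merges
    if (length(sp_accs) >= need) {
      picked <- sp_accs[sample.int(length(sp_accs), need)]
      for (m in seq_len(config$n_merges)) {
        a <- picked[2L * m - 1L]; b <- picked[2L * m]
        at <- 1L + sample.int(n_rel[["SWISSPROT"]] - 1L, 1L)
        entries[[b]]$absorbed_at <- at
        b_held <- entries[[b]]$held[entries[[b]]$held < at]
        entries[[b]]$held <- b_held
        # the merged entry adopts everything the absorbed one held, from the
        # merge release on; shared sentences must not lapse in between, or a
        # merge would fabricate a removal at lineage level
        shared <- intersect(names(b_held), names(entries[[a]]$held))
        entries[[a]]$held[shared] <- pmin(entries[[a]]$held[shared], at)
        new <- setdiff(names(b_held), names(entries[[a]]$held))
        entries[[a]]$held <- c(entries[[a]]$held,
                               stats::setNames(rep(at, length(new)), new))
        entries[[a]]$secondaries <- c(entries[[a]]$secondaries, b)
        entries[[a]]$merge_at <- at
        merges <- rbind(merges, data.frame(
          absorber = a, absorbed = b,
          release_id = rel[["SWISSPROT"]][at], stringsAsFactors = FALSE))
      }
    }
  }

  # --- planted pattern instances ------------------------------------------
  # each instance uses a dedicated sentence and dedicated entries, with a
  # fully explicit presence schedule (acc -> release indices)
  planted_schedule <- list()   # acc -> list(db, birth, sentence, at = indices)
  manifest_patterns <- data.frame(sentence_text = character(0),
                                  pattern = character(0),
                                  database = character(0),
                                  stringsAsFactors = FALSE)
  eligible <- function(min_rel) dbs[n_rel[dbs] >= min_rel]

  pl <- config$planted
  if (pl[["missing_origin"]] > 0L) {
    el <- eligible(3L)
    for (i in seq_len(pl[["missing_origin"]])) {
      db <- el[1L + ((i - 1L) %% length(el))]
      L <- n_rel[[db]]
      extant <- (L < 4L) || (i %% 2L == 1L)
      a <- sprintf("MOA%03d", i); b <- sprintf("MOB%03d", i)
      s <- sprintf("planted annotation %03d was copied before its origin lost it.", i)
      planted_schedule[[a]] <- list(db = db, birth = 1L, sentence = s, at = 1:2)
      planted_schedule[[b]] <- list(db = db, birth = 2L, sentence = s,
                                    at = if (extant) 2:L else 2:(L - 1L))
      manifest_patterns <- rbind(manifest_patterns, data.frame(
        sentence_text = s, pattern = "MISSING_ORIGIN", database = db,
        stringsAsFactors = FALSE))
    }
  }
  if (pl[["reappearing"]] > 0L) {
    el <- eligible(3L)
    for (i in seq_len(pl[["reappearing"]])) {
      db <- el[1L + ((i - 1L) %% length(el))]
      L <- n_rel[[db]]
      gap <- 1L + (1L + (i - 1L) %% (L - 2L))   # a middle release
      d <- sprintf("RAP%03d", i)
      s <- sprintf("planted annotation %03d was re-added after its removal.", i)
      planted_schedule[[d]] <- list(db = db, birth = 1L, sentence = s,
                                    at = setdiff(1:L, gap))
      manifest_patterns <- rbind(manifest_patterns, data.frame(
        sentence_text = s, pattern = "REAPPEARING_ENTRY", database = db,
        stringsAsFactors = FALSE))
    }
  }
  if (pl[["transient"]] > 0L) {
    el <- eligible(2L)
    for (i in seq_len(pl[["transient"]])) {
      db <- el[1L + ((i - 1L) %% length(el))]
      L <- n_rel[[db]]
      at <- 1L + ((i - 1L) %% (L - 1L))         # never the final release
      d <- sprintf("TRS%03d", i)
      s <- sprintf("planted annotation %03d appeared for a single release only.", i)
      planted_schedule[[d]] <- list(db = db, birth = at, sentence = s, at = at)
      manifest_patterns <- rbind(manifest_patterns, data.frame(
        sentence_text = s, pattern = "TRANSIENT", database = db,
        stringsAsFactors = FALSE))
    }
  }
  if (pl[["trembl_origin"]] > 0L) {
    tr_dates <- cal$date[match(rel[["TREMBL"]], cal$release_id)]
    sp_dates <- cal$date[match(rel[["SWISSPROT"]], cal$release_id)]
    q <- which(sp_dates > tr_dates[1L])[1L]
    for (i in seq_len(pl[["trembl_origin"]])) {
      a <- sprintf("TOT%03d", i); b <- sprintf("TOS%03d", i)
      s <- sprintf("planted annotation %03d originated in the unreviewed section.", i)
      planted_schedule[[a]] <- list(db = "TREMBL", birth = 1L, sentence = s,
                                    at = 1:n_rel[["TREMBL"]])
      planted_schedule[[b]] <- list(db = "SWISSPROT", birth = q, sentence = s,
                                    at = q:n_rel[["SWISSPROT"]])
      manifest_patterns <- rbind(manifest_patterns, data.frame(
        sentence_text = s, pattern = "TREMBL_ORIGIN", database = "TREMBL",
        stringsAsFactors = FALSE))
    }
  }

  # --- entry-level occurrence table ---------------------------------------
  occ_entry <- list()
  ent_rows <- list()
  for (acc in names(entries)) {
    e <- entries[[acc]]
    last <- if (!is.na(e$absorbed_at)) e$absorbed_at - 1L else n_rel[[e$db]]
    if (e$birth > last) next
    for (j in e$birth:last) {
      rid <- rel[[e$db]][j]
      secs <- if (!is.null(e$merge_at) && j >= e$merge_at) e$secondaries
              else character(0)
      sent <- names(e$held)[e$held <= j]
      ent_rows[[length(ent_rows) + 1L]] <-
        list(acc = acc, secs = secs, db = e$db, release_id = rid, sentences = sent)
      if (length(sent))
        occ_entry[[length(occ_entry) + 1L]] <- data.frame(
          acc = acc, release_id = rid, sentence_text = sent,
          stringsAsFactors = FALSE)
    }
  }
  for (acc in names(planted_schedule)) {
    p <- planted_schedule[[acc]]
    for (j in p$birth:n_rel[[p$db]]) {
      rid <- rel[[p$db]][j]
      sent <- if (j %in% p$at) p$sentence else character(0)
      ent_rows[[length(ent_rows) + 1L]] <-
        list(acc = acc, secs = character(0), db = p$db, release_id = rid,
             sentences = sent)
      if (length(sent))
        occ_entry[[length(occ_entry) + 1L]] <- data.frame(
          acc = acc, release_id = rid, sentence_text = sent,
          stringsAsFactors = FALSE)
    }
  }
  occ_entry <- if (length(occ_entry)) do.call(rbind, occ_entry)
               else data.frame(acc = character(0), release_id = character(0),
                               sentence_text = character(0))

  # --- lineage resolution (merge components, smallest accession wins) -----
  lin <- stats::setNames(unique(occ_entry$acc), unique(occ_entry$acc))
  all_accs <- unique(c(vapply(ent_rows, `[[`, character(1), "acc")))
  lin <- stats::setNames(all_accs, all_accs)
  if (nrow(merges)) {
    for (m in seq_len(nrow(merges))) {
      comp <- c(merges$absorber[m], merges$absorbed[m])
      canon <- min(lin[comp])
      lin[names(lin) %in% comp | lin %in% lin[comp]] <- canon
    }
  }

  occ <- unique(data.frame(sentence_text = occ_entry$sentence_text,
                           lineage_id = unname(lin[occ_entry$acc]),
                           release_id = occ_entry$release_id,
                           stringsAsFactors = FALSE))
  occ <- occ[order(occ$sentence_text, occ$release_id, occ$lineage_id), ,
             drop = FALSE]
  rownames(occ) <- NULL

  release_counts <- do.call(rbind, lapply(cal$release_id, function(rid) {
    sub <- occ[occ$release_id == rid, , drop = FALSE]
    tab <- table(sub$sentence_text)
    data.frame(release_id = rid, total = nrow(sub), unique = length(tab),
               singleton = sum(tab == 1L), stringsAsFactors = FALSE)
  }))

  # --- emit flat files -----------------------------------------------------
  files <- lapply(cal$release_id, function(rid) {
    date <- cal$date[cal$release_id == rid]
    db <- cal$database[cal$release_id == rid]
    recs <- Filter(function(r) r$release_id == rid, ent_rows)
    recs <- recs[order(vapply(recs, `[[`, character(1), "acc"))]
    unlist(lapply(recs, function(r)
      .format_record(r$acc, r$secs, date, db, pool_emit, r$sentences)),
      use.names = FALSE)
  })
  names(files) <- cal$release_id

  manifest <- list(occurrences = occ, patterns = manifest_patterns,
                   release_counts = release_counts, merges = merges)
  out <- structure(list(files = files, manifest = manifest, config = config),
                   class = "synthetic_corpus")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (rid in names(files))
      writeLines(files[[rid]], file.path(dir, paste0(rid, ".dat")))
    write_release_calendar(cal, file.path(dir, "calendar.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("synthetic_corpus:", length(x$files), "release files,",
      nrow(x$manifest$occurrences), "true occurrence triples,",
      nrow(x$manifest$patterns), "planted pattern instances\n")
  invisible(x)
}

#' Parse a synthetic corpus into an entry table
#'
#' @param corpus a [generate_corpus()] result.
#' @return \code{data.frame} of parsed entries across all releases, suitable
#'   for [build_index()].
#' @export
corpus_entries <- function(corpus) {
  do.call(rbind, lapply(names(corpus$files), function(rid)
    parse_flatfile(corpus$files[[rid]], release_id = rid)))
}

#' Parse and index a synthetic corpus
#'
#' Convenience wrapper: [corpus_entries()] then [build_index()] with the
#' generating calendar.
#'
#' @param corpus a [generate_corpus()] result.
#' @return an \code{occurrence_index}.
#' @export
index_corpus <- function(corpus) {
  build_index(corpus_entries(corpus), corpus$config$calendar)
}
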