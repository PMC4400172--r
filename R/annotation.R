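#' Construct a debate annotation
#'
#' A `debate_annotation` is the conversational timeline of a broadcast
#' event: an ordered set of speech turns (speaker, start/end in seconds
#' relative to event onset, interruption flag), an absolute onset
#' timestamp used to align a message stream, and a list of salient
#' events (pointed remarks whose key terms propagate through social
#' media).
#'
#' Turn times are seconds relative to `onset_timestamp`.  Turns are
#' sorted by start time on construction.  Overlapping turns are legal —
#' an interruption starts before the previous speaker has finished —
#' but two turns may not share an identical start time, because the
#' per-second floor-resolution rule ("last starter holds the floor")
#' would then be ambiguous.
#'
#' @param onset_timestamp Absolute event onset, epoch seconds.
#' @param duration_s Event duration in seconds (> 0).
#' @param speakers Character vector of speaker labels: the two
#'   principals (candidates) plus an optional moderator.
#' @param turns Data frame with columns `speaker`, `start_s`, `end_s`,
#'   `is_interruption`.
#' @param salient_events Data frame with columns `label`, `onset_s` and
#'   a list column `match_terms` (lowercase root terms, e.g.
#'   `"big bird"`), or `NULL`.
#' @param moderator Label of the moderator within `speakers`, or `NULL`
#'   if every speaker is a principal.
#' @return An object of class `debate_annotation`.
#' @seealso [read_annotation()], [floor_holder()], [generate_debate()]
#' @export
debate_annotation <- function(onset_timestamp, duration_s, speakers, turns,
                              salient_events = NULL, moderator = NULL) {
  stopifnot(is.numeric(onset_timestamp), length(onset_timestamp) == 1L,
            is.numeric(duration_s), length(duration_s) == 1L)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be a positive finite number of seconds")
  speakers <- as.character(speakers)
  if (!is.null(moderator) && !moderator %in% speakers)
    stop("moderator label must be one of `speakers`")
  turns <- as.data.frame(turns)
  required <- c("speaker", "start_s", "end_s", "is_interruption")
  missing_cols <- setdiff(required, names(turns))
  if (length(missing_cols))
    stop("turns is missing column(s): ", paste(missing_cols, collapse = ", "))
  turns$speaker <- as.character(turns$speaker)
  turns$start_s <- as.numeric(turns$start_s)
  turns$end_s <- as.numeric(turns$end_s)
  turns$is_interruption <- as.logical(turns$is_interruption)
  turns <- turns[order(turns$start_s), required, drop = FALSE]
  rownames(turns) <- NULL

  if (is.null(salient_events)) {
    salient_events <- data.frame(label = character(), onset_s = numeric())
    salient_events$match_terms <- list()
  } else {
    salient_events <- as.data.frame(salient_events)
    if (!all(c("label", "onset_s") %in% names(salient_events)))
      stop("salient_events needs columns label, onset_s, match_terms")
    if (is.null(salient_events$match_terms))
      stop("salient_events needs a match_terms list column")
    salient_events$match_terms <- lapply(salient_events$match_terms,
                                         as.character)
  }

  ann <- structure(
    list(onset_timestamp = as.numeric(onset_timestamp),
         duration_s = as.numeric(duration_s),
         speakers = speakers,
         moderator = moderator,
         turns = turns,
         salient_events = salient_events),
    class = "debate_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  turns <- ann$turns
  if (nrow(turns)) {
    bad <- which(!(turns$end_s > turns$start_s))
    if (length(bad))
      stop(sprintf("turn %d: end_s (%g) must be greater than start_s (%g)",
                   bad[1L], turns$end_s[bad[1L]], turns$start_s[bad[1L]]))
    bad <- which(turns$start_s < 0 | turns$end_s > ann$duration_s)
    if (length(bad))
      stop(sprintf("turn %d lies outside [0, duration_s]", bad[1L]))
    bad <- which(!turns$speaker %in% ann$speakers)
    if (length(bad))
      stop(sprintf("turn %d: speaker '%s' is not in the declared speaker set",
                   bad[1L], turns$speaker[bad[1L]]))
    dup <- which(duplicated(turns$start_s))
    if (length(dup))
      stop(sprintf(paste("turns %d and %d share start time %g;",
                         "floor resolution is ambiguous"),
                   dup[1L] - 1L, dup[1L], turns$start_s[dup[1L]]))
  }
  ev <- ann$salient_events
  if (nrow(ev)) {
    if (any(ev$onset_s < 0 | ev$onset_s > ann$duration_s))
      stop("salient event onset outside [0, duration_s]")
    n_terms <- vapply(ev$match_terms, length, integer(1L))
    if (any(n_terms == 0L))
      stop("every salient event needs at least one match term")
    low <- vapply(ev$match_terms,
                  function(x) identical(x, tolower(x)), logical(1L))
    if (!all(low)) stop("salient event match terms must be lowercase")
  }
  invisible(ann)
}

#' @method print debate_annotation
#' @export
print.debate_annotation <- function(x, ...) {
  cat("Debate annotation\n")
  cat(sprintf("  onset: %.3f (epoch s), duration: %g s\n",
              x$onset_timestamp, x$duration_s))
  cat(sprintf("  speakers: %s%s\n", paste(x$speakers, collapse = ", "),
              if (!is.null(x$moderator))
                sprintf(" (moderator: %s)", x$moderator) else ""))
  cat(sprintf("  %d turns (%d interruptions), %d salient event(s)\n",
              nrow(x$turns), sum(x$turns$is_interruption),
              nrow(x$salient_events)))
  invisible(x)
}

#' Principal (candidate) speakers of an annotation
#'
#' The declared speakers minus the moderator, i.e. the speakers whose
#' mentions are tracked as channels.
#'
#' @param annotation A [debate_annotation()].
#' @return Character vector of principal labels.
#' @export
candidates <- function(annotation) {
  setdiff(annotation$speakers, annotation$moderator)
}

#' Resolve which turn holds the floor at given times
#'
#' At time `t` the floor-holder is the turn with the latest start not
#' later than `t` that has not yet ended — the "last starter wins" rule,
#' which mirrors interruption semantics: an interrupter takes the floor
#' at their start, and the floor reverts to the interrupted turn if it
#' outlasts the interruption.
#'
#' @param annotation A [debate_annotation()].
#' @param t Numeric vector of times in seconds relative to event onset.
#' @return Integer vector of row indices into `annotation$turns`
#'   (`NA` where no turn is active).
#' @export
floor_holder <- function(annotation, t) {
  turns <- annotation$turns
  if (!nrow(turns)) return(rep(NA_integer_, length(t)))
  starts <- turns$start_s
  ends <- turns$end_s
  last_started <- findInterval(t, starts)
  vapply(seq_along(t), function(i) {
    j <- last_started[i]
    while (j >= 1L) {
      if (ends[j] > t[i]) return(j)
      j <- j - 1L
    }
    NA_integer_
  }, integer(1L))
}

#' Read a debate annotation from file
#'
#' Two on-disk layouts are supported.  `format = "json"` is a single
#' JSON document with fields `onset_timestamp`, `duration_s`,
#' `speakers`, optional `moderator`, `turns` (array of objects with
#' `speaker`, `start_s`, `end_s`, `is_interruption`) and
#' `salient_events` (array of objects with `label`, `onset_s`,
#' `match_terms`).  `format = "csv"` is a turn table with columns
#' `speaker,start_s,end_s,is_interruption` plus a JSON sidecar (default
#' `<path>.meta.json`) holding everything else.
#'
#' @param path Input file.
#' @param format `"json"` or `"csv"`; guessed from the extension by
#'   default.
#' @param sidecar Path of the JSON sidecar used by the CSV layout.
#' @return A [debate_annotation()].
#' @export
read_annotation <- function(path,
                            format = c("auto", "json", "csv"),
                            sidecar = paste0(path, ".meta.json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    turns <- parse_turn_rows(doc$turns, path)
    ev <- parse_salient_rows(doc$salient_events)
    debate_annotation(
      onset_timestamp = as.numeric(doc$onset_timestamp),
      duration_s = as.numeric(doc$duration_s),
      speakers = unlist(doc$speakers),
      moderator = if (is.null(doc$moderator)) NULL else doc$moderator[[1L]],
      turns = turns, salient_events = ev)
  } else {
    turns <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("speaker", "start_s", "end_s", "is_interruption")
    if (!all(required %in% names(turns)))
      stop("annotation CSV must have columns ",
           paste(required, collapse = ","), ": ", path)
    for (col in c("start_s", "end_s")) {
      v <- suppressWarnings(as.numeric(turns[[col]]))
      bad <- which(is.na(v) & !is.na(turns[[col]]))
      if (length(bad))
        stop(sprintf("%s line %d: non-numeric %s '%s'",
                     path, bad[1L] + 1L, col, turns[[col]][bad[1L]]))
      turns[[col]] <- v
    }
    if (!file.exists(sidecar))
      stop("annotation CSV needs its JSON sidecar: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
    debate_annotation(
      onset_timestamp = as.numeric(meta$onset_timestamp),
      duration_s = as.numeric(meta$duration_s),
      speakers = unlist(meta$speakers),
      moderator = if (is.null(meta$moderator)) NULL else meta$moderator[[1L]],
      turns = turns, salient_events = parse_salient_rows(meta$salient_events))
  }
}

parse_turn_rows <- function(rows, path) {
  if (is.null(rows) || !length(rows))
    return(data.frame(speaker = character(), start_s = numeric(),
                      end_s = numeric(), is_interruption = logical()))
  req <- c("speaker", "start_s", "end_s", "is_interruption")
  for (i in seq_along(rows)) {
    miss <- setdiff(req, names(rows[[i]]))
    if (length(miss))
      stop(sprintf("%s: turn %d is missing field(s) %s",
                   path, i, paste(miss, collapse = ", ")))
  }
  data.frame(
    speaker = vapply(rows, function(r) as.character(r$speaker), character(1L)),
    start_s = vapply(rows, function(r) as.numeric(r$start_s), numeric(1L)),
    end_s = vapply(rows, function(r) as.numeric(r$end_s), numeric(1L)),
    is_interruption = vapply(rows, function(r) as.logical(r$is_interruption),
                             logical(1L)))
}

parse_salient_rows <- function(rows) {
  if (is.null(rows) || !length(rows)) return(NULL)
  ev <- data.frame(
    label = vapply(rows, function(r) as.character(r$label), character(1L)),
    onset_s = vapply(rows, function(r) as.numeric(r$onset_s), numeric(1L)))
  ev$match_terms <- lapply(rows, function(r) unlist(r$match_terms))
  ev
}

#' Write a debate annotation to file
#'
#' Inverse of [read_annotation()]; `write_annotation()` followed by
#' `read_annotation()` is an identity (up to turn ordering, which both
#' normalise).
#'
#' @param annotation A [debate_annotation()].
#' @param path Output file.
#' @param format `"json"` (single file) or `"csv"` (+ JSON sidecar).
#' @param sidecar Sidecar path for the CSV layout.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path,
                             format = c("auto", "json", "csv"),
                             sidecar = paste0(path, ".meta.json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  ev_list <- lapply(seq_len(nrow(annotation$salient_events)), function(i) {
    list(label = annotation$salient_events$label[i],
         onset_s = annotation$salient_events$onset_s[i],
         match_terms = as.list(annotation$salient_events$match_terms[[i]]))
  })
  meta <- list(onset_timestamp = annotation$onset_timestamp,
               duration_s = annotation$duration_s,
               speakers = as.list(annotation$speakers),
               moderator = annotation$moderator,
               salient_events = ev_list)
  if (format == "json") {
    turn_list <- lapply(seq_len(nrow(annotation$turns)), function(i)
      as.list(annotation$turns[i, ]))
    doc <- c(meta[c("onset_timestamp", "duration_s", "speakers", "moderator")],
             list(turns = turn_list, salient_events = ev_list))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    utils::write.csv(annotation$turns, path, row.names = FALSE)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Read speech turns from a Praat TextGrid interval tier
#'
#' Minimal reader for the long ("ooTextFile") TextGrid format produced
#' by Praat.  Non-empty labelled intervals of one interval tier become
#' speech turns; empty labels are silences and are skipped.  Only turns
#' are recovered — onset timestamp, duration, and salient events must
#' be supplied to assemble a full [debate_annotation()].
#'
#' @param path TextGrid file.
#' @param tier Name or 1-based index of the interval tier to read.
#' @return Data frame with columns `speaker`, `start_s`, `end_s`,
#'   `is_interruption` (interruption inferred from overlap with the
#'   preceding interval, which plain TextGrid tiers cannot encode:
#'   always `FALSE`).
#' @export
read_textgrid_turns <- function(path, tier = 1L) {
  lines <- readLines(path, warn = FALSE)
  strip <- function(x) gsub('^[^"]*"|"[^"]*$', "", x)
  num <- function(x) as.numeric(sub("^.*=\\s*", "", x))
  tier_starts <- grep("item\\s*\\[\\s*[0-9]+\\s*\\]", lines)
  if (!length(tier_starts)) stop("no tiers found in TextGrid: ", path)
  tier_names <- vapply(tier_starts, function(i) {
    nm <- grep("^\\s*name\\s*=", lines[i:min(i + 5L, length(lines))],
               value = TRUE)
    if (length(nm)) strip(nm[1L]) else ""
  }, character(1L))
  idx <- if (is.character(tier)) match(tier, tier_names) else as.integer(tier)
  if (is.na(idx) || idx < 1L || idx > length(tier_starts))
    stop("tier not found in TextGrid: ", tier)
  from <- tier_starts[idx]
  to <- if (idx < length(tier_starts)) tier_starts[idx + 1L] - 1L
        else length(lines)
  block <- lines[from:to]
  xmin <- num(grep("^\\s*xmin\\s*=", block, value = TRUE))
  xmax <- num(grep("^\\s*xmax\\s*=", block, value = TRUE))
  labs <- strip(grep("^\\s*text\\s*=", block, value = TRUE))
  # first xmin/xmax pair describes the tier itself, the rest its intervals
  if (length(xmin) > length(labs)) {
    xmin <- xmin[-1L]; xmax <- xmax[-1L]
  }
  keep <- nzchar(trimws(labs))
  data.frame(speaker = trimws(labs[keep]),
             start_s = xmin[keep], end_s = xmax[keep],
             is_interruption = FALSE)
}
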