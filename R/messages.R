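#' Read a timestamped message stream
#'
#' A message stream is a data frame with columns `timestamp` (epoch
#' seconds, numeric), `text` (character) and `is_retweet` (logical).
#' `format = "jsonl"` reads JSON Lines with fields `timestamp` (epoch
#' float or ISO-8601 string), `text` and optional `is_retweet`;
#' `format = "csv"` reads the equivalent CSV.  When `is_retweet` is
#' absent it is inferred from the conventional `"RT @"` text prefix,
#' emulating the platform metadata flag.
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension.
#' @return Data frame with columns `timestamp`, `text`, `is_retweet`.
#' @export
read_messages <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "jsonl") {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(text = "character"))
  }
  if (!all(c("timestamp", "text") %in% names(df)))
    stop("message stream needs fields timestamp and text: ", path)
  df$timestamp <- parse_timestamp(df$timestamp, path)
  df$text <- as.character(df$text)
  if (is.null(df$is_retweet)) {
    df$is_retweet <- startsWith(df$text, "RT @")
  } else {
    df$is_retweet <- as.logical(df$is_retweet)
  }
  df[c("timestamp", "text", "is_retweet")]
}

parse_timestamp <- function(x, path = "<messages>") {
  if (is.numeric(x)) {
    if (any(!is.finite(x))) stop("non-finite timestamp in ", path)
    return(as.numeric(x))
  }
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  iso <- is.na(num)
  if (any(iso)) {
    parsed <- as.POSIXct(x[iso], tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS"))
    if (any(is.na(parsed))) {
      bad <- which(iso)[which(is.na(parsed))[1L]]
      stop(sprintf("%s line %d: unparseable timestamp '%s'",
                   path, bad, x[bad]))
    }
    num[iso] <- as.numeric(parsed)
  }
  num
}

#' Write a message stream
#'
#' Inverse of [read_messages()].
#'
#' @param messages Message data frame (`timestamp`, `text`,
#'   `is_retweet`).
#' @param path Output file.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_messages <- function(messages, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  messages <- as.data.frame(messages)[c("timestamp", "text", "is_retweet")]
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    jsonlite::stream_out(messages, con, verbose = FALSE, digits = NA)
  } else {
    utils::write.csv(messages, path, row.names = FALSE)
  }
  invisible(path)
}

#' Message filtering specification
#'
#' Captures the inclusion/exclusion rules applied to a raw stream
#' before any rate is computed: keep messages mentioning at least one
#' target root term (case-insensitive substring, so `"#obama2012"`
#' matches the term `"obama"`); drop messages containing a URL
#' (a spam-bot heuristic); drop retweets (verbatim reposts), so rate
#' patterns are not driven by repetition of the same message.
#'
#' @param include_terms Character vector of lowercase root terms.
#' @param exclude_urls Drop messages whose text contains `http://`,
#'   `https://` or `www.` (case-insensitive)?
#' @param exclude_retweets Drop messages flagged as retweets?
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(include_terms, exclude_urls = TRUE,
                        exclude_retweets = TRUE) {
  include_terms <- as.character(include_terms)
  if (!length(include_terms) || any(!nzchar(include_terms)))
    stop("include_terms must be a non-empty set of non-empty strings")
  if (!identical(include_terms, tolower(include_terms)))
    stop("include_terms must be lowercase")
  structure(list(include_terms = include_terms,
                 exclude_urls = isTRUE(exclude_urls),
                 exclude_retweets = isTRUE(exclude_retweets)),
            class = "filter_spec")
}

#' @method print filter_spec
#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Filter: terms {%s}; URLs %s; retweets %s\n",
              paste(x$include_terms, collapse = ", "),
              if (x$exclude_urls) "excluded" else "kept",
              if (x$exclude_retweets) "excluded" else "kept"))
  invisible(x)
}

has_url <- function(text) {
  grepl("http://|https://|www\\.", text, ignore.case = TRUE)
}

#' Filter a message stream and assign messages to term channels
#'
#' Applies a [filter_spec()] to a stream: after the URL and retweet
#' exclusions, each surviving message is assigned to every term whose
#' lowercase form occurs as a substring of the lowercased text (a
#' message mentioning both principals appears under both terms).
#'
#' @param messages Message data frame (`timestamp`, `text`,
#'   `is_retweet`).
#' @param spec A [filter_spec()].
#' @return Named list (one element per term) of message data frames,
#'   each carrying a `.idx` column with the row index in `messages`
#'   so that multi-term membership can be resolved downstream.
#' @export
filter_messages <- function(messages, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  messages <- as.data.frame(messages)
  if (is.null(messages$.idx)) messages$.idx <- seq_len(nrow(messages))
  keep <- rep(TRUE, nrow(messages))
  if (spec$exclude_urls) keep <- keep & !has_url(messages$text)
  if (spec$exclude_retweets) {
    rt <- if (!is.null(messages$is_retweet)) messages$is_retweet
          else startsWith(messages$text, "RT @")
    keep <- keep & !rt
  }
  survivors <- messages[keep, , drop = FALSE]
  lower <- tolower(survivors$text)
  out <- lapply(spec$include_terms, function(term)
    survivors[grepl(term, lower, fixed = TRUE), , drop = FALSE])
  names(out) <- spec$include_terms
  out
}
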