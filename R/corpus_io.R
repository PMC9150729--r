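#' Write post records to JSONL or CSV
#'
#' JSONL output has one UTF-8 JSON object per line; CSV output has a header
#' row with RFC-4180 quoting. Timestamps are serialized as ISO-8601 UTC
#' (`YYYY-MM-DDTHH:MM:SS`).
#'
#' @param posts Tibble of post records (see [generate_corpus()] for columns).
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(posts, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  check_posts(posts)
  out <- posts
  out$timestamp <- format_utc(out$timestamp)
  if (format == "csv") {
    readr::write_csv(out, path, na = "")
  } else {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      row <- lapply(out[i, post_columns], function(v) v[[1]])
      if (is.na(row$country)) row$country <- NULL
      jsonlite::toJSON(row, auto_unbox = TRUE, null = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Load and validate a post corpus
#'
#' Reads post records from JSONL (one object per line) or CSV, validates the
#' required fields, normalizes timestamps to UTC, and skips malformed rows
#' (missing `post_id`, unparseable timestamp, unknown platform) with a
#' warning giving the number skipped. Record order is preserved.
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return Tibble of validated post records; the number of skipped rows is
#'   attached as attribute `n_skipped`.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "aefitrends_io_error")
  }
  if (format == "csv") {
    raw <- tryCatch(
      readr::read_csv(path, col_types = readr::cols(.default = readr::col_character())),
      error = function(e) abort(sprintf("Cannot parse CSV file %s: %s", path,
                                        conditionMessage(e)),
                                class = "aefitrends_format_error"))
    missing <- setdiff(post_columns, names(raw))
    if (length(missing) > 0) {
      abort(sprintf("CSV %s is missing required column(s): %s", path,
                    paste(missing, collapse = ", ")),
            class = "aefitrends_schema_error")
    }
    rows <- lapply(seq_len(nrow(raw)), function(i) as.list(raw[i, ]))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE), error = function(e) NULL)
    })
  }

  parsed <- lapply(rows, parse_post_row)
  ok <- !vapply(parsed, is.null, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(sprintf("Skipped %d malformed record(s) while reading %s",
                 n_skipped, path))
  }
  posts <- dplyr::bind_rows(parsed[ok])
  if (nrow(posts) == 0) {
    posts <- tibble(platform = character(), post_id = character(),
                    user_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                    text = character(), country = character(), is_repost = logical())
  }
  attr(posts, "n_skipped") <- n_skipped
  posts
}

# One raw row -> validated one-row tibble, or NULL when malformed.
parse_post_row <- function(row) {
  if (is.null(row) || !is.list(row)) return(NULL)
  get_chr <- function(k) {
    v <- row[[k]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !nzchar(as.character(v))) NA_character_
    else as.character(v)
  }
  platform <- get_chr("platform")
  post_id <- get_chr("post_id")
  user_id <- get_chr("user_id")
  text <- row[["text"]]
  text <- if (is.null(text) || length(text) != 1L || is.na(text)) NA_character_ else as.character(text)
  ts_raw <- get_chr("timestamp")
  if (is.na(platform) || !platform %in% c("facebook", "twitter")) return(NULL)
  if (is.na(post_id) || is.na(user_id) || is.na(ts_raw) || is.na(text)) return(NULL)
  ts <- parse_utc(ts_raw)
  if (is.na(ts)) return(NULL)
  country <- get_chr("country")
  if (!is.na(country)) country <- toupper(country)
  rp <- row[["is_repost"]]
  rp <- if (is.null(rp) || length(rp) != 1L) FALSE else isTRUE(as.logical(rp))
  tibble(platform = platform, post_id = post_id, user_id = user_id,
         timestamp = ts, text = text, country = country, is_repost = rp)
}

#' Drop duplicate posts
#'
#' Keeps the first occurrence of each (`platform`, `post_id`) pair, so that
#' every remaining record is a unique post. Idempotent.
#'
#' @param posts Tibble of post records.
#' @return Tibble with duplicates removed, original order preserved.
#' @export
deduplicate_posts <- function(posts) {
  check_posts(posts)
  posts[!duplicated(posts[c("platform", "post_id")]), , drop = FALSE]
}

#' Remove reposts and retweets
#'
#' Drops records flagged `is_repost`, and twitter records whose text begins
#' with the conventional retweet prefix `"RT @"` even when unflagged.
#' Idempotent.
#'
#' @param posts Tibble of post records.
#' @return Tibble of original (non-repost) posts.
#' @export
exclude_reposts <- function(posts) {
  check_posts(posts)
  rt_prefix <- posts$platform == "twitter" & startsWith(posts$text, "RT @")
  posts[!(posts$is_repost | rt_prefix), , drop = FALSE]
}

#' Geographical filter
#'
#' Retains posts whose `country` equals `target_country` (case-insensitive
#' ISO-3166 alpha-2 comparison). Posts with no country code are dropped: the
#' filter is applied across the whole data set and unlocated posts cannot be
#' attributed to the target country.
#'
#' @param posts Tibble of post records.
#' @param target_country ISO-3166 alpha-2 code, default `"GB"`.
#' @return Tibble of posts located in the target country.
#' @export
geo_filter <- function(posts, target_country = "GB") {
  check_posts(posts)
  if (!is.character(target_country) || length(target_country) != 1L ||
      !grepl("^[A-Za-z]{2}$", target_country)) {
    stop_invalid("target_country", "must be an ISO-3166 alpha-2 code")
  }
  keep <- !is.na(posts$country) &
    toupper(posts$country) == toupper(target_country)
  posts[keep, , drop = FALSE]
}
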