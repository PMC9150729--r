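# Internal validation and date helpers shared across modules.

# Abort with a consistent class so callers can test on condition class.
stop_invalid <- function(field, msg) {
  abort(sprintf("Invalid `%s`: %s", field, msg), class = "aefitrends_validation_error")
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_invalid(field, "must be a single probability in [0, 1]")
  }
  invisible(x)
}

as_utc_date <- function(x, field = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) stop_invalid(field, "must be a parseable calendar date")
  d
}

# Parse character timestamps to POSIXct UTC; NA where unparseable.
parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  out
}

format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# 0-based bin index of timestamp t for bins of `width_days` anchored at `origin`
# (a Date); bins are left-closed, right-open in time.
bin_index <- function(t, origin, width_days) {
  secs <- as.numeric(t) - as.numeric(as.POSIXct(paste0(origin, " 00:00:00"), tz = "UTC"))
  floor(secs / (width_days * 86400))
}

bin_starts_covering <- function(origin, window_end, width_days) {
  # All bin start dates from origin through the bin containing window_end.
  n_bins <- floor(as.numeric(window_end - origin) / width_days) + 1L
  origin + (seq_len(n_bins) - 1L) * width_days
}

# Columns every post tibble must carry.
post_columns <- c("platform", "post_id", "user_id", "timestamp", "text",
                  "country", "is_repost")

check_posts <- function(posts, arg = "posts") {
  if (!is.data.frame(posts)) stop_invalid(arg, "must be a data frame of post records")
  missing <- setdiff(post_columns, names(posts))
  if (length(missing) > 0) {
    stop_invalid(arg, paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(posts)
}
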