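# Shared fixture builders and independent oracles.

# Vectorized post-tibble builder with sensible defaults.
make_posts <- function(text,
                       platform = "facebook",
                       post_id = sprintf("p%03d", seq_along(text)),
                       user_id = "u1",
                       timestamp = as.POSIXct("2021-01-15 12:00:00", tz = "UTC"),
                       country = "GB",
                       is_repost = FALSE) {
  tibble::tibble(platform = platform, post_id = post_id, user_id = user_id,
                 timestamp = as.POSIXct(timestamp, tz = "UTC"), text = text,
                 country = country, is_repost = is_repost)
}

# Independent word-boundary term matcher: character-level scan using base R
# only (gregexpr on the lower-cased text, then boundary checks), no shared
# code with the package's regex path.
oracle_term_count <- function(text, term) {
  txt <- tolower(text)
  term <- tolower(gsub("\\s+", " ", trimws(term)))
  # normalize runs of whitespace in the text so phrases match across them
  txt <- gsub("\\s+", " ", txt)
  hits <- gregexpr(term, txt, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(0L)
  is_alnum <- function(ch) grepl("[[:alnum:]]", ch)
  n <- 0L
  for (h in hits) {
    before <- if (h == 1) "" else substr(txt, h - 1, h - 1)
    after_pos <- h + nchar(term)
    after <- if (after_pos > nchar(txt)) "" else substr(txt, after_pos, after_pos)
    if ((before == "" || !is_alnum(before)) && (after == "" || !is_alnum(after))) {
      n <- n + 1L
    }
  }
  n
}

oracle_match_any <- function(text, terms) {
  any(vapply(terms, function(t) oracle_term_count(text, t) > 0, logical(1)))
}

# Ground-truth tally of group mention shares (fraction of posts mentioning
# each group, normalized over groups).
truth_group_shares <- function(truth, groups) {
  tallies <- vapply(groups, function(g) {
    sum(vapply(truth$aefi_groups, function(x) g %in% x, logical(1)))
  }, numeric(1))
  100 * tallies / sum(tallies)
}
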