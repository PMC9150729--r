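#' Define a grouped AEFI lexicon
#'
#' Maps adverse-effect group names (e.g. `clots`, `injection_site`) to the
#' term lists that count as mentions of that group. A term appearing in two
#' groups counts toward both; a validation warning is emitted when that
#' happens so accidental overlap is visible.
#'
#' @param groups Named list, group name -> non-empty character vector of
#'   terms/phrases.
#' @return Object of class `aefi_lexicon`.
#' @seealso [default_aefi_lexicon()], [count_mentions()]
#' @export
aefi_lexicon <- function(groups) {
  if (!is.list(groups) || length(groups) == 0 || is.null(names(groups)) ||
      any(names(groups) == "") || anyDuplicated(names(groups))) {
    stop_invalid("groups", "must be a named list with unique, non-empty names")
  }
  for (g in names(groups)) {
    t <- groups[[g]]
    if (!is.character(t) || length(t) == 0 || any(!nzchar(t)) || any(is.na(t))) {
      stop_invalid(g, "term list must be non-empty character with no empty terms")
    }
  }
  all_terms <- unlist(lapply(groups, tolower), use.names = FALSE)
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup) > 0) {
    warn(sprintf("Term(s) shared between AEFI groups (counted in each): %s",
                 paste(dup, collapse = ", ")))
  }
  structure(groups, class = "aefi_lexicon")
}

#' Default AEFI lexicon
#'
#' Ten tracked groups covering the most-discussed vaccine adverse effects
#' during the UK rollout: appetite change, allergy, injection-site reactions,
#' blood clots, Bell palsy, Guillain-Barre syndrome, headache, fever,
#' diarrhea, and a generalized-symptom group (lethargy, muscle ache, flu,
#' vomiting, nausea).
#'
#' @return An `aefi_lexicon`.
#' @export
default_aefi_lexicon <- function() {
  aefi_lexicon(list(
    appetite = c("appetite", "loss of appetite", "appetite change"),
    allergy = c("allergy", "allergic", "allergies", "anaphylaxis"),
    injection_site = c("injection site", "sore arm", "arm soreness"),
    clots = c("blood clot", "blood clots", "clot", "clots", "thrombosis"),
    bell_palsy = c("bell palsy", "bells palsy", "bell's palsy", "facial droop"),
    guillain_barre = c("guillain-barre", "guillain barre", "gbs syndrome",
                       "guillain barre syndrome"),
    headache = c("headache", "headaches", "migraine"),
    fever = c("fever", "high temperature", "feverish"),
    diarrhea = c("diarrhea", "diarrhoea"),
    generalized = c("lethargy", "lethargic", "muscle ache", "muscle aches",
                    "flu", "vomit", "vomiting", "nausea", "nauseous")
  ))
}

#' Read an AEFI lexicon from YAML or JSON
#'
#' Expected structure: a mapping from group name to a list of terms.
#'
#' @param path Config file path (`.yml`/`.yaml` or `.json`).
#' @return An `aefi_lexicon`.
#' @export
read_aefi_lexicon <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  aefi_lexicon(lapply(cfg, function(t) as.character(unlist(t))))
}

#' Count grouped AEFI mentions per post
#'
#' For each post and lexicon group, counts term occurrences in the
#' case-folded text under word-boundary matching. Occurrences of the same
#' term are counted by a non-overlapping left-to-right scan; distinct terms
#' count independently (so a post can contribute several mentions to one
#' group, and to several groups).
#'
#' @param posts Tibble of post records.
#' @param lexicon An [aefi_lexicon()].
#' @return Tidy tibble with one row per post x group: `platform`, `post_id`,
#'   `group`, `count`.
#' @export
#' @examples
#' posts <- tibble::tibble(platform = "twitter", post_id = "p1", user_id = "u1",
#'   timestamp = as.POSIXct("2021-01-01", tz = "UTC"),
#'   text = "headache and fever, then another headache",
#'   country = "GB", is_repost = FALSE)
#' lex <- aefi_lexicon(list(headache = "headache", fever = "fever"))
#' count_mentions(posts, lex)
count_mentions <- function(posts, lexicon) {
  check_posts(posts)
  if (!inherits(lexicon, "aefi_lexicon")) {
    stop_invalid("lexicon", "must be an aefi_lexicon")
  }
  groups <- names(lexicon)
  n <- nrow(posts)
  per_group <- lapply(groups, function(g) {
    terms <- lexicon[[g]]
    counts <- integer(n)
    for (term in terms) {
      pat <- stage_pattern(term, "word_boundary")
      counts <- counts + stringr::str_count(posts$text, pat)
    }
    tibble(platform = posts$platform, post_id = posts$post_id,
           group = g, count = counts)
  })
  out <- dplyr::bind_rows(per_group)
  out <- dplyr::arrange(out, match(.data$post_id, posts$post_id),
                        match(.data$group, groups))
  out
}

#' Bin mention counts into fixed-width time bins
#'
#' Assigns each post's mention counts to the bin
#' `floor((timestamp - bin_origin) / bin_width days)` (bins left-closed,
#' right-open, anchored at `bin_origin`) and sums per group. The table
#' covers every bin from the origin through `window_end`, including empty
#' bins and a final partial bin.
#'
#' @param mention_counts Per-post counts from [count_mentions()].
#' @param posts The post tibble the counts were computed from.
#' @param bin_origin First bin start date (default 2020-12-08, the rollout
#'   start).
#' @param bin_width Bin width in days (default 14).
#' @param window_end Last calendar date covered (default 2021-04-30).
#' @param groups Group names the table must cover; defaults to the groups
#'   present in `mention_counts`. Pass the lexicon's group names to get a
#'   full table of zeros for an empty corpus.
#' @return Tidy tibble of class `mention_table`: `group`, `bin_start`,
#'   `bin_end` (inclusive dates), `count`; attributes `bin_origin`,
#'   `bin_width`, `window_end`.
#' @export
bin_mentions <- function(mention_counts, posts,
                         bin_origin = as.Date("2020-12-08"),
                         bin_width = 14,
                         window_end = as.Date("2021-04-30"),
                         groups = unique(mention_counts$group)) {
  check_posts(posts)
  bin_origin <- as_utc_date(bin_origin, "bin_origin")
  window_end <- as_utc_date(window_end, "window_end")
  idx <- bin_index(posts$timestamp, bin_origin, bin_width)
  if (any(idx < 0)) {
    abort("All post timestamps must fall on or after bin_origin",
          class = "aefitrends_contract_error")
  }
  starts <- bin_starts_covering(bin_origin, window_end, bin_width)

  post_bin <- tibble(platform = posts$platform, post_id = posts$post_id,
                     bin = idx)
  joined <- dplyr::inner_join(mention_counts, post_bin,
                              by = c("platform", "post_id"))
  binned <- joined |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  grid <- tidyr::expand_grid(group = groups, bin = seq_along(starts) - 1L)
  out <- grid |>
    dplyr::left_join(binned, by = c("group", "bin")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L),
                  bin_start = starts[.data$bin + 1L],
                  bin_end = starts[.data$bin + 1L] + bin_width - 1L) |>
    dplyr::select("group", "bin_start", "bin_end", "count")
  structure(out, class = c("mention_table", class(out)),
            bin_origin = bin_origin, bin_width = bin_width,
            window_end = window_end)
}

#' Per-group totals and percentages of all grouped mentions
#'
#' Percentage of group g is `100 * total[g] / grand_total`, reported rounded
#' (default: nearest integer, the conventional presentation) alongside the
#' full-precision value.
#'
#' @param table A `mention_table` from [bin_mentions()], or any tibble with
#'   `group` and `count` columns.
#' @param digits Rounding for the `percentage` column (default 0).
#' @return Tibble: `group`, `total`, `percentage`, `percentage_raw`.
#' @export
mention_percentages <- function(table, digits = 0) {
  if (!is.data.frame(table) || !all(c("group", "count") %in% names(table))) {
    stop_invalid("table", "must contain `group` and `count` columns")
  }
  totals <- table |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  grand <- sum(totals$total)
  if (grand <= 0) {
    abort("Grand total of mentions is zero; percentages undefined",
          class = "aefitrends_contract_error")
  }
  totals |>
    dplyr::mutate(percentage_raw = 100 * .data$total / grand,
                  percentage = round(.data$percentage_raw, digits)) |>
    dplyr::select("group", "total", "percentage", "percentage_raw")
}

#' Per-user posting-activity statistics
#'
#' Summarizes the distribution of posts per user: the mean is exactly
#' `n_posts / n_users`, the SD is the sample (n-1) standard deviation of the
#' per-user counts, and a natural-log histogram of counts is included for
#' density plotting (per-user activity on social platforms is typically
#' log-normal).
#'
#' @param posts Non-empty tibble of post records.
#' @return Object of class `user_activity`: `n_posts`, `n_users`,
#'   `mean_posts_per_user`, `sd_posts_per_user`, `per_user` (tibble
#'   `user_id`, `n`), `log_hist` (histogram of `log(n)`).
#' @export
user_activity <- function(posts) {
  check_posts(posts)
  if (nrow(posts) == 0) {
    abort("Cannot summarize activity of an empty corpus",
          class = "aefitrends_contract_error")
  }
  per_user <- posts |>
    dplyr::count(.data$user_id, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$user_id)
  n_posts <- nrow(posts)
  n_users <- nrow(per_user)
  structure(
    list(n_posts = n_posts, n_users = n_users,
         mean_posts_per_user = n_posts / n_users,
         sd_posts_per_user = if (n_users > 1) sd(per_user$n) else NA_real_,
         per_user = per_user,
         log_hist = graphics::hist(log(per_user$n), plot = FALSE)),
    class = "user_activity")
}

#' @export
print.user_activity <- function(x, ...) {
  cat(sprintf("<user_activity> %d posts by %d users: mean %.2f (SD %.2f) posts/user\n",
              x$n_posts, x$n_users, x$mean_posts_per_user, x$sd_posts_per_user))
  invisible(x)
}

#' @rdname user_activity
#' @param x A `user_activity` object.
#' @param ... Unused.
#' @method glance user_activity
#' @export
glance.user_activity <- function(x, ...) {
  tibble(n_posts = x$n_posts, n_users = x$n_users,
         mean_posts_per_user = x$mean_posts_per_user,
         sd_posts_per_user = x$sd_posts_per_user)
}

#' @rdname user_activity
#' @method tidy user_activity
#' @export
tidy.user_activity <- function(x, ...) x$per_user
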