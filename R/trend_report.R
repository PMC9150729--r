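#' Weekly sentiment trend series
#'
#' Aggregates per-post sentiment labels into consecutive weekly bins
#' (left-closed, right-open, anchored at `origin`). Each bin reports the
#' count and proportion of every label plus the bin total `n`; bins with no
#' posts are flagged `empty` and carry `NA` proportions.
#'
#' @param labels Label tibble from [classify_corpus()] (needs `platform`,
#'   `post_id`, `label`).
#' @param posts Post tibble providing timestamps; every labeled post must be
#'   present.
#' @param origin First bin start date (default 2020-12-08).
#' @param bin_width Bin width in days (default 7).
#' @param window_end Last calendar date covered (default 2021-04-30).
#' @return Tibble of class `trend_series`: `week_start`, `label`, `count`,
#'   `n`, `proportion`, `empty`.
#' @export
weekly_trend <- function(labels, posts, origin = as.Date("2020-12-08"),
                         bin_width = 7, window_end = as.Date("2021-04-30")) {
  check_posts(posts)
  origin <- as_utc_date(origin, "origin")
  window_end <- as_utc_date(window_end, "window_end")
  joined <- dplyr::left_join(labels, posts[c("platform", "post_id", "timestamp")],
                             by = c("platform", "post_id"))
  if (any(is.na(joined$timestamp))) {
    abort("Label table references post_id(s) absent from `posts`",
          class = "aefitrends_contract_error")
  }
  idx <- bin_index(joined$timestamp, origin, bin_width)
  if (any(idx < 0)) {
    abort("All labeled posts must fall on or after the trend origin",
          class = "aefitrends_contract_error")
  }
  starts <- bin_starts_covering(origin, window_end, bin_width)
  lvls <- c("positive", "negative", "neutral")

  counts <- tibble(bin = idx, label = joined$label) |>
    dplyr::count(.data$bin, .data$label, name = "count")
  grid <- tidyr::expand_grid(bin = seq_along(starts) - 1L, label = lvls)
  out <- grid |>
    dplyr::left_join(counts, by = c("bin", "label")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(n = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(week_start = starts[.data$bin + 1L],
                  empty = .data$n == 0,
                  proportion = ifelse(.data$n > 0, .data$count / .data$n, NA_real_)) |>
    dplyr::select("week_start", "label", "count", "n", "proportion", "empty")
  structure(out, class = c("trend_series", class(out)),
            origin = origin, bin_width = bin_width, window_end = window_end)
}

#' Overall sentiment proportions
#'
#' @param labels Non-empty label tibble from [classify_corpus()].
#' @return Tibble: `label`, `count`, `proportion` (full precision),
#'   `percentage` (rounded to the nearest integer for reporting).
#' @export
overall_proportions <- function(labels) {
  if (!is.data.frame(labels) || !"label" %in% names(labels) || nrow(labels) == 0) {
    abort("Need a non-empty label table", class = "aefitrends_contract_error")
  }
  lvls <- c("positive", "negative", "neutral")
  tibble(label = factor(labels$label, levels = lvls)) |>
    dplyr::count(.data$label, name = "count", .drop = FALSE) |>
    dplyr::mutate(label = as.character(.data$label),
                  proportion = .data$count / sum(.data$count),
                  percentage = round(100 * .data$proportion))
}

#' Attach key events to a weekly trend series
#'
#' Annotations (e.g. regulatory announcements) are attached to the week bin
#' containing their date; the numeric content of the series is unchanged.
#' Events outside the series window are skipped with a warning.
#'
#' @param series A `trend_series` from [weekly_trend()].
#' @param events Tibble or data frame with columns `date` and `text`.
#' @return The series with an `events` attribute (tibble `week_start`,
#'   `date`, `text`).
#' @export
annotate_events <- function(series, events) {
  if (!inherits(series, "trend_series")) {
    stop_invalid("series", "must be a trend_series")
  }
  origin <- attr(series, "origin")
  width <- attr(series, "bin_width")
  window_end <- attr(series, "window_end")
  if (is.null(events) || nrow(events) == 0) {
    attr(series, "events") <- tibble(week_start = as.Date(character()),
                                     date = as.Date(character()),
                                     text = character())
    return(series)
  }
  dates <- as.Date(events$date)
  in_win <- dates >= origin & dates <= window_end
  if (any(!in_win)) {
    warn(sprintf("Skipping %d event(s) outside the series window", sum(!in_win)))
  }
  kept <- events[in_win, , drop = FALSE]
  kept_dates <- dates[in_win]
  idx <- floor(as.numeric(kept_dates - origin) / width)
  attr(series, "events") <- tibble(week_start = origin + idx * width,
                                   date = kept_dates,
                                   text = as.character(kept$text))
  series
}

#' Run the full analysis pipeline on a post corpus
#'
#' Convenience wrapper chaining the stages: deduplicate, exclude reposts,
#' geographical filter, thematic filter, AEFI mention counting and binning
#' (on stage-1 survivors), sentiment classification and weekly trend (on
#' stage-2 survivors), and user-activity statistics.
#'
#' @param posts Tibble of post records.
#' @param fspec A [filter_spec()] (default [default_filter_spec()]).
#' @param lexicon An [aefi_lexicon()] (default [default_aefi_lexicon()]).
#' @param config An [ensemble_config()].
#' @param scorer_a,scorer_b,categorical Ensemble scorers.
#' @param target_country ISO code for the geographical filter; `NULL` skips it.
#' @param bin_width Width in days of the mention-count bins (default 14).
#' @return List of class `aefi_pipeline`: `filter` (filter_result),
#'   `activity` (user_activity on stage-1 survivors), `mentions`
#'   (mention_table), `mention_shares`, `labels`, `sentiment` (overall
#'   proportions), `trend` (trend_series), `sizes` (per-stage record
#'   counts).
#' @export
run_pipeline <- function(posts, fspec = default_filter_spec(),
                         lexicon = default_aefi_lexicon(),
                         config = ensemble_config(),
                         scorer_a = score_compound, scorer_b = score_polarity,
                         categorical = classify_rules,
                         target_country = "GB", bin_width = 14) {
  check_posts(posts)
  sizes <- tibble(stage = "input", n = nrow(posts))
  add_size <- function(sizes, stage, n) dplyr::bind_rows(sizes, tibble(stage = stage, n = n))

  current <- deduplicate_posts(posts)
  sizes <- add_size(sizes, "deduplicated", nrow(current))
  current <- exclude_reposts(current)
  sizes <- add_size(sizes, "reposts_excluded", nrow(current))
  if (!is.null(target_country)) {
    current <- geo_filter(current, target_country)
    sizes <- add_size(sizes, paste0("geo_", target_country), nrow(current))
  }
  filt <- apply_filter(current, fspec)
  sizes <- dplyr::bind_rows(sizes, filt$report[-1, ])

  activity <- user_activity(filt$stage1)
  counts <- count_mentions(filt$stage1, lexicon)
  mentions <- bin_mentions(counts, filt$stage1,
                           bin_origin = fspec$date_start, bin_width = bin_width,
                           window_end = fspec$date_end, groups = names(lexicon))
  shares <- mention_percentages(mentions)

  labels <- classify_corpus(filt$stage2, scorer_a, scorer_b, categorical, config)
  sentiment <- overall_proportions(labels)
  trend <- weekly_trend(labels, filt$stage2, origin = fspec$date_start,
                        bin_width = 7, window_end = fspec$date_end)

  structure(
    list(filter = filt, activity = activity, mentions = mentions,
         mention_shares = shares, labels = labels, sentiment = sentiment,
         trend = trend, sizes = sizes),
    class = "aefi_pipeline")
}

#' @export
print.aefi_pipeline <- function(x, ...) {
  cat("<aefi_pipeline>\n")
  print(x$sizes)
  cat(sprintf("  sentiment: pos %d%% / neg %d%% / neu %d%%\n",
              x$sentiment$percentage[x$sentiment$label == "positive"],
              x$sentiment$percentage[x$sentiment$label == "negative"],
              x$sentiment$percentage[x$sentiment$label == "neutral"]))
  invisible(x)
}

#' Write a run report for a completed pipeline
#'
#' Emits a markdown report plus the tables behind it as CSV files (and,
#' optionally, the two standard figures as PNGs): corpus sizes before/after
#' each stage, user-activity statistics, the binned mention table with
#' per-group percentages, overall sentiment percentages, and the weekly
#' trend. Every number in the markdown is written from the same objects as
#' the CSVs, so the report is traceable to its stage outputs.
#'
#' @param pipeline An `aefi_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param plots Also write PNG figures (default `TRUE`).
#' @return Invisibly, a named character vector of paths written.
#' @export
build_report <- function(pipeline, dir, plots = TRUE) {
  if (!inherits(pipeline, "aefi_pipeline")) {
    stop_invalid("pipeline", "must be an aefi_pipeline")
  }
  for (part in c("sizes", "activity", "mentions", "mention_shares",
                 "sentiment", "trend")) {
    if (is.null(pipeline[[part]])) {
      abort(sprintf("Pipeline output missing stage `%s`", part),
            class = "aefitrends_contract_error")
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sizes = file.path(dir, "stage_sizes.csv"),
    mentions = file.path(dir, "mention_counts.csv"),
    shares = file.path(dir, "mention_shares.csv"),
    labels = file.path(dir, "labels.csv"),
    sentiment = file.path(dir, "sentiment_overall.csv"),
    trend = file.path(dir, "weekly_trend.csv"),
    activity = file.path(dir, "user_activity.csv"),
    report = file.path(dir, "report.md"))
  readr::write_csv(pipeline$sizes, paths["sizes"])
  readr::write_csv(as_tibble(pipeline$mentions), paths["mentions"])
  readr::write_csv(pipeline$mention_shares, paths["shares"])
  readr::write_csv(pipeline$labels, paths["labels"])
  readr::write_csv(pipeline$sentiment, paths["sentiment"])
  readr::write_csv(as_tibble(pipeline$trend), paths["trend"])
  readr::write_csv(glance(pipeline$activity), paths["activity"])

  act <- pipeline$activity
  sent <- pipeline$sentiment
  lines <- c(
    "# AEFI social-media surveillance run report", "",
    "## Corpus sizes by stage", "",
    sprintf("- %s: %d", pipeline$sizes$stage, pipeline$sizes$n), "",
    "## User activity (stage-1 corpus)", "",
    sprintf("- %d posts by %d users: mean %.2f (SD %.2f) posts per user",
            act$n_posts, act$n_users, act$mean_posts_per_user,
            act$sd_posts_per_user), "",
    "## Grouped AEFI mention shares", "",
    sprintf("- %s: n=%d (%d%%)", pipeline$mention_shares$group,
            pipeline$mention_shares$total, pipeline$mention_shares$percentage), "",
    "## Overall sentiment", "",
    sprintf("- %s: %d (%d%%)", sent$label, sent$count, sent$percentage), "",
    "## Files", "",
    sprintf("- %s", basename(paths[names(paths) != "report"])))
  writeLines(lines, paths["report"], useBytes = TRUE)

  if (plots) {
    paths <- c(paths, mentions_png = file.path(dir, "mention_counts.png"),
               trend_png = file.path(dir, "weekly_trend.png"))
    ggplot2::ggsave(paths[["mentions_png"]], autoplot(pipeline$mentions),
                    width = 9, height = 5, dpi = 120)
    ggplot2::ggsave(paths[["trend_png"]], autoplot(pipeline$trend),
                    width = 9, height = 5, dpi = 120)
  }
  invisible(paths)
}
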