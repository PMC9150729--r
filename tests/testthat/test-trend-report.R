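test_that("a week of all-positive posts yields proportions (1, 0, 0)", {
  posts <- make_posts(rep("x", 5),
                      timestamp = as.POSIXct("2020-12-10 12:00:00", tz = "UTC"))
  labels <- tibble::tibble(platform = posts$platform, post_id = posts$post_id,
                           label = "positive")
  tr <- weekly_trend(labels, posts)
  wk1 <- tr[tr$week_start == as.Date("2020-12-08"), ]
  expect_identical(wk1$proportion[wk1$label == "positive"], 1)
  expect_identical(wk1$proportion[wk1$label == "negative"], 0)
  expect_identical(wk1$count[wk1$label == "positive"], 5L)
  expect_false(any(wk1$empty))
})

test_that("an empty corpus flags every weekly bin empty", {
  posts <- make_posts(character(0))
  labels <- classify_corpus(posts)
  tr <- weekly_trend(labels, posts)
  expect_true(all(tr$empty))
  expect_true(all(is.na(tr$proportion)))
  # default window covers 21 weekly bins
  expect_identical(length(unique(tr$week_start)), 21L)
})

test_that("unknown post ids in the label table are a consistency error", {
  posts <- make_posts("x")
  labels <- tibble::tibble(platform = "facebook", post_id = "ghost",
                           label = "neutral")
  expect_error(weekly_trend(labels, posts), class = "aefitrends_contract_error")
})

test_that("per-week proportions recover the generator's bin-conditional mixes", {
  corpus <- generate_corpus(corpus_spec(n_users = 800, seed = 101))
  osc <- oracle_scorers()
  labels <- classify_corpus(corpus$posts, scorer_a = osc$continuous,
                            scorer_b = osc$continuous,
                            categorical = osc$categorical)
  tr <- weekly_trend(labels, corpus$posts)
  # oracle: tally ground truth per week directly
  truth <- dplyr::inner_join(corpus$truth,
                             corpus$posts[c("platform", "post_id", "timestamp")],
                             by = c("platform", "post_id"))
  truth$week_start <- as.Date("2020-12-08") +
    7 * floor(as.numeric(difftime(truth$timestamp,
                                  as.POSIXct("2020-12-08", tz = "UTC"),
                                  units = "days")) / 7)
  for (wk in unique(tr$week_start[!tr$empty])) {
    wk_truth <- truth[truth$week_start == wk, ]
    for (lbl in c("positive", "negative", "neutral")) {
      got <- tr$count[tr$week_start == wk & tr$label == lbl]
      expect_identical(got, sum(wk_truth$sentiment == lbl))
    }
  }
})

test_that("overall proportions report counts, full precision and percentages", {
  labels <- tibble::tibble(label = c("positive", "positive", "negative", "neutral"))
  out <- overall_proportions(labels)
  expect_identical(out$percentage[out$label == "positive"], 50)
  expect_identical(out$percentage[out$label == "negative"], 25)
  expect_identical(out$percentage[out$label == "neutral"], 25)

  allneu <- overall_proportions(tibble::tibble(label = rep("neutral", 4)))
  expect_identical(allneu$percentage, c(0, 0, 100))
  expect_error(overall_proportions(tibble::tibble(label = character(0))),
               class = "aefitrends_contract_error")
})

test_that("overall proportions are invariant to record order", {
  corpus <- generate_corpus(corpus_spec(n_users = 60, seed = 103))
  labels <- classify_corpus(corpus$posts)
  shuffled <- labels[withr::with_seed(1, sample(nrow(labels))), ]
  expect_identical(overall_proportions(labels), overall_proportions(shuffled))
})

test_that("weekly counts aggregate to the overall counts and to biweekly bins", {
  corpus <- generate_corpus(corpus_spec(n_users = 250, seed = 107))
  labels <- classify_corpus(corpus$posts)
  tr7 <- weekly_trend(labels, corpus$posts, bin_width = 7)
  tr14 <- weekly_trend(labels, corpus$posts, bin_width = 14)
  overall <- overall_proportions(labels)
  for (lbl in c("positive", "negative", "neutral")) {
    expect_identical(sum(tr7$count[tr7$label == lbl]),
                     overall$count[overall$label == lbl])
  }
  # pairwise re-aggregation of weekly bins equals direct 14-day aggregation
  t7 <- tibble::as_tibble(tr7)
  t7$bin14 <- as.Date("2020-12-08") +
    14 * floor(as.numeric(t7$week_start - as.Date("2020-12-08")) / 14)
  reagg <- t7 |>
    dplyr::group_by(week_start = bin14, label) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::arrange(week_start, label)
  direct <- tibble::as_tibble(tr14)[c("week_start", "label", "count")] |>
    dplyr::arrange(week_start, label)
  expect_equal(reagg, direct, ignore_attr = TRUE)
})

test_that("events attach to their containing week without changing numbers", {
  posts <- make_posts(rep("x", 3))
  labels <- tibble::tibble(platform = posts$platform, post_id = posts$post_id,
                           label = "neutral")
  tr <- weekly_trend(labels, posts)
  before <- tibble::as_tibble(tr)

  ann <- annotate_events(tr, tibble::tibble(
    date = c("2020-12-10", "2021-04-30"), text = c("rollout starts", "window end")))
  ev <- attr(ann, "events")
  expect_identical(ev$week_start[1], as.Date("2020-12-08"))
  expect_identical(ev$week_start[2], max(tr$week_start))
  expect_equal(tibble::as_tibble(ann), before, ignore_attr = TRUE)

  expect_warning(annotate_events(tr, tibble::tibble(date = "2022-01-01", text = "late")),
                 "outside")
  unchanged <- annotate_events(tr, tibble::tibble(date = character(0),
                                                  text = character(0)))
  expect_equal(tibble::as_tibble(unchanged), before, ignore_attr = TRUE)
})

test_that("the run report is complete, internally consistent and deterministic", {
  run_once <- function(dir) {
    corpus <- generate_corpus(corpus_spec(n_users = 120, seed = 109))
    pl <- run_pipeline(corpus$posts)
    build_report(pl, dir, plots = FALSE)
    pl
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  pl <- run_once(d1)
  run_once(d2)

  files <- c("report.md", "stage_sizes.csv", "mention_counts.csv",
             "mention_shares.csv", "labels.csv", "sentiment_overall.csv",
             "weekly_trend.csv", "user_activity.csv")
  expect_true(all(file.exists(file.path(d1, files))))

  # cross-file consistency: totals recomputed from stage CSVs agree
  mentions <- readr::read_csv(file.path(d1, "mention_counts.csv"),
                              show_col_types = FALSE)
  shares <- readr::read_csv(file.path(d1, "mention_shares.csv"),
                            show_col_types = FALSE)
  expect_identical(sum(mentions$count), sum(shares$total))
  trend <- readr::read_csv(file.path(d1, "weekly_trend.csv"),
                           show_col_types = FALSE)
  senti <- readr::read_csv(file.path(d1, "sentiment_overall.csv"),
                           show_col_types = FALSE)
  expect_identical(sum(trend$count), sum(senti$count))
  labels <- readr::read_csv(file.path(d1, "labels.csv"), show_col_types = FALSE)
  expect_identical(nrow(labels), as.integer(sum(senti$count)))

  # byte-identical re-run under the same seed
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  # a missing stage is a named error
  pl_broken <- pl
  pl_broken$mentions <- NULL
  expect_error(build_report(pl_broken, withr::local_tempdir()),
               "mentions", class = "aefitrends_contract_error")
})

test_that("autoplot methods return ggplot objects", {
  corpus <- generate_corpus(corpus_spec(n_users = 60, seed = 113))
  pl <- run_pipeline(corpus$posts)
  expect_s3_class(ggplot2::autoplot(pl$mentions), "ggplot")
  tr <- annotate_events(pl$trend,
                        tibble::tibble(date = "2021-01-04", text = "event"))
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
  expect_s3_class(plot_activity_density(pl$activity), "ggplot")
  expect_s3_class(tidy(pl$filter), "tbl_df")
})
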