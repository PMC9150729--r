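test_that("count_mentions counts term occurrences per group", {
  posts <- make_posts("headache and fever, then another headache")
  lex <- aefi_lexicon(list(headache = "headache", fever = "fever"))
  out <- count_mentions(posts, lex)
  expect_identical(out$count[out$group == "headache"], 2L)
  expect_identical(out$count[out$group == "fever"], 1L)

  none <- count_mentions(make_posts("nothing to see here"), lex)
  expect_true(all(none$count == 0))
})

test_that("same-term occurrences are scanned non-overlapping, distinct terms add", {
  lex <- aefi_lexicon(list(g = c("ache", "muscle ache")))
  out <- count_mentions(make_posts("muscle ache and ache"), lex)
  # "ache" twice + "muscle ache" once
  expect_identical(sum(out$count), 3L)
})

test_that("counting is case-invariant and term-order-invariant", {
  lex1 <- aefi_lexicon(list(clots = c("clots", "thrombosis", "blood clot")))
  lex2 <- aefi_lexicon(list(clots = c("blood clot", "clots", "thrombosis")))
  txt <- "CLOTS reported; thrombosis and Blood Clot fears; clots again"
  a <- count_mentions(make_posts(txt), lex1)
  b <- count_mentions(make_posts(toupper(txt)), lex2)
  expect_identical(a$count, b$count)
})

test_that("per-group totals on generated posts equal an independent scan oracle", {
  corpus <- generate_corpus(corpus_spec(n_users = 180, seed = 47))
  posts <- head(corpus$posts, 500)
  lex <- default_aefi_lexicon()
  got <- count_mentions(posts, lex) |>
    dplyr::group_by(group) |>
    dplyr::summarise(total = sum(count))
  for (g in names(lex)) {
    oracle_total <- sum(vapply(posts$text, function(txt) {
      sum(vapply(lex[[g]], function(t) oracle_term_count(txt, t), integer(1)))
    }, integer(1)))
    expect_identical(got$total[got$group == g], as.integer(oracle_total))
  }
})

test_that("bin boundaries follow 14-day arithmetic anchored at the origin", {
  posts <- make_posts(rep("headache", 3),
                      timestamp = as.POSIXct(c("2020-12-08 00:00:00",
                                               "2020-12-21 23:59:59",
                                               "2020-12-22 00:00:00"), tz = "UTC"))
  counts <- count_mentions(posts, aefi_lexicon(list(headache = "headache")))
  tab <- bin_mentions(counts, posts)
  expect_identical(tab$count[tab$bin_start == as.Date("2020-12-08")], 2L)
  expect_identical(tab$count[tab$bin_start == as.Date("2020-12-22")], 1L)
  # default window 2020-12-08..2021-04-30 covers 11 biweekly bins
  expect_identical(nrow(tab), 11L)
  expect_identical(max(tab$bin_start), as.Date("2021-04-27"))
})

test_that("an empty corpus yields a full table of zeros", {
  posts <- make_posts(character(0))
  counts <- count_mentions(posts, default_aefi_lexicon())
  tab <- bin_mentions(counts, posts, groups = names(default_aefi_lexicon()))
  expect_identical(nrow(tab), 10L * 11L)
  expect_true(all(tab$count == 0))
})

test_that("timestamps before the bin origin violate the binning contract", {
  posts <- make_posts("headache", timestamp = as.POSIXct("2020-12-01", tz = "UTC"))
  counts <- count_mentions(posts, aefi_lexicon(list(headache = "headache")))
  expect_error(bin_mentions(counts, posts), class = "aefitrends_contract_error")
})

test_that("binned totals are conserved regardless of bin width", {
  corpus <- generate_corpus(corpus_spec(n_users = 200, seed = 53))
  counts <- count_mentions(corpus$posts, default_aefi_lexicon())
  t14 <- bin_mentions(counts, corpus$posts, bin_width = 14)
  t7 <- bin_mentions(counts, corpus$posts, bin_width = 7)
  expect_identical(sum(t14$count), sum(counts$count))
  tot14 <- dplyr::count(tibble::as_tibble(t14), group, wt = count, sort = FALSE)
  tot7 <- dplyr::count(tibble::as_tibble(t7), group, wt = count, sort = FALSE)
  expect_equal(dplyr::arrange(tot14, group), dplyr::arrange(tot7, group),
               ignore_attr = TRUE)
})

test_that("mention percentages divide group totals by the grand total", {
  tab <- tibble::tibble(group = c("a", "a", "b"), count = c(20L, 30L, 50L))
  pct <- mention_percentages(tab)
  expect_identical(pct$percentage[pct$group == "a"], 50)
  expect_identical(pct$percentage[pct$group == "b"], 50)

  single <- mention_percentages(tibble::tibble(group = "only", count = 7L))
  expect_identical(single$percentage, 100)

  expect_error(mention_percentages(tibble::tibble(group = "a", count = 0L)),
               class = "aefitrends_contract_error")
})

test_that("percentages sum to 100 within rounding on pipeline output", {
  corpus <- generate_corpus(corpus_spec(n_users = 400, seed = 59))
  counts <- count_mentions(corpus$posts, default_aefi_lexicon())
  tab <- bin_mentions(counts, corpus$posts)
  pct <- mention_percentages(tab)
  expect_equal(sum(pct$percentage_raw), 100, tolerance = 1e-9)
  expect_lte(abs(sum(pct$percentage) - 100), 0.5 * nrow(pct))
})

test_that("a shared term between groups warns and counts in both", {
  expect_warning(lex <- aefi_lexicon(list(a = "flu", b = c("flu", "fever"))),
                 "flu")
  out <- count_mentions(make_posts("the flu season"), lex)
  expect_identical(out$count[out$group == "a"], 1L)
  expect_identical(out$count[out$group == "b"], 1L)
})

test_that("user_activity matches hand arithmetic and a brute-force oracle", {
  posts <- make_posts(sprintf("t%d", 1:6),
                      user_id = c("u1", "u1", "u2", "u2", "u2", "u2"))
  act <- user_activity(posts)
  expect_identical(act$n_posts, 6L)
  expect_identical(act$n_users, 2L)
  expect_identical(act$mean_posts_per_user, 3)
  expect_equal(act$sd_posts_per_user, sqrt(2))

  corpus <- generate_corpus(corpus_spec(n_users = 150, seed = 61))
  act2 <- user_activity(corpus$posts)
  tally <- as.integer(table(corpus$posts$user_id))
  expect_equal(act2$mean_posts_per_user, sum(tally) / length(tally))
  expect_equal(act2$sd_posts_per_user, sd(tally))
  expect_identical(sum(act2$per_user$n), act2$n_posts)
  g <- glance(act2)
  expect_identical(g$n_users, act2$n_users)

  expect_error(user_activity(make_posts(character(0))),
               class = "aefitrends_contract_error")
})
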