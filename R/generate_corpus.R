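#' Generate a synthetic post corpus with ground truth
#'
#' Draws a corpus of social-media post records with the statistical structure
#' the downstream analysis assumes: a log-normal posts-per-user law
#' (`max(1, round(exp(N(mu, sigma))))` per user), timestamps uniform over the
#' calendar window, theme keywords and AEFI group terms embedded at the
#' configured probabilities, and sentiment-bearing phrases consistent with
#' each post's true label. The same spec (including seed) always reproduces
#' the byte-identical corpus.
#'
#' @param spec A [corpus_spec()].
#'
#' @return A list of class `aefi_corpus` with two tibbles:
#' \describe{
#'   \item{`posts`}{one row per post: `platform`, `post_id`, `user_id`,
#'     `timestamp` (POSIXct UTC), `text`, `country`, `is_repost`.}
#'   \item{`truth`}{ground truth keyed by (`platform`, `post_id`):
#'     `sentiment` (true label), `theme_pass` (logical), and `aefi_groups`
#'     (list column of group names mentioned).}
#' }
#' @export
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_users = 20, seed = 42))
#' head(corpus$posts$text, 2)
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) {
    stop_invalid("spec", "must be a corpus_spec object")
  }
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  n_users <- spec$n_users
  user_ids <- sprintf("u%05d", seq_len(n_users))
  counts <- pmax(1, round(exp(rnorm(n_users, spec$activity_mu, spec$activity_sigma))))
  n_posts <- sum(counts)

  user_of_post <- rep(user_ids, times = counts)
  post_ids <- sprintf("p%07d", seq_len(n_posts))

  # Uniform timestamps over the inclusive calendar window.
  t0 <- as.numeric(as.POSIXct(paste(spec$date_start, "00:00:00"), tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(paste(spec$date_end, "00:00:00"), tz = "UTC")) + 86400
  ts <- as.POSIXct(t0 + runif(n_posts) * (t1 - t0 - 1), tz = "UTC",
                   origin = "1970-01-01")
  ts <- as.POSIXct(floor(as.numeric(ts)), tz = "UTC", origin = "1970-01-01")

  labels <- sample(c("positive", "negative", "neutral"), n_posts,
                   replace = TRUE, prob = spec$sentiment_mix)
  theme_pass <- runif(n_posts) < spec$theme_pass_prob
  is_repost <- runif(n_posts) < spec$repost_prob
  offtopic <- runif(n_posts) < spec$offtopic_country_prob
  country <- ifelse(offtopic,
                    sample(offtopic_country_bank, n_posts, replace = TRUE),
                    "GB")

  groups <- names(spec$aefi_group_probs)
  mention_mat <- matrix(FALSE, nrow = n_posts, ncol = length(groups),
                        dimnames = list(NULL, groups))
  for (g in groups) {
    mention_mat[, g] <- runif(n_posts) < spec$aefi_group_probs[[g]]
  }

  texts <- character(n_posts)
  for (i in seq_len(n_posts)) {
    parts <- sample(filler_bank, 1L)
    if (theme_pass[i]) {
      parts <- c(parts,
                 paste("talking about", sample(theme_stage1_bank, 1L),
                       "and the", sample(theme_stage2_bank, 1L), "programme"))
    }
    gi <- groups[mention_mat[i, ]]
    if (length(gi) > 0) {
      terms <- vapply(gi, function(g) sample(aefi_phrase_bank[[g]], 1L), character(1))
      parts <- c(parts, paste("people mention", paste(terms, collapse = " and ")))
    }
    parts <- c(parts, sample(sentiment_phrase_bank[[labels[i]]], 1L))
    txt <- paste(parts, collapse = ". ")
    if (is_repost[i] && spec$platform == "twitter") {
      txt <- paste0("RT @", user_of_post[i], " ", txt)
    }
    texts[i] <- txt
  }

  posts <- tibble(
    platform = spec$platform,
    post_id = post_ids,
    user_id = user_of_post,
    timestamp = ts,
    text = texts,
    country = country,
    is_repost = is_repost
  )
  truth <- tibble(
    platform = spec$platform,
    post_id = post_ids,
    sentiment = labels,
    theme_pass = theme_pass,
    aefi_groups = lapply(seq_len(n_posts), function(i) groups[mention_mat[i, ]])
  )
  structure(list(posts = posts, truth = truth, spec = spec),
            class = "aefi_corpus")
}

#' @export
print.aefi_corpus <- function(x, ...) {
  cat(sprintf("<aefi_corpus> %d posts by %d users (%s), %s to %s\n",
              nrow(x$posts), length(unique(x$posts$user_id)),
              x$spec$platform, x$spec$date_start, x$spec$date_end))
  invisible(x)
}

#' Write a corpus and its ground truth to disk
#'
#' Posts are written with [write_corpus()]; ground truth goes to a JSONL file
#' (one object per post, `aefi_groups` as a JSON array).
#'
#' @param corpus An `aefi_corpus` from [generate_corpus()].
#' @param posts_path,truth_path Output file paths.
#' @param format `"jsonl"` or `"csv"` for the posts file.
#' @return Invisibly, the paths written.
#' @export
write_corpus_with_truth <- function(corpus, posts_path, truth_path,
                                    format = c("jsonl", "csv")) {
  format <- match.arg(format)
  write_corpus(corpus$posts, posts_path, format = format)
  lines <- vapply(seq_len(nrow(corpus$truth)), function(i) {
    row <- corpus$truth[i, ]
    jsonlite::toJSON(list(platform = row$platform, post_id = row$post_id,
                          sentiment = row$sentiment, theme_pass = row$theme_pass,
                          aefi_groups = row$aefi_groups[[1]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, truth_path, useBytes = TRUE)
  invisible(c(posts = posts_path, truth = truth_path))
}
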