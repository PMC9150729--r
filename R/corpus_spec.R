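#' Parameterize a synthetic post corpus
#'
#' A `corpus_spec` fully determines one synthetic social-media corpus: how many
#' users post, how heavy-tailed their activity is, the calendar window, the
#' ground-truth sentiment mix, the per-group probability that a post mentions
#' an adverse effect following immunization (AEFI), and the random seed.
#' Posts-per-user follows a discretized log-normal law,
#' `max(1, round(exp(N(activity_mu, activity_sigma))))`, matching the
#' heavy-tailed activity distributions observed on both major platforms.
#'
#' @param n_users Positive integer; number of distinct posting users.
#' @param platform `"facebook"` or `"twitter"`.
#' @param date_start,date_end Inclusive UTC calendar dates of the posting
#'   window. Defaults span the first five months of the UK vaccine rollout
#'   (2020-12-08 to 2021-04-30).
#' @param activity_mu,activity_sigma Mean and standard deviation of
#'   `log(posts per user)` before discretization. Platform presets are
#'   calibrated so that mean posts-per-user is about 3.26 (facebook) or
#'   2.01 (twitter).
#' @param sentiment_mix Named or unnamed length-3 probability vector
#'   (positive, negative, neutral) summing to 1. Default `c(0.58, 0.22, 0.19)`
#'   renormalized; this is the aggregate split reported for UK vaccine
#'   discourse over the default window.
#' @param aefi_group_probs Named numeric vector mapping AEFI group name to the
#'   probability that a post mentions that group (independent per group).
#' @param theme_pass_prob Probability that a post carries both stage-1
#'   (pandemic) and stage-2 (vaccine/manufacturer) theme keywords.
#' @param repost_prob Probability a post is a repost/retweet.
#' @param offtopic_country_prob Probability a post carries a non-target (or
#'   missing) country code rather than `"GB"`.
#' @param seed Integer random seed; equal specs generate byte-identical
#'   corpora.
#'
#' @return An object of class `corpus_spec`.
#' @seealso [generate_corpus()]
#' @export
#' @examples
#' spec <- corpus_spec(n_users = 50, seed = 1)
#' corpus <- generate_corpus(spec)
#' nrow(corpus$posts)
corpus_spec <- function(n_users,
                        platform = c("facebook", "twitter"),
                        date_start = as.Date("2020-12-08"),
                        date_end = as.Date("2021-04-30"),
                        activity_mu = NULL,
                        activity_sigma = NULL,
                        sentiment_mix = c(positive = 0.58, negative = 0.22, neutral = 0.19),
                        aefi_group_probs = default_aefi_group_probs(),
                        theme_pass_prob = 0.8,
                        repost_prob = 0.1,
                        offtopic_country_prob = 0.05,
                        seed = 1L) {
  platform <- match.arg(platform)
  if (!is.numeric(n_users) || length(n_users) != 1L || is.na(n_users) ||
      n_users < 1 || n_users != floor(n_users)) {
    stop_invalid("n_users", "must be a positive integer")
  }
  date_start <- as_utc_date(date_start, "date_start")
  date_end <- as_utc_date(date_end, "date_end")
  if (date_start > date_end) stop_invalid("date_start", "must not be after date_end")

  # Presets: log-normal moment-matched to the reported mean/SD posts-per-user
  # (3.26/6.40 facebook, 2.01/1.76 twitter); discretization shifts the mean
  # slightly upward, documented in the methods vignette.
  preset <- switch(platform,
    facebook = list(mu = 0.392, sigma = 1.257),
    twitter  = list(mu = 0.414, sigma = 0.754))
  if (is.null(activity_mu)) activity_mu <- preset$mu
  if (is.null(activity_sigma)) activity_sigma <- preset$sigma
  if (!is.numeric(activity_sigma) || activity_sigma <= 0) {
    stop_invalid("activity_sigma", "must be > 0")
  }
  if (!is.numeric(activity_mu) || length(activity_mu) != 1L || is.na(activity_mu)) {
    stop_invalid("activity_mu", "must be a finite number")
  }

  if (!is.numeric(sentiment_mix) || length(sentiment_mix) != 3L ||
      any(is.na(sentiment_mix)) || any(sentiment_mix < 0) || any(sentiment_mix > 1)) {
    stop_invalid("sentiment_mix", "must be three probabilities in [0, 1]")
  }
  sentiment_mix <- sentiment_mix / sum(sentiment_mix)
  if (abs(sum(sentiment_mix) - 1) > 1e-9) {
    stop_invalid("sentiment_mix", "must sum to 1")
  }
  names(sentiment_mix) <- c("positive", "negative", "neutral")

  if (length(aefi_group_probs) > 0) {
    if (is.null(names(aefi_group_probs)) || any(names(aefi_group_probs) == "")) {
      stop_invalid("aefi_group_probs", "must be a named numeric vector")
    }
    for (g in names(aefi_group_probs)) check_prob(aefi_group_probs[[g]], "aefi_group_probs")
    unknown <- setdiff(names(aefi_group_probs), names(aefi_phrase_bank))
    if (length(unknown) > 0) {
      stop_invalid("aefi_group_probs",
                   paste0("unknown group(s): ", paste(unknown, collapse = ", ")))
    }
  }
  check_prob(theme_pass_prob, "theme_pass_prob")
  check_prob(repost_prob, "repost_prob")
  check_prob(offtopic_country_prob, "offtopic_country_prob")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("seed", "must be a single integer")
  }

  structure(
    list(n_users = as.integer(n_users), platform = platform,
         date_start = date_start, date_end = date_end,
         activity_mu = activity_mu, activity_sigma = activity_sigma,
         sentiment_mix = sentiment_mix, aefi_group_probs = aefi_group_probs,
         theme_pass_prob = theme_pass_prob, repost_prob = repost_prob,
         offtopic_country_prob = offtopic_country_prob, seed = as.integer(seed)),
    class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat(sprintf("<corpus_spec> %s, %d users, %s to %s, seed %d\n",
              x$platform, x$n_users, x$date_start, x$date_end, x$seed))
  cat(sprintf("  posts/user ~ round(exp(N(%.3f, %.3f))), clamped >= 1\n",
              x$activity_mu, x$activity_sigma))
  cat(sprintf("  sentiment mix: pos %.2f / neg %.2f / neu %.2f\n",
              x$sentiment_mix[["positive"]], x$sentiment_mix[["negative"]],
              x$sentiment_mix[["neutral"]]))
  invisible(x)
}

#' Default per-group AEFI mention probabilities
#'
#' Probabilities proportional to the reported shares of the four headline
#' mention groups (appetite 14%, allergy 9%, injection site 10%, clots 8%),
#' scaled so a typical post mentions at most a few groups, plus small rates
#' for the remaining tracked groups.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_aefi_group_probs <- function() {
  c(appetite = 0.14, allergy = 0.09, injection_site = 0.10, clots = 0.08,
    headache = 0.02, fever = 0.02, diarrhea = 0.03,
    bell_palsy = 0.02, guillain_barre = 0.02, generalized = 0.05)
}
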