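#' Configure the hybrid ensemble classifier
#'
#' The ensemble averages two continuous lexicon scorers with fixed convex
#' weights, then combines the averaged score with a categorical model by an
#' if-else rule: a weighted score above `positive_threshold` is final
#' (positive); otherwise the categorical model's label is taken wholesale.
#' The default weights are 0.45 for the scorer in the valence-aware
#' (compound) role and 0.55 for the scorer in the pattern-polarity role,
#' reflecting the latter's marginally better positive-class accuracy; the
#' default positivity cutoff 0.05 is the conventional compound-score
#' boundary.
#'
#' @param weight_a Weight of the first continuous scorer (default 0.45).
#' @param weight_b Weight of the second continuous scorer (default 0.55);
#'   must satisfy `weight_a + weight_b == 1` with both non-negative.
#' @param positive_threshold Weighted-score cutoff strictly above which the
#'   label is positive (default 0.05). Scores exactly at the threshold go to
#'   the else branch.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(weight_a = 0.45, weight_b = 0.55,
                            positive_threshold = 0.05) {
  if (!is.numeric(weight_a) || !is.numeric(weight_b) ||
      weight_a < 0 || weight_b < 0 ||
      abs(weight_a + weight_b - 1) > 1e-9) {
    stop_invalid("weight_a/weight_b",
                 "must be non-negative and sum to 1")
  }
  if (!is.numeric(positive_threshold) || length(positive_threshold) != 1L ||
      is.na(positive_threshold)) {
    stop_invalid("positive_threshold", "must be a single number")
  }
  structure(list(weight_a = weight_a, weight_b = weight_b,
                 positive_threshold = positive_threshold),
            class = "ensemble_config")
}

#' Weighted average of two lexicon polarity scores
#'
#' Returns `weight_a * scorer_a(text) + weight_b * scorer_b(text)`. Because
#' the weights are convex and each scorer maps into `[-1, 1]`, the result is
#' guaranteed to lie in `[-1, 1]` (and between the two scores).
#'
#' @param text Character vector.
#' @param scorer_a,scorer_b Continuous scorers (`text -> numeric in [-1,1]`),
#'   e.g. [score_compound()] and [score_polarity()].
#' @param config An [ensemble_config()].
#' @return Numeric vector of weighted polarities.
#' @export
weighted_lexicon_score <- function(text, scorer_a = score_compound,
                                   scorer_b = score_polarity,
                                   config = ensemble_config()) {
  if (!inherits(config, "ensemble_config")) {
    stop_invalid("config", "must be an ensemble_config")
  }
  a <- scorer_a(text)
  b <- scorer_b(text)
  if (any(is.na(a)) || any(is.na(b)) ||
      any(abs(a) > 1 + 1e-9) || any(abs(b) > 1 + 1e-9)) {
    abort("Continuous scorers must return values in [-1, 1]",
          class = "aefitrends_scorer_error")
  }
  config$weight_a * a + config$weight_b * b
}

#' Classify text with the hybrid ensemble rule
#'
#' Implements the if-else combination: IF the weighted lexicon score exceeds
#' `positive_threshold` THEN the final label is positive; ELSE the
#' categorical model's label is the final label. The categorical model is
#' invoked lazily, only for texts that reach the else branch; if it is
#' `NULL` and any text reaches that branch, an explicit model-unavailable
#' error is raised (never a silent fallback).
#'
#' @param text Character vector.
#' @param scorer_a,scorer_b Continuous scorers.
#' @param categorical Categorical scorer (`text -> label`), e.g.
#'   [classify_rules()] or an adapter around a transformer classifier.
#' @param config An [ensemble_config()].
#' @return Tibble: `text_id` (index), `weighted_score`, `branch`
#'   (`"lexicon_positive"` or `"categorical"`), `label`.
#' @export
#' @examples
#' ensemble_classify("what a wonderful day")$label
ensemble_classify <- function(text, scorer_a = score_compound,
                              scorer_b = score_polarity,
                              categorical = classify_rules,
                              config = ensemble_config()) {
  ws <- weighted_lexicon_score(text, scorer_a, scorer_b, config)
  is_pos <- ws > config$positive_threshold
  label <- character(length(text))
  label[is_pos] <- "positive"
  if (any(!is_pos)) {
    if (is.null(categorical)) {
      abort("Categorical model unavailable but required for the else branch",
            class = "aefitrends_model_unavailable_error")
    }
    lab <- categorical(text[!is_pos])
    bad <- !lab %in% c("positive", "negative", "neutral")
    if (any(bad)) {
      abort(sprintf("Categorical scorer returned invalid label(s): %s",
                    paste(unique(lab[bad]), collapse = ", ")),
            class = "aefitrends_scorer_error")
    }
    label[!is_pos] <- lab
  }
  tibble(text_id = seq_along(text), weighted_score = ws,
         branch = ifelse(is_pos, "lexicon_positive", "categorical"),
         label = label)
}

#' Classify every post in a corpus
#'
#' Applies [ensemble_classify()] to each post's text. Per-record scorer
#' errors are collected and reported rather than aborting the run (set
#' `fail_fast = TRUE` to abort on the first error). Batch evaluation yields
#' exactly the same per-record labels as one-at-a-time evaluation because
#' scorers are pure.
#'
#' @param posts Tibble of post records.
#' @param scorer_a,scorer_b,categorical,config As in [ensemble_classify()].
#' @param fail_fast Abort on the first per-record error (default `FALSE`).
#' @return Tibble: `platform`, `post_id`, `label`, `weighted_score`,
#'   `branch`; failed records (if any) appear with `NA` label and are listed
#'   in attribute `errors`.
#' @export
classify_corpus <- function(posts, scorer_a = score_compound,
                            scorer_b = score_polarity,
                            categorical = classify_rules,
                            config = ensemble_config(),
                            fail_fast = FALSE) {
  check_posts(posts)
  if (nrow(posts) == 0) {
    out <- tibble(platform = character(), post_id = character(),
                  label = character(), weighted_score = numeric(),
                  branch = character())
    attr(out, "errors") <- tibble(platform = character(), post_id = character(),
                                  error = character())
    return(out)
  }
  res <- tryCatch(
    ensemble_classify(posts$text, scorer_a, scorer_b, categorical, config),
    error = function(e) e)
  if (inherits(res, "error")) {
    # Vectorized pass failed: fall back to per-record evaluation so one bad
    # record does not void the run.
    if (fail_fast) stop(res)
    rows <- lapply(seq_len(nrow(posts)), function(i) {
      tryCatch(
        ensemble_classify(posts$text[i], scorer_a, scorer_b, categorical, config),
        error = function(e) tibble(text_id = i, weighted_score = NA_real_,
                                   branch = NA_character_, label = NA_character_,
                                   err = conditionMessage(e)))
    })
    res <- dplyr::bind_rows(rows)
    res$text_id <- seq_len(nrow(posts))
  }
  out <- tibble(platform = posts$platform, post_id = posts$post_id,
                label = res$label, weighted_score = res$weighted_score,
                branch = res$branch)
  errs <- if ("err" %in% names(res)) {
    tibble(platform = posts$platform, post_id = posts$post_id,
           error = res$err)[!is.na(res$err), ]
  } else {
    tibble(platform = character(), post_id = character(), error = character())
  }
  if (nrow(errs) > 0 && fail_fast) {
    abort(sprintf("Scorer failed on %d record(s); first: %s (post %s)",
                  nrow(errs), errs$error[1], errs$post_id[1]),
          class = "aefitrends_scorer_error")
  }
  attr(out, "errors") <- errs
  out
}

#' Per-class accuracy of predicted labels against ground truth
#'
#' Evaluation harness for re-fitting ensemble weights on labeled data:
#' joins predictions to ground-truth labels and reports overall and
#' per-class accuracy.
#'
#' @param labels Prediction tibble from [classify_corpus()].
#' @param truth Ground-truth tibble with `platform`, `post_id`, `sentiment`
#'   (as produced by [generate_corpus()]).
#' @return Tibble with rows `overall` plus one per class: `class`, `n`,
#'   `accuracy`.
#' @export
score_against_truth <- function(labels, truth) {
  joined <- dplyr::inner_join(labels, truth, by = c("platform", "post_id"))
  if (nrow(joined) == 0) {
    abort("No predictions matched ground truth by (platform, post_id)",
          class = "aefitrends_contract_error")
  }
  per_class <- joined |>
    dplyr::group_by(class = .data$sentiment) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = mean(.data$label == .data$sentiment),
                     .groups = "drop")
  overall <- tibble(class = "overall", n = nrow(joined),
                    accuracy = mean(joined$label == joined$sentiment))
  dplyr::bind_rows(overall, per_class)
}
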