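# Built-in lexicon polarity scorers and deterministic test doubles.
#
# A continuous scorer maps a character vector of texts to polarity scores in
# [-1, 1]; a categorical scorer maps texts to labels in
# {positive, negative, neutral}. Scorers are pure: the same text always
# yields the same output. Any user function with the same signature can be
# plugged into the ensemble, e.g. an adapter around a transformer sequence
# classifier for the categorical slot.

# Small valence dictionary: word -> polarity in [-1, 1]. Deliberately free of
# symptom vocabulary so adverse-effect terms do not masquerade as sentiment.
valence_dictionary <- c(
  grateful = 0.8, great = 0.8, relief = 0.6, brilliant = 0.9, happy = 0.8,
  thankful = 0.7, wonderful = 0.9, excellent = 0.9, love = 0.8, good = 0.6,
  hope = 0.5, delighted = 0.9, smooth = 0.4, superb = 0.9, glad = 0.7,
  safe = 0.5, amazing = 0.9, best = 0.8, painless = 0.5, easy = 0.4,
  awful = -0.8, terrible = -0.8, scared = -0.7, worried = -0.6, angry = -0.7,
  horrible = -0.8, furious = -0.9, dreadful = -0.8, shambles = -0.7,
  miserable = -0.8, grim = -0.6, hate = -0.8, frustrating = -0.6,
  bad = -0.6, worst = -0.9, anxious = -0.6, afraid = -0.7, useless = -0.7,
  disgrace = -0.8, alarming = -0.6
)

booster_words <- c(really = 0.25, very = 0.25, so = 0.2, utterly = 0.3,
                   totally = 0.25, extremely = 0.3)
negation_words <- c("not", "no", "never", "isnt", "wasnt", "dont", "didnt",
                    "cant", "wont")

tokenize_words <- function(text) {
  stringr::str_split(stringr::str_to_lower(text), "[^[:alnum:]']+")
}

#' Built-in continuous sentiment scorers
#'
#' Two lexicon polarity scorers over a shared valence dictionary, returning
#' scores in `[-1, 1]`:
#'
#' * `score_compound()` follows the compound-score style of
#'   valence-aware lexicon scorers: token valences are adjusted by booster
#'   words and flipped by a preceding negation, summed, and normalized by
#'   `s / sqrt(s^2 + alpha)` with `alpha = 15`.
#' * `score_polarity()` follows the pattern-lexicon style: the mean valence
#'   of matched dictionary words (0 when none match), with negation flipping.
#'
#' The two scorers weight evidence differently, which is exactly what the
#' weighted-average ensemble exploits.
#'
#' @param text Character vector.
#' @return Numeric vector of polarities in `[-1, 1]`.
#' @export
score_compound <- function(text) {
  toks_list <- tokenize_words(text)
  vapply(toks_list, function(toks) {
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) return(0)
    s <- 0
    for (i in seq_along(toks)) {
      v <- valence_dictionary[toks[i]]
      if (is.na(v)) next
      if (i > 1 && !is.na(b <- booster_words[toks[i - 1L]])) {
        v <- v + sign(v) * b
      }
      if (i > 1 && toks[i - 1L] %in% negation_words) v <- -0.74 * v
      if (i > 2 && toks[i - 2L] %in% negation_words) v <- -0.74 * v
      s <- s + v
    }
    s / sqrt(s^2 + 15)
  }, numeric(1))
}

#' @rdname score_compound
#' @export
score_polarity <- function(text) {
  toks_list <- tokenize_words(text)
  vapply(toks_list, function(toks) {
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) return(0)
    vals <- numeric(0)
    for (i in seq_along(toks)) {
      v <- valence_dictionary[toks[i]]
      if (is.na(v)) next
      if (i > 1 && toks[i - 1L] %in% negation_words) v <- -0.5 * v
      vals <- c(vals, v)
    }
    if (length(vals) == 0) 0 else max(-1, min(1, mean(vals)))
  }, numeric(1))
}

#' Built-in categorical sentiment classifier
#'
#' A deterministic rule-based 3-class classifier standing in the categorical
#' (transformer-model) slot of the ensemble: it counts positive and negative
#' dictionary words (with negation flipping the vote) and returns the
#' majority polarity, or `"neutral"` on a tie or when no valenced word is
#' present. Any user-supplied function `text -> label` — for instance an
#' adapter around a fine-tuned sequence classifier — can replace it.
#'
#' @param text Character vector.
#' @return Character vector of labels in `{"positive", "negative", "neutral"}`.
#' @export
classify_rules <- function(text) {
  toks_list <- tokenize_words(text)
  vapply(toks_list, function(toks) {
    toks <- toks[nzchar(toks)]
    pos <- 0L; neg <- 0L
    for (i in seq_along(toks)) {
      v <- valence_dictionary[toks[i]]
      if (is.na(v)) next
      if (i > 1 && toks[i - 1L] %in% negation_words) v <- -v
      if (v > 0) pos <- pos + 1L else neg <- neg + 1L
    }
    if (pos > neg) "positive" else if (neg > pos) "negative" else "neutral"
  }, character(1))
}

#' Deterministic keyword-oracle scorers for testing
#'
#' Test doubles keyed to the synthetic generator's sentiment phrase banks:
#' the continuous oracle returns `+1` when any positive marker word is
#' present, `-1` for any negative marker, else `0`; the categorical oracle
#' returns the corresponding label. On generated text these recover the
#' ground-truth label exactly, which makes end-to-end parameter-recovery
#' tests meaningful.
#'
#' @return A list with elements `continuous` (text -> score) and
#'   `categorical` (text -> label).
#' @export
oracle_scorers <- function() {
  pos_stage <- filter_stage("pos", sentiment_marker_words$positive)
  neg_stage <- filter_stage("neg", sentiment_marker_words$negative)
  continuous <- function(text) {
    ifelse(match_any(text, pos_stage), 1,
           ifelse(match_any(text, neg_stage), -1, 0))
  }
  categorical <- function(text) {
    ifelse(match_any(text, pos_stage), "positive",
           ifelse(match_any(text, neg_stage), "negative", "neutral"))
  }
  list(continuous = continuous, categorical = categorical)
}
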