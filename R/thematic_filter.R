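#' Define one stage of the thematic keyword filter
#'
#' A stage retains a post when at least one of its terms matches the post
#' text. Matching is case-insensitive (Unicode case folding). In
#' `word_boundary` mode a term matches only when delimited by
#' non-alphanumeric characters or string edges; multi-word phrases match as
#' contiguous token sequences separated by whitespace. `substring` mode
#' matches anywhere, which is useful for hashtag-dense text such as
#' `#covidvaccine`.
#'
#' @param name Stage name.
#' @param terms Non-empty character vector of keywords and phrases.
#' @param match_mode `"word_boundary"` (default) or `"substring"`.
#' @return Object of class `filter_stage`.
#' @export
filter_stage <- function(name, terms, match_mode = c("word_boundary", "substring")) {
  match_mode <- match.arg(match_mode)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("name", "must be a non-empty string")
  }
  if (!is.character(terms) || length(terms) == 0 || any(!nzchar(terms)) ||
      any(is.na(terms))) {
    stop_invalid("terms", "must be a non-empty character vector with no empty terms")
  }
  structure(list(name = name, terms = terms, match_mode = match_mode),
            class = "filter_stage")
}

#' Define the full multi-stage thematic filter
#'
#' An ordered sequence of [filter_stage()]s plus an inclusive UTC date
#' window. The canonical configuration is a 2-step filter: stage 1 retains
#' pandemic-related posts, stage 2 narrows to vaccine- and
#' manufacturer-related posts.
#'
#' @param stages List of [filter_stage()] objects (at least one).
#' @param date_start,date_end Inclusive UTC calendar dates.
#' @return Object of class `filter_spec`.
#' @seealso [default_filter_spec()], [apply_filter()]
#' @export
filter_spec <- function(stages, date_start = as.Date("2020-12-08"),
                        date_end = as.Date("2021-04-30")) {
  if (inherits(stages, "filter_stage")) stages <- list(stages)
  if (!is.list(stages) || length(stages) == 0 ||
      !all(vapply(stages, inherits, logical(1), "filter_stage"))) {
    stop_invalid("stages", "must be a non-empty list of filter_stage objects")
  }
  date_start <- as_utc_date(date_start, "date_start")
  date_end <- as_utc_date(date_end, "date_end")
  if (date_start > date_end) stop_invalid("date_start", "must not be after date_end")
  structure(list(stages = stages, date_start = date_start, date_end = date_end),
            class = "filter_spec")
}

#' Default two-step thematic filter
#'
#' Stage 1 is seeded with pandemic keywords (covid, coronavirus, sars-cov-2
#' variants); stage 2 with vaccine terms and the manufacturers most discussed
#' during the UK rollout. These defaults are a reasonable starting lexicon,
#' not an authoritative keyword list; replace them via [filter_spec()] or a
#' config file ([read_filter_config()]).
#'
#' @param date_start,date_end Inclusive window, defaulting to the UK rollout
#'   study window.
#' @return A `filter_spec` with two stages.
#' @export
default_filter_spec <- function(date_start = as.Date("2020-12-08"),
                                date_end = as.Date("2021-04-30")) {
  filter_spec(
    list(
      filter_stage("covid", c("covid", "covid-19", "covid19", "coronavirus",
                              "sars-cov-2", "sars cov 2")),
      filter_stage("vaccine", c("vaccine", "vaccines", "vaccination",
                                "vaccinated", "jab", "jabs", "booster",
                                "astrazeneca", "oxford-astrazeneca",
                                "pfizer", "moderna"))
    ),
    date_start = date_start, date_end = date_end
  )
}

#' Read a filter specification from YAML or JSON
#'
#' Expected structure: `stages`, a list of `{name, terms, match_mode}`
#' entries in order, plus `date_start` and `date_end` as ISO-8601 dates.
#'
#' @param path Config file path; format inferred from the extension
#'   (`.yml`/`.yaml` vs `.json`).
#' @return A `filter_spec`.
#' @export
read_filter_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$stages)) {
    abort("Filter config must contain a `stages` list",
          class = "aefitrends_schema_error")
  }
  stages <- lapply(cfg$stages, function(s) {
    filter_stage(s$name, unlist(s$terms),
                 match_mode = s$match_mode %||% "word_boundary")
  })
  filter_spec(stages,
              date_start = cfg$date_start %||% "2020-12-08",
              date_end = cfg$date_end %||% "2021-04-30")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build one regex alternation for a set of terms under the stage's mode.
# Word-boundary mode: each term delimited by non-alphanumerics/string edges;
# internal whitespace in phrases matches any whitespace run.
stage_pattern <- function(terms, match_mode) {
  esc <- vapply(terms, function(t) {
    t <- stringr::str_squish(t)
    toks <- strsplit(t, "\\s+")[[1]]
    paste(vapply(toks, escape_regex, character(1)), collapse = "\\s+")
  }, character(1))
  alt <- paste0("(?:", paste(esc, collapse = "|"), ")")
  if (match_mode == "word_boundary") {
    alt <- paste0("(?<![[:alnum:]])", alt, "(?![[:alnum:]])")
  }
  stringr::regex(alt, ignore_case = TRUE)
}

escape_regex <- function(x) gsub("([\\^$.|?*+()\\[\\]{}\\\\-])", "\\\\\\1", x, perl = TRUE)

#' Does any stage term match a text?
#'
#' @param text Character vector of texts.
#' @param stage A [filter_stage()].
#' @return Logical vector, `TRUE` where at least one term matches.
#' @export
#' @examples
#' match_any("Got my Covid result!", filter_stage("covid", "covid"))
match_any <- function(text, stage) {
  if (!inherits(stage, "filter_stage")) {
    stop_invalid("stage", "must be a filter_stage")
  }
  stringr::str_detect(text, stage_pattern(stage$terms, stage$match_mode))
}

#' Apply the multi-stage thematic filter
#'
#' Restricts records to the inclusive date window, then applies the stages in
#' order, each to the survivors of the previous one. For the canonical
#' 2-step configuration, the stage-1 survivors are the corpus used for AEFI
#' mention counting and the stage-2 survivors the corpus used for sentiment
#' analysis.
#'
#' @param posts Tibble of post records.
#' @param spec A [filter_spec()].
#' @return A list of class `filter_result`:
#' \describe{
#'   \item{`stage1`, `stage2`}{survivor tibbles of the first and last stage
#'     (identical when the spec has a single stage).}
#'   \item{`stages`}{named list of survivor tibbles for every stage.}
#'   \item{`report`}{tibble of survivor counts: input, in-window, then one
#'     row per stage.}
#' }
#' @export
apply_filter <- function(posts, spec) {
  check_posts(posts)
  if (!inherits(spec, "filter_spec")) stop_invalid("spec", "must be a filter_spec")

  day <- as.Date(posts$timestamp, tz = "UTC")
  in_window <- posts[!is.na(day) & day >= spec$date_start & day <= spec$date_end, ,
                     drop = FALSE]

  report <- tibble(stage = c("input", "date_window"),
                   n = c(nrow(posts), nrow(in_window)))
  survivors <- list()
  current <- in_window
  for (st in spec$stages) {
    current <- current[match_any(current$text, st), , drop = FALSE]
    survivors[[st$name]] <- current
    report <- dplyr::bind_rows(report, tibble(stage = st$name, n = nrow(current)))
  }
  structure(
    list(stage1 = survivors[[1]],
         stage2 = survivors[[length(survivors)]],
         stages = survivors,
         report = report),
    class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>\n")
  print(x$report)
  invisible(x)
}

#' @rdname apply_filter
#' @param x A `filter_result`.
#' @param ... Unused.
#' @method tidy filter_result
#' @export
tidy.filter_result <- function(x, ...) x$report
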