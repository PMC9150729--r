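# ggplot2 methods for the result objects.

#' Stacked-bar plot of binned AEFI mention counts
#'
#' One bar per time bin, stacked by AEFI group.
#'
#' @param object A `mention_table` from [bin_mentions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mention_table
#' @export
autoplot.mention_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin_start, y = .data$count,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Bin start", y = "Mentions", fill = "AEFI group",
                  title = "Grouped AEFI mentions per time bin") +
    ggplot2::theme_minimal()
}

#' Weekly sentiment trend plot
#'
#' One line per sentiment label showing the per-week proportion.
#'
#' @param object A `trend_series` from [weekly_trend()]. Event annotations
#'   attached by [annotate_events()] are drawn as vertical dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_series
#' @export
autoplot.trend_series <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df[!df$empty, ],
                       ggplot2::aes(x = .data$week_start, y = .data$proportion,
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Week", y = "Share of posts", colour = "Sentiment",
                  title = "Average weekly public sentiment") +
    ggplot2::theme_minimal()
  ev <- attr(object, "events")
  if (!is.null(ev) && nrow(ev) > 0) {
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$date),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Density plot of log posts-per-user
#'
#' Per-user activity on social platforms is heavy-tailed and roughly
#' log-normal, so the density of `log(posts per user)` should look
#' approximately normal.
#'
#' @param activity A `user_activity` from [user_activity()].
#' @return A ggplot object.
#' @export
plot_activity_density <- function(activity) {
  if (!inherits(activity, "user_activity")) {
    stop_invalid("activity", "must be a user_activity")
  }
  ggplot2::ggplot(activity$per_user, ggplot2::aes(x = log(.data$n))) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "log(posts per user)", y = "Density",
                  title = "Distribution of user posting activity") +
    ggplot2::theme_minimal()
}
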