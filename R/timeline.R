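#' Schedule timelines
#'
#' A timeline records, for every executed array-job unit, which worker ran
#' it and when (`submission`, `task_index`, `worker_id`, `t_start`,
#' `t_end`). Both the live engine ([engine_timeline()]) and the simulator
#' ([simulate_schedule()]) produce one, so their schedules can be compared
#' directly. It is a tibble subclass; all dplyr verbs apply.
#'
#' @name vge_timeline
NULL

new_timeline <- function(df, n_workers = NA_integer_) {
  df <- as_tibble(df)
  stopifnot(all(c("submission", "task_index", "worker_id",
                  "t_start", "t_end") %in% names(df)))
  structure(df, class = c("vge_timeline", class(df)),
            n_workers = as.integer(n_workers))
}

#' @rdname vge_timeline
#' @param tl A timeline.
#' @return `timeline_makespan()`: elapsed seconds from the first start to
#'   the last end (0 for an empty timeline).
#' @export
timeline_makespan <- function(tl) {
  if (nrow(tl) == 0) return(0)
  max(tl$t_end) - min(tl$t_start)
}

#' @rdname vge_timeline
#' @return `worker_counts()`: tibble of units completed per worker (workers
#'   that ran nothing get an explicit 0 when the worker count is known).
#' @export
worker_counts <- function(tl) {
  W <- attr(tl, "n_workers")
  counts <- dplyr::count(as_tibble(tl), .data$worker_id, name = "n_units")
  if (!is.na(W)) {
    all_w <- tibble(worker_id = seq_len(W))
    counts <- left_join(all_w, counts, by = "worker_id")
    counts$n_units[is.na(counts$n_units)] <- 0L
  }
  counts
}

#' Write / read a timeline as TSV
#'
#' One row per unit (`submission`, `task_index`, `worker_id`, `t_start`,
#' `t_end`), sorted by start time — the flat file from which start-time
#' staircase and worker-filling plots are drawn.
#'
#' @param tl A [vge_timeline].
#' @param path Output file.
#' @return `timeline_export()`: `path`, invisibly. `timeline_read()`: the
#'   timeline.
#' @export
timeline_export <- function(tl, path) {
  df <- as_tibble(tl)[c("submission", "task_index", "worker_id",
                        "t_start", "t_end")]
  df <- df[order(df$t_start, df$submission, df$task_index), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname timeline_export
#' @param n_workers Worker count to attach (defaults to the number of
#'   distinct workers in the file).
#' @export
timeline_read <- function(path, n_workers = NA_integer_) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (is.na(n_workers) && nrow(df) > 0)
    n_workers <- length(unique(df$worker_id))
  new_timeline(df, n_workers = n_workers)
}

#' @export
tidy.vge_timeline <- function(x, ...) {
  out <- as_tibble(x)
  out$duration <- out$t_end - out$t_start
  out
}

#' @export
glance.vge_timeline <- function(x, ...) {
  wc <- worker_counts(x)$n_units
  busy <- sum(x$t_end - x$t_start)
  mk <- timeline_makespan(x)
  W <- attr(x, "n_workers")
  tibble(
    n_units = nrow(x),
    n_workers = if (is.na(W)) length(unique(x$worker_id)) else W,
    makespan = mk,
    min_per_worker = if (length(wc)) min(wc) else 0L,
    max_per_worker = if (length(wc)) max(wc) else 0L,
    utilization = if (mk > 0 && !is.na(W)) busy / (mk * W) else NA_real_
  )
}

#' Plot a timeline
#'
#' `autoplot()` draws the start time of each unit against its start rank —
#' the staircase whose step width is the worker count and step height the
#' unit duration; the zero-overhead ideal is overlaid when `ideal` is
#' given. `plot_worker_filling()` draws one horizontal bar per executed
#' unit, stacked by worker and coloured by submission, showing how work
#' fills the worker pool over time (white gaps are idle workers).
#'
#' @param object,tl A [vge_timeline].
#' @param ideal Optional zero-overhead makespan (seconds) to overlay as a
#'   reference line from origin to `(n_units, ideal)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vge_timeline <- function(object, ideal = NULL, ...) {
  df <- as_tibble(object)
  t0 <- if (nrow(df) > 0) min(df$t_start) else 0
  df <- df[order(df$t_start), ]
  df$rank <- seq_len(nrow(df))
  df$rel_start <- df$t_start - t0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rel_start)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "job (ordered by start)", y = "start time [s]") +
    ggplot2::theme_minimal()
  if (!is.null(ideal) && nrow(df) > 0) {
    p <- p + ggplot2::annotate("segment", x = 1, xend = nrow(df), y = 0,
                               yend = ideal, colour = "red", linetype = 2)
  }
  p
}

#' @rdname autoplot.vge_timeline
#' @export
plot_worker_filling <- function(tl) {
  df <- as_tibble(tl)
  t0 <- if (nrow(df) > 0) min(df$t_start) else 0
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$t_start - t0, xend = .data$t_end - t0,
      y = .data$worker_id, yend = .data$worker_id,
      colour = factor(.data$submission)), linewidth = 1.5) +
    ggplot2::labs(x = "time [s]", y = "worker", colour = "submission") +
    ggplot2::theme_minimal()
}
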