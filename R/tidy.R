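# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an alignment fit into its per-step loss trajectory
#'
#' @param x an `alignment_fit` from [pretrain()]
#' @param ... unused
#' @return tibble with one row per optimization step
#' @export
tidy.alignment_fit <- function(x, ...) x$trajectory

#' One-row summary of an alignment fit
#'
#' @param x an `alignment_fit`
#' @param ... unused
#' @return tibble with step count, initial/final/best loss and the
#'   temperature used
#' @export
glance.alignment_fit <- function(x, ...) {
  tr <- x$trajectory
  tibble::tibble(
    steps = nrow(tr),
    initial_loss = tr$total[1],
    final_loss = tr$total[nrow(tr)],
    best_loss = min(tr$total),
    temperature = x$config$temperature,
    batch_struct = x$config$batch_struct,
    batch_text = x$config$batch_text
  )
}

#' Plot the pretraining loss trajectory
#'
#' @param object an `alignment_fit`
#' @param ... unused
#' @return a ggplot of the per-term and total losses over steps
#' @export
autoplot.alignment_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectory,
                              cols = c("loss_seq_struct", "loss_seq_text", "total"),
                              names_to = "term", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "step", y = "InfoNCE loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy per-seed metrics of a task result
#'
#' @param x a `task_result` from [run_task()]
#' @param ... unused
#' @return tibble (seed, metric, value)
#' @export
tidy.task_result <- function(x, ...) x$per_seed

#' Metric means and SDs of a task result
#'
#' @param x a `task_result`
#' @param ... unused
#' @return one row per metric with mean and SD over seeds
#' @export
glance.task_result <- function(x, ...) {
  dplyr::mutate(x$summary, task = x$task, n_seeds = length(x$seeds))
}

#' Plot per-seed task metrics
#'
#' @param object a `task_result`
#' @param ... unused
#' @return a ggplot with one point per seed and the mean per metric
#' @export
autoplot.task_result <- function(object, ...) {
  ggplot2::ggplot(object$per_seed,
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, position = ggplot2::position_jitter(width = 0.05)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "steelblue") +
    ggplot2::labs(x = NULL, y = "metric value", title = object$task) +
    ggplot2::theme_minimal()
}

#' Tidy retrieval ranks
#'
#' @param x a `retrieval_result` from [retrieve()]
#' @param ... unused
#' @return the per-query rank tibble
#' @export
tidy.retrieval_result <- function(x, ...) x$ranks

#' One-row retrieval summary
#'
#' @param x a `retrieval_result`
#' @param ... unused
#' @return tibble with recall at each k and class-level top-1
#' @export
glance.retrieval_result <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$recall_at_k))
  out$class_top1 <- x$class_top1
  out$n <- x$n
  out
}

#' Plot the distribution of retrieval ranks
#'
#' @param object a `retrieval_result`
#' @param ... unused
#' @return a ggplot histogram of the rank of the true counterpart
#' @export
autoplot.retrieval_result <- function(object, ...) {
  ggplot2::ggplot(object$ranks, ggplot2::aes(x = .data$rank_of_true)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "rank of true counterpart", y = "queries") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
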