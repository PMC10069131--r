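# Scoring a call set against the planted truth: greedy 1-to-1 matching of
# truth events to the nearest call within a tolerance (default the 30 bp
# anchor window), then TP/FP/FN counts and the derived sensitivity and
# false-positive fraction.

#' Match calls against a truth ledger
#'
#' Greedy nearest-first 1-to-1 matching: each truth event is paired with the
#' closest unmatched call on the same contig within `tolerance` bp (ties
#' broken towards the smaller coordinate, so matching is deterministic and
#' independent of input order). With `strict = TRUE` (default) a pair must
#' also agree on the TE family to count as a true positive; position-only
#' pairs are tallied as `mislabeled` and count as TP only when
#' `strict = FALSE`. Unmatched calls are false positives, unmatched truth
#' events false negatives.
#'
#' @param calls Calls tibble (`contig`, `start`, `family`).
#' @param truth Truth tibble (`contig`, `position`, `family`).
#' @param tolerance Maximum distance (bp) between call start and truth
#'   position.
#' @param strict Require family agreement for a TP.
#' @return List with `tp`, `fp`, `fn`, `mislabeled` counts and `events`, a
#'   per-truth-event table with the matched call (if any).
#' @export
match_calls <- function(calls, truth, tolerance = 30, strict = TRUE) {
  calls <- as_tibble(calls)
  truth <- as_tibble(truth)
  if (nrow(calls) && nrow(truth) &&
      !length(intersect(unique(calls$contig), unique(truth$contig)))) {
    abort("calls and truth share no contig: mixed coordinate systems?")
  }
  pairs <- tibble(truth_idx = integer(), call_idx = integer(),
                  dist = double(), family_ok = logical())
  if (nrow(calls) && nrow(truth)) {
    cand <- tidyr::expand_grid(truth_idx = seq_len(nrow(truth)),
                               call_idx = seq_len(nrow(calls))) |>
      filter(truth$contig[.data$truth_idx] == calls$contig[.data$call_idx]) |>
      mutate(dist = abs(truth$position[.data$truth_idx] -
                          calls$start[.data$call_idx])) |>
      filter(.data$dist <= tolerance) |>
      mutate(family_ok = truth$family[.data$truth_idx] ==
               calls$family[.data$call_idx]) |>
      arrange(dplyr::desc(.data$family_ok), .data$dist,
              truth$position[.data$truth_idx],
              calls$start[.data$call_idx])
    t_used <- logical(nrow(truth)); c_used <- logical(nrow(calls))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ti <- cand$truth_idx[i]; ci <- cand$call_idx[i]
      if (!t_used[ti] && !c_used[ci]) {
        t_used[ti] <- TRUE; c_used[ci] <- TRUE; keep[i] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  mislabeled <- sum(!pairs$family_ok)
  tp_pairs <- if (strict) pairs |> filter(.data$family_ok) else pairs
  tp <- nrow(tp_pairs)
  fp <- nrow(calls) - tp
  fn <- nrow(truth) - tp
  events <- truth |>
    mutate(truth_idx = row_number()) |>
    left_join(tp_pairs |>
                select("truth_idx", "call_idx", "dist"),
              by = "truth_idx") |>
    mutate(detected = !is.na(.data$call_idx),
           call_start = ifelse(.data$detected, calls$start[.data$call_idx],
                               NA_real_),
           call_family = ifelse(.data$detected,
                                calls$family[.data$call_idx],
                                NA_character_)) |>
    select(-"truth_idx")
  list(tp = tp, fp = fp, fn = fn, mislabeled = mislabeled, events = events)
}

#' Summarize TP/FP/FN counts into benchmark metrics
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Tibble with `tp`, `fp`, `fn`, `sensitivity` (TP / (TP + FN)) and
#'   `fp_fraction` (FP / (TP + FP)); metrics are `NA` when their denominator
#'   is zero.
#' @examples
#' summarize_benchmark(1064, 95, 36)
#' @export
summarize_benchmark <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tibble(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fp_fraction = if (tp + fp > 0) fp / (tp + fp) else NA_real_
  )
}

#' Score a call set against the planted truth
#'
#' Convenience wrapper around [match_calls()] and [summarize_benchmark()]
#' returning a `te_benchmark` object with [tidy()], [glance()] and
#' [autoplot()] methods.
#'
#' @inheritParams match_calls
#' @return A `te_benchmark` object.
#' @export
benchmark_calls <- function(calls, truth, tolerance = 30, strict = TRUE) {
  m <- match_calls(calls, truth, tolerance, strict)
  structure(list(
    counts = list(tp = m$tp, fp = m$fp, fn = m$fn,
                  mislabeled = m$mislabeled),
    metrics = summarize_benchmark(m$tp, m$fp, m$fn),
    events = m$events,
    n_calls = nrow(as_tibble(calls)),
    tolerance = tolerance,
    strict = strict
  ), class = "te_benchmark")
}

#' @export
print.te_benchmark <- function(x, ...) {
  cat(sprintf(
    "TE benchmark (tolerance %d bp%s): %d truth events, %d calls\n",
    x$tolerance, if (x$strict) ", strict families" else "",
    nrow(x$events), x$n_calls))
  cat(sprintf("  TP %d | FP %d | FN %d | mislabeled %d\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$mislabeled))
  cat(sprintf("  sensitivity %.1f%% | FP fraction %.1f%%\n",
              100 * x$metrics$sensitivity, 100 * x$metrics$fp_fraction))
  invisible(x)
}

#' @describeIn benchmark_calls Per-truth-event table (one row per planted
#'   event with its matched call, distance and detection status).
#' @param x A `te_benchmark` object.
#' @param ... Unused.
#' @method tidy te_benchmark
#' @export
tidy.te_benchmark <- function(x, ...) {
  as_tibble(x$events)
}

#' @describeIn benchmark_calls One-row summary of counts and metrics.
#' @method glance te_benchmark
#' @export
glance.te_benchmark <- function(x, ...) {
  x$metrics |> mutate(mislabeled = x$counts$mislabeled,
                      n_calls = x$n_calls, tolerance = x$tolerance)
}

#' @describeIn benchmark_calls Bar chart of TP/FP/FN counts, optionally per
#'   truth class.
#' @param object A `te_benchmark` object.
#' @method autoplot te_benchmark
#' @export
autoplot.te_benchmark <- function(object, ...) {
  d <- tibble(
    outcome = factor(c("true (+)", "false (+)", "false (-)"),
                     levels = c("true (+)", "false (+)", "false (-)")),
    count = c(object$counts$tp, object$counts$fp, object$counts$fn)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$count,
                                  fill = .data$outcome)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "TE insertions",
                  title = "Call set vs planted truth") +
    ggplot2::theme_minimal()
}

#' Plot estimated against planted allele frequencies
#'
#' Violin-style summary of frequency recovery: one panel per planted
#' frequency, estimated frequencies on the y axis with the planted value as
#' a dashed line.
#'
#' @param calls Frequency-annotated calls tibble.
#' @param truth Truth tibble with `position` and `population_frequency`.
#' @param tolerance Matching tolerance (bp).
#' @return A ggplot object.
#' @export
plot_frequency_recovery <- function(calls, truth, tolerance = 30) {
  m <- match_calls(calls, truth, tolerance)
  d <- m$events |>
    filter(.data$detected) |>
    mutate(estimated = calls$frequency[.data$call_idx],
           planted = factor(round(.data$population_frequency, 3)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$planted, y = .data$estimated)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::geom_segment(
      data = d |> distinct(.data$planted, .data$population_frequency),
      ggplot2::aes(x = as.integer(.data$planted) - 0.45,
                   xend = as.integer(.data$planted) + 0.45,
                   y = .data$population_frequency,
                   yend = .data$population_frequency),
      linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "planted frequency", y = "estimated frequency") +
    ggplot2::theme_minimal()
}
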