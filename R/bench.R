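#' Score full-length identification against simulator truth
#'
#' Precision is the fraction of reads identified as full-length that truly
#' are full-length; recall is the fraction of true full-length reads that
#' were retrieved.  A read counts as identified full-length when its label
#' is `full_length` and, if present, its `passes_quality` flag is `TRUE`.
#'
#' @param classification Per-read classification table
#'   (from [classify_reads()] or [tidy()] of a [preprocess()] result).
#' @param truth Truth table of a [generate_dataset()] result.
#' @param beta F-beta weighting for the summary score.
#' @param dataset_id Optional label carried into the result.
#' @return A one-row tibble of class `eval_result`: `dataset_id`, `beta`,
#'   `n`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f_beta`.
#' @export
evaluate_full_length <- function(classification, truth, beta = 0.2,
                                 dataset_id = NA_character_) {
  stopifnot(is.data.frame(classification), is.data.frame(truth))
  only_pred <- setdiff(classification$read_id, truth$read_id)
  only_truth <- setdiff(truth$read_id, classification$read_id)
  if (length(only_pred) || length(only_truth)) {
    stop("read_id sets differ; only in classification: ",
         paste(head(only_pred, 5), collapse = ", "),
         if (length(only_pred) > 5) " ...",
         "; only in truth: ",
         paste(head(only_truth, 5), collapse = ", "),
         if (length(only_truth) > 5) " ...",
         call. = FALSE)
  }
  m <- match(truth$read_id, classification$read_id)
  pred_fl <- classification$label[m] == "full_length"
  if ("passes_quality" %in% names(classification)) {
    pred_fl <- pred_fl & classification$passes_quality[m]
  }
  true_fl <- truth$category == "full_length"
  tp <- sum(pred_fl & true_fl)
  fp <- sum(pred_fl & !true_fl)
  fn <- sum(!pred_fl & true_fl)
  tn <- sum(!pred_fl & !true_fl)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  out <- tibble::tibble(
    dataset_id = dataset_id, beta = beta, n = nrow(truth),
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall,
    f_beta = f_beta(precision, recall, beta)
  )
  class(out) <- c("eval_result", class(out))
  out
}

#' Run the simulation benchmark
#'
#' For each configuration: generate a ground-truthed dataset, self-tune
#' cutoffs on that dataset (tuning is per dataset, as in per-file
#' self-optimisation), classify and trim, and score full-length
#' identification for each requested beta.  Medians across datasets (the
#' boxplot summary statistic) are reported per beta.
#'
#' @param configs List of [sim_config()]s, e.g. from [benchmark_grid()].
#' @param betas Numeric vector of F-beta weightings; cutoffs are
#'   re-optimised for each beta from the same alignment samples.
#' @param schema An [ap_schema()] used both to simulate and to detect.
#' @param min_q Mean-quality filter applied to full-length reads
#'   (0 disables, the benchmarking default, so scores reflect
#'   classification alone).
#' @param sample_size Tuning sample size per dataset.
#' @return An object of class `benchmark_result`: list with `results`
#'   (one row per dataset x beta) and `medians` (per-beta median precision
#'   and recall).  Supports [tidy()], [glance()] and [autoplot()].
#' @export
run_benchmark <- function(configs, betas = 0.2, schema = synthetic_schema(),
                          min_q = 0, sample_size = 5000L) {
  stopifnot(length(configs) > 0)
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- sprintf("dataset%03d", seq_along(configs))
  }
  results <- purrr::imap_dfr(configs, function(cfg, id) {
    ds <- generate_dataset(cfg, schema)
    samples <- sample_alignments(ds$reads, schema,
                                 sample_size = sample_size,
                                 seed = cfg$seed)
    purrr::map_dfr(betas, function(b) {
      tun <- optimize_cutoffs(samples, beta = b)
      res <- preprocess(ds$reads, schema, cutoffs = tun, min_q = min_q)
      ev <- evaluate_full_length(res$classification, ds$truth, beta = b,
                                 dataset_id = id)
      dplyr::mutate(ev, error_rate = cfg$error_rate,
                    frac_full_length = cfg$frac_full_length,
                    frac_fusion = cfg$frac_fusion,
                    frac_truncated = cfg$frac_truncated,
                    .after = "n")
    })
  })
  medians <- results |>
    dplyr::group_by(.data$beta) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      median_precision = median(.data$precision),
      median_recall = median(.data$recall),
      .groups = "drop"
    )
  structure(list(results = results, medians = medians),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", nrow(x$results), "dataset x beta runs\n")
  print(x$medians)
  invisible(x)
}

#' @rdname run_benchmark
#' @param x,object A `benchmark_result`.
#' @param ... Unused.
#' @export
tidy.benchmark_result <- function(x, ...) x$results

#' @rdname run_benchmark
#' @export
glance.benchmark_result <- function(x, ...) x$medians

#' @rdname run_benchmark
#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- object$results |>
    tidyr::pivot_longer(c("precision", "recall"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$beta), y = .data$value)) +
    ggplot2::geom_boxplot(fill = "turquoise3", alpha = 0.6) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = expression(beta), y = NULL,
                  title = "Full-length identification across simulated datasets") +
    ggplot2::theme_minimal()
}
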