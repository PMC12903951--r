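#' F-beta score
#'
#' Weighted harmonic mean of precision and recall,
#' \eqn{F_\beta = (1+\beta^2) P R / (\beta^2 P + R)}; 0 when the denominator
#' is 0.  `beta < 1` weights precision, `beta > 1` weights recall; as
#' `beta -> 0` the score tends to P and as `beta -> Inf` to R.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @param beta Positive weighting factor.
#' @return Numeric vector of scores.
#' @export
f_beta <- function(precision, recall, beta) {
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  denom <- beta^2 * precision + recall
  ifelse(denom == 0, 0, (1 + beta^2) * precision * recall / denom)
}

#' Sample true and random AP alignments from a read set
#'
#' The empirical device behind cutoff self-optimisation: on each sampled
#' read, each AP-end substring is aligned twice.  The best hit (taking the
#' better of the two strands) is labelled `true`; the best hit on the
#' remainder of the read, with the first interval excluded, is labelled
#' `random`.  The resulting score distributions show, for this dataset, what
#' genuine end-of-read AP hits and chance hits look like, and are the input
#' of [optimize_cutoffs()].
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param schema An [ap_schema()].
#' @param length_grid Integer vector of AP substring lengths to try; default
#'   10 to the full AP length in steps of 2 (always including the full
#'   length), per AP end.
#' @param sample_size Maximum number of reads to sample (simple random
#'   sample under `seed`; the file-streaming interfaces use reservoir
#'   sampling with the same seed convention).
#' @param seed Integer seed controlling the read sample.
#' @return A tibble with one row per (read, AP end, length, label):
#'   `read_id`, `read_length`, `ap_id`, `ap_sub_length`, `label`
#'   (`"true"`/`"random"`), `strand`, `similarity`, `end_distance`.
#' @export
sample_alignments <- function(reads, schema, length_grid = NULL,
                              sample_size = 5000L, seed = 1136L) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) stop("no reads to tune on", call. = FALSE)
  if (sample_size < 1L) stop("sample_size must be >= 1", call. = FALSE)
  if (nrow(reads) > sample_size) {
    idx <- withr::with_seed(seed, sample.int(nrow(reads), sample_size))
    reads <- reads[sort(idx), ]
  }
  seqs <- reads$sequence
  lens <- nchar(seqs)

  per_ap <- function(ap_id) {
    full <- ap_full_length(schema, ap_id)
    grid <- if (is.null(length_grid)) {
      unique(pmin(c(seq(10L, full, by = 2L), full), full))
    } else {
      unique(pmin(as.integer(length_grid), full))
    }
    if (any(grid < 1L)) stop("AP substring lengths must be >= 1", call. = FALSE)
    purrr::map_dfr(grid, function(L) {
      sample_one_length(reads, seqs, lens, schema, ap_id, L)
    })
  }
  out <- dplyr::bind_rows(per_ap("front"), per_ap("rear"))
  out
}

# True/random sample rows for one (AP end, substring length).
sample_one_length <- function(reads, seqs, lens, schema, ap_id, L) {
  pat_p <- ap_pattern(schema, ap_id, L, "+")
  pat_m <- ap_pattern(schema, ap_id, L, "-")
  hp <- cpp_infix_best(pat_p, seqs)
  hm <- cpp_infix_best(pat_m, seqs)
  dp <- hp[, "edit_distance"]; dm <- hm[, "edit_distance"]
  # better of the two strands; ties favour "+" for determinism
  use_m <- !is.na(dm) & (is.na(dp) | dm < dp)
  found <- !is.na(dp) | !is.na(dm)
  if (!any(found)) return(NULL)
  first <- ifelse(rep(use_m, 3L), hm, hp)
  dim(first) <- dim(hp)
  strand <- ifelse(use_m, "-", "+")
  i <- which(found)

  d1 <- first[i, 1L]; s1 <- first[i, 2L]; e1 <- first[i, 3L]
  ed1 <- end_distance(ap_id, strand[i], s1, e1, lens[i])
  true_rows <- tibble::tibble(
    read_id = reads$read_id[i], read_length = lens[i],
    ap_id = ap_id, ap_sub_length = L, label = "true", strand = strand[i],
    similarity = 1 - d1 / L,
    end_distance = ed1
  )

  # Random alignment: same pattern, first interval excluded.
  pat1 <- ifelse(use_m[i], pat_m, pat_p)
  sec <- matrix(NA_integer_, length(i), 3L)
  for (pat in unique(pat1)) {
    j <- which(pat1 == pat)
    sec[j, ] <- cpp_infix_second(pat, seqs[i][j], s1[j], e1[j])
  }
  has2 <- !is.na(sec[, 1L])
  rand_rows <- NULL
  if (any(has2)) {
    k <- which(has2)
    d2 <- sec[k, 1L]; s2 <- sec[k, 2L]; e2 <- sec[k, 3L]
    ed2 <- end_distance(ap_id, strand[i][k], s2, e2, lens[i][k])
    rand_rows <- tibble::tibble(
      read_id = reads$read_id[i][k], read_length = lens[i][k],
      ap_id = ap_id, ap_sub_length = L, label = "random",
      strand = strand[i][k],
      similarity = 1 - d2 / L,
      end_distance = ed2
    )
  }
  dplyr::bind_rows(true_rows, rand_rows)
}

#' Precision and recall of one cutoff pair on an alignment sample
#'
#' A sample passes when `similarity >= s_cut` and `end_distance <= loc_cut`.
#' Precision is the fraction of passing samples that are true alignments
#' (1 when nothing passes); recall is the fraction of true alignments that
#' pass.
#'
#' @param samples Alignment sample tibble (one AP end and substring length;
#'   see [sample_alignments()]).
#' @param s_cut Similarity cutoff in \[0, 1\].
#' @param loc_cut Location cutoff (maximum allowed `end_distance`, bases).
#' @return A one-row tibble with `precision` and `recall`.
#' @export
evaluate_cutoff <- function(samples, s_cut, loc_cut) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0)
  pass <- samples$similarity >= s_cut & samples$end_distance <= loc_cut
  is_true <- samples$label == "true"
  tp <- sum(pass & is_true)
  fp <- sum(pass & !is_true)
  fn <- sum(!pass & is_true)
  tibble::tibble(
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn)
  )
}

default_similarity_grid <- function() seq(0.50, 1.00, by = 0.01)
default_location_grid <- function() seq(10L, 200L, by = 10L)

# F-beta surface of one (ap_id, L) over the full cutoff grid.
cutoff_surface <- function(samples, beta, s_grid, loc_grid) {
  is_true <- samples$label == "true"
  n_true <- sum(is_true)
  Ps <- outer(samples$similarity, s_grid, `>=`) * 1
  Pl <- outer(samples$end_distance, loc_grid, `<=`) * 1
  TP <- crossprod(Ps[is_true, , drop = FALSE], Pl[is_true, , drop = FALSE])
  FP <- crossprod(Ps[!is_true, , drop = FALSE], Pl[!is_true, , drop = FALSE])
  P <- ifelse(TP + FP == 0, 1, TP / (TP + FP))
  R <- if (n_true == 0) matrix(1, nrow(TP), ncol(TP)) else TP / n_true
  list(precision = P, recall = R, f = f_beta(P, R, beta))
}

# Most stringent cell within `tol` of the best score on one surface:
# highest similarity cutoff, then smallest location cutoff.
stringent_cell <- function(surf, target, s_grid, loc_grid) {
  cand <- which(surf$f >= target, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(NULL)
  si <- max(cand[, 1L])
  li <- min(cand[cand[, 1L] == si, 2L])
  tibble::tibble(
    similarity_cutoff = s_grid[si], location_cutoff = loc_grid[li],
    precision = surf$precision[si, li], recall = surf$recall[si, li],
    f_beta = surf$f[si, li]
  )
}

#' Optimise AP identification cutoffs by F-beta maximisation
#'
#' For each AP end and each candidate AP substring length, grid-searches the
#' (similarity cutoff, location cutoff) plane for the pair maximising the
#' F-beta score of separating true from random alignment samples; the length
#' whose best score is highest wins.  Ties prefer stringency: highest
#' similarity cutoff, then smallest location window, then longest substring.
#'
#' @param samples Alignment samples from [sample_alignments()].
#' @param beta F-beta weighting; the default 0.2 sits in the
#'   precision-first 0.1--0.3 band recommended for full-length read
#'   identification.
#' @param similarity_grid,location_grid Candidate cutoff grids.
#' @param stringency_tolerance Score tolerance for final selection: among
#'   grid cells whose F-beta is within this much of the maximum, the most
#'   stringent cutoffs (highest similarity, smallest location window,
#'   longest substring) are chosen.  The score surface is estimated from a
#'   finite sample contaminated by reads that violate the one-AP-per-end
#'   assumption, so score differences below estimation noise carry no
#'   information; this one-standard-error-style rule keeps the selection
#'   from chasing that noise toward lax cutoffs.
#' @return An object of class `ap_tuning`: a list with `cutoffs` (one row
#'   per AP end: `ap_id`, `similarity_cutoff`, `location_cutoff`,
#'   `ap_sub_length`, `beta`, achieved `precision`, `recall`, `f_beta`),
#'   `by_length` (the best score per candidate length), `samples` and the
#'   grids.  Supports [tidy()], [glance()] and [autoplot()].
#' @export
optimize_cutoffs <- function(samples, beta = 0.2,
                             similarity_grid = default_similarity_grid(),
                             location_grid = default_location_grid(),
                             stringency_tolerance = 0.002) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0)
  if (length(beta) != 1L || beta <= 0) stop("beta must be > 0", call. = FALSE)
  ap_ids <- unique(samples$ap_id)
  per_ap <- lapply(ap_ids, function(ap) {
    sub <- samples[samples$ap_id == ap, ]
    if (nrow(sub) == 0L || !any(sub$label == "true")) {
      stop("no alignment samples for AP '", ap, "'", call. = FALSE)
    }
    lengths <- sort(unique(sub$ap_sub_length))
    surfaces <- lapply(lengths, function(L) {
      cutoff_surface(sub[sub$ap_sub_length == L, ], beta,
                     similarity_grid, location_grid)
    })
    f_max <- max(vapply(surfaces, function(s) max(s$f), numeric(1)))
    # The score surface is estimated from a finite, contaminated sample:
    # differences below the estimation noise are not meaningful.  Among
    # cells statistically indistinguishable from the optimum, prefer the
    # most stringent (highest similarity cutoff, smallest location window,
    # longest AP substring) -- a one-standard-error-style rule serving the
    # precision-first objective.
    target <- f_max - stringency_tolerance
    by_length <- purrr::map2_dfr(lengths, surfaces, function(L, surf) {
      row <- stringent_cell(surf, max(surf$f), similarity_grid, location_grid)
      dplyr::bind_cols(tibble::tibble(ap_id = ap, ap_sub_length = L), row)
    })
    cand <- purrr::map2_dfr(lengths, surfaces, function(L, surf) {
      row <- stringent_cell(surf, target, similarity_grid, location_grid)
      if (is.null(row)) return(NULL)
      dplyr::bind_cols(tibble::tibble(ap_id = ap, ap_sub_length = L), row)
    })
    sel <- cand |>
      dplyr::filter(.data$similarity_cutoff == max(.data$similarity_cutoff)) |>
      dplyr::filter(.data$location_cutoff == min(.data$location_cutoff)) |>
      dplyr::filter(.data$ap_sub_length == max(.data$ap_sub_length))
    list(by_length = by_length, selected = sel)
  })
  by_length <- purrr::map_dfr(per_ap, "by_length")
  cutoffs <- purrr::map_dfr(per_ap, "selected") |>
    dplyr::mutate(beta = beta) |>
    dplyr::select("ap_id", "similarity_cutoff", "location_cutoff",
                  "ap_sub_length", "beta", "precision", "recall", "f_beta")
  # Chimera-evidence threshold: interior AP hits are screened over the whole
  # read at full AP length, so their similarity must exceed what chance
  # alignments reach there.  A robust upper bound of the sampled random
  # (second-alignment) similarity distribution at the longest sampled length
  # is used -- median + 4 MAD, robust to contamination by genuine extra AP
  # copies on chimeric reads -- and never less than the tuned cutoff.
  cutoffs$mid_similarity_cutoff <- vapply(cutoffs$ap_id, function(ap) {
    sub <- samples[samples$ap_id == ap, ]
    lmax <- max(sub$ap_sub_length)
    rs <- sub$similarity[sub$ap_sub_length == lmax & sub$label == "random"]
    co <- cutoffs$similarity_cutoff[cutoffs$ap_id == ap]
    if (length(rs) < 10) return(co)
    min(1, max(co, median(rs) + 4 * stats::mad(rs)))
  }, numeric(1))
  structure(
    list(cutoffs = cutoffs, by_length = by_length, samples = samples,
         beta = beta, similarity_grid = similarity_grid,
         location_grid = location_grid),
    class = "ap_tuning"
  )
}

#' Tune cutoffs directly from reads
#'
#' Convenience wrapper: [sample_alignments()] then [optimize_cutoffs()].
#'
#' @inheritParams sample_alignments
#' @inheritParams optimize_cutoffs
#' @return An `ap_tuning` object.
#' @export
tune_cutoffs <- function(reads, schema, beta = 0.2, length_grid = NULL,
                         sample_size = 5000L, seed = 1136L,
                         similarity_grid = default_similarity_grid(),
                         location_grid = default_location_grid()) {
  samples <- sample_alignments(reads, schema, length_grid = length_grid,
                               sample_size = sample_size, seed = seed)
  optimize_cutoffs(samples, beta = beta, similarity_grid = similarity_grid,
                   location_grid = location_grid)
}

#' @export
print.ap_tuning <- function(x, ...) {
  cat("<ap_tuning> beta =", x$beta, "\n")
  print(x$cutoffs)
  invisible(x)
}

#' @rdname optimize_cutoffs
#' @param x An `ap_tuning` object.
#' @param ... Unused.
#' @export
tidy.ap_tuning <- function(x, ...) x$cutoffs

#' @rdname optimize_cutoffs
#' @export
glance.ap_tuning <- function(x, ...) {
  tibble::tibble(
    beta = x$beta,
    n_samples = nrow(x$samples),
    n_reads = length(unique(x$samples$read_id)),
    mean_f_beta = mean(x$cutoffs$f_beta),
    min_precision = min(x$cutoffs$precision),
    min_recall = min(x$cutoffs$recall)
  )
}

#' Plot true vs random alignment score distributions
#'
#' Faceted histograms of similarity and end-distance for the true and
#' random alignment samples at each AP's selected substring length, with the
#' selected cutoffs drawn as dashed lines.
#'
#' @param object An `ap_tuning` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ap_tuning <- function(object, ...) {
  sel <- object$cutoffs
  df <- object$samples |>
    dplyr::inner_join(
      dplyr::select(sel, "ap_id", "ap_sub_length",
                    "similarity_cutoff", "location_cutoff"),
      by = c("ap_id", "ap_sub_length")
    ) |>
    tidyr::pivot_longer(c("similarity", "end_distance"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(cut = ifelse(.data$metric == "similarity",
                               .data$similarity_cutoff,
                               .data$location_cutoff))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$cut),
                        linetype = "dashed") +
    ggplot2::facet_grid(ap_id ~ metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "alignments", fill = NULL,
                  title = "True vs random AP alignments at the selected length") +
    ggplot2::theme_minimal()
}
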