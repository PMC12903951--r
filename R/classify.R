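as_cutoffs <- function(cutoffs) {
  if (inherits(cutoffs, "ap_tuning")) cutoffs <- cutoffs$cutoffs
  stopifnot(is.data.frame(cutoffs))
  need <- c("ap_id", "similarity_cutoff", "location_cutoff", "ap_sub_length")
  if (!all(need %in% names(cutoffs))) {
    stop("cutoffs must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("front", "rear") %in% cutoffs$ap_id)) {
    stop("cutoffs must cover both 'front' and 'rear' AP ends", call. = FALSE)
  }
  cutoffs
}

cutoff_row <- function(cutoffs, ap) cutoffs[match(ap, cutoffs$ap_id), ]

# Hits of one (AP end, strand) across all reads.  End acceptance uses the
# tuned substring length; chimera (mid-read) evidence is collected at full
# AP length: interior candidates are searched over the whole read rather
# than a terminal window, so they need the full AP's specificity to keep
# the chance-evidence rate negligible.  The masked second alignment at full
# length detects an internal extra copy even when the terminal copy aligned
# best.
combo_hits <- function(seqs, lens, schema, ap, strand, co) {
  L <- co$ap_sub_length
  pat <- ap_pattern(schema, ap, L, strand)
  h <- cpp_infix_best(pat, seqs)
  d <- h[, "edit_distance"]
  s <- 1 - d / L
  ed <- end_distance(ap, strand, h[, "read_start"], h[, "read_end"], lens)
  pass_s <- !is.na(s) & s >= co$similarity_cutoff
  accepted <- pass_s & ed <= co$location_cutoff

  mid_cut <- if (!is.null(co$mid_similarity_cutoff) &&
                 !is.na(co$mid_similarity_cutoff)) {
    co$mid_similarity_cutoff
  } else {
    co$similarity_cutoff
  }
  Lf <- ap_full_length(schema, ap)
  patf <- ap_pattern(schema, ap, Lf, strand)
  hf <- cpp_infix_best(patf, seqs)
  df <- hf[, "edit_distance"]
  sf <- 1 - df / Lf
  edf <- end_distance(ap, strand, hf[, "read_start"], hf[, "read_end"], lens)
  passf <- !is.na(sf) & sf >= mid_cut
  mid <- passf & edf > co$location_cutoff

  n <- length(seqs)
  mid2 <- rep(FALSE, n)
  s2v <- rep(NA_real_, n)
  ed2v <- st2v <- en2v <- rep(NA_integer_, n)
  i <- which(!is.na(df))
  if (length(i)) {
    h2 <- cpp_infix_second(patf, seqs[i], hf[i, "read_start"],
                           hf[i, "read_end"])
    d2 <- h2[, "edit_distance"]
    s2 <- 1 - d2 / Lf
    ed2 <- end_distance(ap, strand, h2[, "read_start"], h2[, "read_end"],
                        lens[i])
    pass2 <- !is.na(s2) & s2 >= mid_cut
    mid2[i] <- pass2 & ed2 > co$location_cutoff
    s2v[i] <- s2
    ed2v[i] <- ed2
    st2v[i] <- h2[, "read_start"]
    en2v[i] <- h2[, "read_end"]
  }
  list(similarity = s, end_distance = ed,
       start = h[, "read_start"], end = h[, "read_end"],
       accepted = accepted, mid = mid, mid_second = mid2,
       full_length_L = Lf,
       full_similarity = sf, full_end_distance = edf,
       full_start = hf[, "read_start"], full_end = hf[, "read_end"],
       full2_similarity = s2v, full2_end_distance = ed2v,
       full2_start = st2v, full2_end = en2v)
}

#' Locate adapter/primer hits on reads under tuned cutoffs
#'
#' Aligns each AP end's tuned-length substring on both strands of every
#' read; a hit passing the similarity cutoff and lying within the location
#' window of its expected terminus is an accepted end hit.  Interior
#' (chimera) evidence is collected with the full-length AP: the read's best
#' full-AP alignment and, after excluding it, the best alignment on the
#' remainder; either is a mid-read hit when it passes the similarity cutoff
#' but fails the location cutoff.
#'
#' @param reads Read tibble.
#' @param schema An [ap_schema()].
#' @param cutoffs An `ap_tuning` object or its cutoff tibble
#'   (see [optimize_cutoffs()]).
#' @return A tibble of hits: `read_id`, `ap_id`, `strand`, `rank`
#'   (`"first"`/`"second"`), `ap_sub_length` (the tuned length for
#'   end-acceptance rows, the full AP length for mid-evidence rows),
#'   `read_start`, `read_end` (0-based half-open, forward read),
#'   `similarity`, `end_distance`, `accepted`, `mid`.
#' @export
locate_aps <- function(reads, schema, cutoffs) {
  cutoffs <- as_cutoffs(cutoffs)
  seqs <- reads$sequence
  lens <- nchar(seqs)
  rows <- list()
  add <- function(ap, strand, rank, L, start, end, sim, ed, acc, mid) {
    found <- which(!is.na(start))
    if (!length(found)) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      read_id = reads$read_id[found], ap_id = ap, strand = strand,
      rank = rank, ap_sub_length = L,
      read_start = start[found], read_end = end[found],
      similarity = sim[found], end_distance = ed[found],
      accepted = acc[found], mid = mid[found]
    )
  }
  for (ap in c("front", "rear")) {
    co <- cutoff_row(cutoffs, ap)
    for (strand in c("+", "-")) {
      cb <- combo_hits(seqs, lens, schema, ap, strand, co)
      add(ap, strand, "first", co$ap_sub_length,
          cb$start, cb$end, cb$similarity, cb$end_distance,
          cb$accepted, rep(FALSE, length(seqs)))
      add(ap, strand, "first", cb$full_length_L,
          cb$full_start, cb$full_end, cb$full_similarity,
          cb$full_end_distance, rep(FALSE, length(seqs)), cb$mid)
      add(ap, strand, "second", cb$full_length_L,
          cb$full2_start, cb$full2_end, cb$full2_similarity,
          cb$full2_end_distance, rep(FALSE, length(seqs)), cb$mid_second)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- dplyr::arrange(out, match(.data$read_id, reads$read_id),
                          .data$ap_id, .data$strand, .data$rank,
                          .data$ap_sub_length)
  }
  out
}

#' Classify reads as full-length, truncated or chimeric
#'
#' A read with any mid-read AP hit is chimeric (this takes precedence).
#' Otherwise a read with accepted front and rear end hits in a consistent
#' orientation is full-length, with its strand taken from those hits; any
#' other read is truncated (a single accepted end hit still records the
#' strand).
#'
#' @inheritParams locate_aps
#' @return A tibble with one row per read: `read_id`, `label`
#'   (`full_length` / `truncated` / `chimeric`), `strand` (`+`, `-` or
#'   `unknown`), `front_similarity`, `rear_similarity`, `front_start`,
#'   `front_end`, `rear_start`, `rear_end` (forward-read coordinates of the
#'   accepted hits) and `n_mid_hits`.
#' @export
classify_reads <- function(reads, schema, cutoffs) {
  cutoffs <- as_cutoffs(cutoffs)
  seqs <- reads$sequence
  lens <- nchar(seqs)
  n <- length(seqs)
  combos <- list(
    fp = combo_hits(seqs, lens, schema, "front", "+", cutoff_row(cutoffs, "front")),
    fm = combo_hits(seqs, lens, schema, "front", "-", cutoff_row(cutoffs, "front")),
    rp = combo_hits(seqs, lens, schema, "rear", "+", cutoff_row(cutoffs, "rear")),
    rm = combo_hits(seqs, lens, schema, "rear", "-", cutoff_row(cutoffs, "rear"))
  )
  n_mid <- combos$fp$mid + combos$fm$mid +
    combos$rp$mid + combos$rm$mid +
    combos$fp$mid_second + combos$fm$mid_second +
    combos$rp$mid_second + combos$rm$mid_second
  chimeric <- n_mid > 0

  fl_p <- combos$fp$accepted & combos$rp$accepted
  fl_m <- combos$fm$accepted & combos$rm$accepted
  s_p <- combos$fp$similarity + combos$rp$similarity
  s_m <- combos$fm$similarity + combos$rm$similarity
  # when both orientations qualify (degenerate), prefer the better-scoring one
  use_minus <- fl_m & (!fl_p | (!is.na(s_m) & !is.na(s_p) & s_m > s_p))
  full <- (fl_p | fl_m) & !chimeric

  label <- rep("truncated", n)
  label[full] <- "full_length"
  label[chimeric] <- "chimeric"

  # strand for truncated reads: best single accepted end hit
  acc_s <- cbind(ifelse(combos$fp$accepted, combos$fp$similarity, NA),
                 ifelse(combos$fm$accepted, combos$fm$similarity, NA),
                 ifelse(combos$rp$accepted, combos$rp$similarity, NA),
                 ifelse(combos$rm$accepted, combos$rm$similarity, NA))
  combo_strand <- c("+", "-", "+", "-")
  any_acc <- rowSums(!is.na(acc_s)) > 0
  best_combo <- rep(NA_integer_, n)
  best_combo[any_acc] <- max.col(replace(acc_s, is.na(acc_s), -Inf),
                                 ties.method = "first")[any_acc]
  strand <- rep("unknown", n)
  strand[any_acc] <- combo_strand[best_combo[any_acc]]
  strand[full] <- ifelse(use_minus[full], "-", "+")

  pick <- function(field, which_combo, sel) {
    out <- rep(NA_integer_, n)
    out[sel] <- which_combo[[field]][sel]
    out
  }
  fr <- ifelse(strand == "-" & full, "fm", "fp")
  front_sim <- rear_sim <- rep(NA_real_, n)
  front_start <- front_end <- rear_start <- rear_end <- rep(NA_integer_, n)
  for (side in c("+", "-")) {
    sel <- full & strand == side
    fc <- combos[[if (side == "+") "fp" else "fm"]]
    rc <- combos[[if (side == "+") "rp" else "rm"]]
    front_sim[sel] <- fc$similarity[sel]
    rear_sim[sel] <- rc$similarity[sel]
    front_start[sel] <- fc$start[sel]
    front_end[sel] <- fc$end[sel]
    rear_start[sel] <- rc$start[sel]
    rear_end[sel] <- rc$end[sel]
  }

  tibble::tibble(
    read_id = reads$read_id, label = label, strand = strand,
    front_similarity = front_sim, rear_similarity = rear_sim,
    front_start = front_start, front_end = front_end,
    rear_start = rear_start, rear_end = rear_end,
    n_mid_hits = as.integer(n_mid)
  )
}

# PolyA boundary scan: from the rear AP's insert-proximal boundary
# (0-based `rear_start` on the sense-oriented read) move insert-ward,
# consuming A's.  A non-A base is consumed only when the four bases
# immediately insert-ward of it are all A; at least `min_lead` A's adjacent
# to the AP are required for any trimming.  Returns the new trim end.
polya_boundary <- function(chars, rear_start, min_lead = 4L, lookahead = 4L) {
  i <- rear_start
  run0 <- 0L
  while (i > 0L && chars[i] == "A") {
    i <- i - 1L
    run0 <- run0 + 1L
  }
  if (run0 < min_lead) return(rear_start)
  repeat {
    if (i == 0L) break
    if (i > lookahead && all(chars[(i - lookahead):(i - 1L)] == "A")) {
      i <- i - 1L
      while (i > 0L && chars[i] == "A") i <- i - 1L
    } else {
      break
    }
  }
  i
}

#' Trim full-length reads to their insert
#'
#' Reorients each full-length read to the sense strand (reverse-complement
#' plus quality reversal for minus-strand reads), removes the front AP up to
#' its insert-proximal boundary and the rear AP from its insert-proximal
#' boundary, then trims the polyA run adjacent to the rear boundary (see
#' Details).  The output sequence is always a contiguous subsequence of the
#' oriented read; qualities are trimmed identically.  The original strand is
#' recorded in the FASTQ comment as `strand=+` or `strand=-`.
#'
#' @details The polyA scan moves insert-ward from the rear AP boundary
#' consuming A's; an interrupting non-A base is consumed only when the four
#' bases beyond it are all A, and at least four A's adjacent to the AP are
#' required for any polyA trimming.  This removes tails with isolated
#' sequencing-error interruptions while never walking into insert sequence
#' that does not itself end in an A run (where the boundary is inherently
#' ambiguous).
#'
#' @inheritParams locate_aps
#' @param classification Output of [classify_reads()].
#' @return A tibble of trimmed sense-oriented reads (`read_id`, `sequence`,
#'   `quality`, `comment`) with `trim_start`/`trim_end` (0-based half-open
#'   on the oriented read).  Degenerate reads whose AP intervals leave no
#'   insert get an empty sequence and an `NA` interval.
#' @export
trim_reads <- function(reads, classification, schema) {
  stopifnot(is.data.frame(classification))
  cls <- classification[classification$label == "full_length", ]
  if (any(!cls$read_id %in% reads$read_id)) {
    stop("classification refers to reads not present in `reads`", call. = FALSE)
  }
  if (nrow(cls) == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character(), comment = character(),
                          trim_start = integer(), trim_end = integer()))
  }
  ri <- match(cls$read_id, reads$read_id)
  seqs <- reads$sequence[ri]
  quals <- reads$quality[ri]
  lens <- nchar(seqs)
  minus <- cls$strand == "-"
  seqs[minus] <- as.character(cpp_revcomp(seqs[minus]))
  quals[minus] <- as.character(cpp_strrev(quals[minus]))
  # hit intervals on the oriented read
  o_front_end <- ifelse(minus, lens - cls$front_start, cls$front_end)
  o_rear_start <- ifelse(minus, lens - cls$rear_end, cls$rear_start)

  n <- nrow(cls)
  trim_start <- as.integer(o_front_end)
  trim_end <- rep(NA_integer_, n)
  out_seq <- character(n)
  out_qual <- character(n)
  for (k in seq_len(n)) {
    rs <- o_rear_start[k]
    ts <- trim_start[k]
    if (is.na(rs) || is.na(ts) || rs <= ts) next
    chars <- strsplit(substr(seqs[k], 1L, rs), "", fixed = TRUE)[[1]]
    te <- polya_boundary(chars, rs)
    if (te <= ts) { trim_start[k] <- NA_integer_; next }
    trim_end[k] <- te
    out_seq[k] <- substr(seqs[k], ts + 1L, te)
    out_qual[k] <- substr(quals[k], ts + 1L, te)
  }
  empty <- is.na(trim_end)
  trim_start[empty] <- NA_integer_
  tibble::tibble(
    read_id = cls$read_id, sequence = out_seq, quality = out_qual,
    comment = paste0("strand=", cls$strand),
    trim_start = trim_start, trim_end = trim_end
  )
}

#' Preprocess a read set: classify, reorient, trim and quality-filter
#'
#' Runs the full pipeline on an in-memory read tibble: (optionally) tune
#' cutoffs on the data itself, classify every read, trim and sense-orient
#' the full-length reads, and apply the mean-quality filter as the last
#' step, after trimming, so terminal AP/polyA bases do not perturb the
#' quality estimate.  Every input read lands in exactly one of the four
#' output partitions.
#'
#' @inheritParams locate_aps
#' @param cutoffs Tuned cutoffs (an `ap_tuning` or cutoff tibble); when
#'   `NULL`, cutoffs are tuned on `reads` with [tune_cutoffs()].
#' @param beta F-beta weighting used when tuning (ignored when `cutoffs`
#'   is supplied).
#' @param min_q Minimum mean read quality (probability-space mean Phred)
#'   after trimming for a full-length read to pass; `0` disables filtering.
#' @param sample_size,seed,length_grid Tuning parameters, see
#'   [sample_alignments()].
#' @return An object of class `preprocess_result`: a list with read tibbles
#'   `full_length` (trimmed, sense-oriented, quality-passing), `truncated`,
#'   `chimeric`, `failed_quality`, the per-read `classification` table
#'   (`read_id`, `label`, `strand`, similarities, trim interval,
#'   `mean_q`, `passes_quality`), and the `cutoffs` used.  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
preprocess <- function(reads, schema, cutoffs = NULL, beta = 0.2, min_q = 7,
                       sample_size = 5000L, seed = 1136L, length_grid = NULL) {
  tuning <- NULL
  if (is.null(cutoffs)) {
    tuning <- tune_cutoffs(reads, schema, beta = beta,
                           length_grid = length_grid,
                           sample_size = sample_size, seed = seed)
    cutoffs <- tuning
  }
  cut_tab <- as_cutoffs(cutoffs)
  cls <- classify_reads(reads, schema, cut_tab)
  trimmed <- trim_reads(reads, cls, schema)

  cls <- dplyr::left_join(
    cls,
    dplyr::select(trimmed, "read_id", "trim_start", "trim_end"),
    by = "read_id"
  )
  ok <- !is.na(trimmed$trim_end)
  mean_q <- rep(NA_real_, nrow(trimmed))
  mean_q[ok] <- mean_quality(trimmed$quality[ok])
  passes <- ok & mean_q >= min_q
  cls$mean_q <- mean_q[match(cls$read_id, trimmed$read_id)]
  cls$passes_quality <- cls$label == "full_length" &
    passes[match(cls$read_id, trimmed$read_id)]
  cls$passes_quality[is.na(cls$passes_quality)] <- FALSE

  keep_cols <- c("read_id", "sequence", "quality", "comment")
  fl <- trimmed[passes, keep_cols]
  failed <- trimmed[!passes, keep_cols]
  raw_cols <- intersect(c("read_id", "sequence", "quality", "comment"),
                        names(reads))
  res <- list(
    full_length = fl,
    truncated = reads[cls$label == "truncated", raw_cols],
    chimeric = reads[cls$label == "chimeric", raw_cols],
    failed_quality = failed,
    classification = cls,
    cutoffs = cut_tab,
    tuning = tuning,
    min_q = min_q
  )
  class(res) <- "preprocess_result"
  res
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname preprocess
#' @param x,object A `preprocess_result`.
#' @param ... Unused.
#' @export
tidy.preprocess_result <- function(x, ...) x$classification

#' @rdname preprocess
#' @export
glance.preprocess_result <- function(x, ...) {
  tibble::tibble(
    n_reads = nrow(x$classification),
    full_length = nrow(x$full_length),
    truncated = nrow(x$truncated),
    chimeric = nrow(x$chimeric),
    failed_quality = nrow(x$failed_quality),
    min_q = x$min_q
  )
}

#' @rdname preprocess
#' @export
autoplot.preprocess_result <- function(object, ...) {
  counts <- glance(object) |>
    dplyr::select("full_length", "truncated", "chimeric", "failed_quality") |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "category", values_to = "reads")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$category, y = .data$reads,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "reads",
                  title = "Read classification") +
    ggplot2::theme_minimal()
}
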