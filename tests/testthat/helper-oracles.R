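# Independent oracles, deliberately implemented with different machinery
# than the package (utils::adist and plain loops).

# Infix alignment oracle: minimal edit distance of `pattern` against any
# substring of `text`, with the (min d, min start, min end) tie-break.
# utils::adist(partial = TRUE) supplies d from an unrelated C
# implementation; the interval is found by exhaustive substring
# enumeration.  Valid for A/C/G/T-only inputs (adist matches N to N,
# the package does not).
oracle_infix <- function(pattern, text) {
  n <- nchar(text)
  L <- nchar(pattern)
  if (L > n) return(NULL)
  d <- as.integer(utils::adist(pattern, text, partial = TRUE))
  lens <- max(1L, L - d):min(n, L + d)
  best <- NULL
  cand_start <- integer()
  cand_end <- integer()
  cand_str <- character()
  for (len in lens) {
    starts <- 0:(n - len)
    cand_start <- c(cand_start, starts)
    cand_end <- c(cand_end, starts + len)
    cand_str <- c(cand_str, substring(text, starts + 1L, starts + len))
  }
  dd <- as.integer(utils::adist(pattern, cand_str))
  hit <- which(dd == d)
  ord <- hit[order(cand_start[hit], cand_end[hit])][1]
  list(d = d, start = cand_start[ord], end = cand_end[ord])
}

# Oracle for the masked second alignment: best hit over the two flanking
# segments of [mstart, mend), never overlapping the mask.
oracle_infix_masked <- function(pattern, text, mstart, mend) {
  n <- nchar(text)
  left <- if (mstart >= nchar(pattern)) {
    oracle_infix(pattern, substr(text, 1, mstart))
  }
  right <- if (n - mend >= nchar(pattern)) {
    r <- oracle_infix(pattern, substr(text, mend + 1, n))
    if (!is.null(r)) list(d = r$d, start = r$start + mend, end = r$end + mend)
  }
  if (is.null(left)) return(right)
  if (is.null(right)) return(left)
  if (right$d < left$d ||
      (right$d == left$d && (right$start < left$start ||
                             (right$start == left$start && right$end < left$end)))) {
    right
  } else {
    left
  }
}

# Exhaustive cutoff-grid oracle: plain loops over every
# (length, similarity, location) cell, recomputing precision and recall by
# direct counting, then the same stringency-tolerant selection contract.
oracle_optimize <- function(samples, beta,
                            s_grid = seq(0.50, 1.00, by = 0.01),
                            loc_grid = seq(10L, 200L, by = 10L),
                            tol = 0.002) {
  out <- NULL
  for (ap in unique(samples$ap_id)) {
    sub <- samples[samples$ap_id == ap, ]
    lens <- sort(unique(sub$ap_sub_length))
    n_cells <- length(lens) * length(s_grid) * length(loc_grid)
    cells <- data.frame(ap_id = rep(ap, n_cells), ap_sub_length = 0L,
                        similarity_cutoff = 0, location_cutoff = 0L,
                        precision = 0, recall = 0, f_beta = 0)
    k <- 0L
    for (L in lens) {
      sl <- sub[sub$ap_sub_length == L, ]
      for (s_cut in s_grid) {
        for (loc in loc_grid) {
          pass <- sl$similarity >= s_cut & sl$end_distance <= loc
          tp <- sum(pass & sl$label == "true")
          fp <- sum(pass & sl$label == "random")
          fn <- sum(!pass & sl$label == "true")
          P <- if (tp + fp == 0) 1 else tp / (tp + fp)
          R <- if (tp + fn == 0) 1 else tp / (tp + fn)
          f <- if (beta^2 * P + R == 0) 0 else {
            (1 + beta^2) * P * R / (beta^2 * P + R)
          }
          k <- k + 1L
          cells$ap_sub_length[k] <- L
          cells$similarity_cutoff[k] <- s_cut
          cells$location_cutoff[k] <- loc
          cells$precision[k] <- P
          cells$recall[k] <- R
          cells$f_beta[k] <- f
        }
      }
    }
    keep <- cells[cells$f_beta >= max(cells$f_beta) - tol, ]
    keep <- keep[keep$similarity_cutoff == max(keep$similarity_cutoff), ]
    keep <- keep[keep$location_cutoff == min(keep$location_cutoff), ]
    keep <- keep[keep$ap_sub_length == max(keep$ap_sub_length), ]
    out <- rbind(out, keep[1, ])
  }
  out
}

# Order-independent confusion-matrix recount.
oracle_confusion <- function(pred_fl, true_fl) {
  c(tp = sum(pred_fl & true_fl), fp = sum(pred_fl & !true_fl),
    fn = sum(!pred_fl & true_fl), tn = sum(!pred_fl & !true_fl))
}
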