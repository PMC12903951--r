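#' Alignment similarity score
#'
#' Similarity of an adapter/primer alignment: one minus the edit distance
#' divided by the AP substring length, \eqn{s = 1 - d/L}.
#'
#' @param d Edit distance(s), non-negative integers.
#' @param L AP substring length(s), positive integers.
#' @return Numeric similarity values.
#' @export
similarity <- function(d, L) {
  if (any(L < 1)) stop("AP substring length must be >= 1", call. = FALSE)
  if (any(d < 0)) stop("edit distance must be >= 0", call. = FALSE)
  1 - d / L
}

hit_tibble <- function(mat, ap_id, strand, L, rank) {
  keep <- which(!is.na(mat[, "edit_distance"]))
  d <- unname(mat[keep, "edit_distance"])
  tibble::tibble(
    ap_id = ap_id, strand = strand,
    read_start = unname(mat[keep, "read_start"]),
    read_end = unname(mat[keep, "read_end"]),
    edit_distance = d,
    ap_sub_length = L,
    similarity = 1 - d / L,
    rank = rank
  )
}

check_align_args <- function(ap_sub, read_seq) {
  if (length(ap_sub) != 1L || is.na(ap_sub) || nchar(ap_sub) < 1L) {
    stop("ap_sub must be a single non-empty DNA string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", ap_sub)) {
    stop("ap_sub contains characters outside A/C/G/T/N", call. = FALSE)
  }
}

#' Best infix alignment of an AP substring on a read
#'
#' Aligns the entire `ap_sub` against the read, minimising Levenshtein edit
#' distance (substitutions, insertions and deletions cost 1 each) in infix
#' (semi-global) mode: positions of the read before and after the matched
#' interval are free.  Ties are broken deterministically: minimal distance,
#' then smallest `read_start`, then smallest `read_end`.  `N` in the read
#' (or a masking symbol) mismatches every pattern base.
#'
#' @param ap_sub AP substring to align (single DNA string).
#' @param read_seq Read sequence (single DNA string).
#' @param ap_id Label for the AP end, carried into the result
#'   (conventionally `"front"` or `"rear"`).
#' @param strand Strand label carried into the result (`"+"` or `"-"`);
#'   callers align the reverse-complemented pattern for the minus strand.
#' @return A one-row tibble with columns `ap_id`, `strand`, `read_start`,
#'   `read_end` (0-based, half-open), `edit_distance`, `ap_sub_length`,
#'   `similarity` and `rank`, or a zero-row tibble when the read is shorter
#'   than `ap_sub`.
#' @export
#' @examples
#' best_infix_hit("ACGT", "TTACGTTT")  # exact hit at [2, 6)
best_infix_hit <- function(ap_sub, read_seq, ap_id = "front", strand = "+") {
  check_align_args(ap_sub, read_seq)
  mat <- cpp_infix_best(ap_sub, read_seq)
  hit_tibble(mat, ap_id, strand, nchar(ap_sub), "first")
}

#' Paired (true/random) infix alignments on one read
#'
#' Aligns `ap_sub` twice: the best hit on the read (the candidate true
#' alignment), then the best hit on the remainder of the read with the first
#' hit's interval excluded (the candidate random alignment).  The exclusion
#' guarantees the second hit never overlaps the first, and since the first
#' hit is the global optimum, `second$similarity <= first$similarity` always
#' holds.  The second row is absent when neither flank of the first hit is
#' long enough to contain `ap_sub`.
#'
#' @inheritParams best_infix_hit
#' @return A tibble with one or two rows; `rank` is `"first"` / `"second"`.
#' @export
paired_hits <- function(ap_sub, read_seq, ap_id = "front", strand = "+") {
  first <- best_infix_hit(ap_sub, read_seq, ap_id, strand)
  if (nrow(first) == 0L) return(first)
  mat2 <- cpp_infix_second(ap_sub, read_seq, first$read_start, first$read_end)
  second <- hit_tibble(mat2, ap_id, strand, nchar(ap_sub), "second")
  dplyr::bind_rows(first, second)
}
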