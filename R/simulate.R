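#' Simulation configuration
#'
#' Parameters of the ground-truthed read simulator.  Defaults emulate a
#' typical ONT cDNA run: a mixture of full-length, fusion (chimeric) and
#' truncated molecules, per-base errors split between substitutions,
#' insertions and deletions, and an elevated error rate within a window at
#' both read ends (the terminal quality drop of nanopore reads).
#'
#' @param n_reads Number of reads.
#' @param frac_full_length,frac_fusion,frac_truncated Category fractions,
#'   must sum to 1.  Category counts are allocated exactly by
#'   largest-remainder rounding.
#' @param error_rate Total per-base error probability (e.g. 0.14, 0.05,
#'   0.001).
#' @param error_mix Named fractions of `sub`, `ins`, `del` errors, summing
#'   to 1.
#' @param insert_length_range,polyA_length_range Uniform sampling ranges
#'   (bases).
#' @param terminal_error_multiplier Error-rate multiplier within
#'   `terminal_window` bases of either read end (>= 1; 1 disables).
#' @param terminal_window Width of the elevated-error terminal window.
#' @param q_clean Phred score assigned to unedited bases; default
#'   `round(-10 log10(error_rate))` capped to \[2, 40\].
#' @param q_error Phred score assigned to substituted/inserted bases.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1000L,
                       frac_full_length = 0.7, frac_fusion = 0.05,
                       frac_truncated = 0.25,
                       error_rate = 0.05,
                       error_mix = c(sub = 0.5, ins = 0.25, del = 0.25),
                       insert_length_range = c(300L, 2000L),
                       polyA_length_range = c(15L, 60L),
                       terminal_error_multiplier = 2,
                       terminal_window = 30L,
                       q_clean = NULL, q_error = 5L,
                       seed = 1L) {
  fr <- c(frac_full_length, frac_fusion, frac_truncated)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8) {
    stop("category fractions must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  if (length(error_mix) != 3L || any(error_mix < 0) ||
      abs(sum(error_mix) - 1) > 1e-8) {
    stop("error_mix must be three non-negative fractions summing to 1",
         call. = FALSE)
  }
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_reads >= 1, terminal_error_multiplier >= 1,
            length(insert_length_range) == 2L,
            insert_length_range[1] <= insert_length_range[2],
            insert_length_range[1] >= 20L,
            length(polyA_length_range) == 2L,
            polyA_length_range[1] <= polyA_length_range[2])
  if (is.null(q_clean)) {
    q_clean <- if (error_rate > 0) {
      max(2L, min(40L, as.integer(round(-10 * log10(error_rate)))))
    } else 40L
  }
  structure(
    list(n_reads = as.integer(n_reads),
         frac_full_length = frac_full_length, frac_fusion = frac_fusion,
         frac_truncated = frac_truncated,
         error_rate = error_rate,
         error_mix = setNames(as.numeric(error_mix), c("sub", "ins", "del")),
         insert_length_range = as.integer(insert_length_range),
         polyA_length_range = as.integer(polyA_length_range),
         terminal_error_multiplier = terminal_error_multiplier,
         terminal_window = as.integer(terminal_window),
         q_clean = as.integer(q_clean), q_error = as.integer(q_error),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n=%d  FL/fusion/truncated = %.2f/%.2f/%.2f  error=%.4g  seed=%d\n",
    x$n_reads, x$frac_full_length, x$frac_fusion, x$frac_truncated,
    x$error_rate, x$seed))
  invisible(x)
}

#' Random DNA sequence
#'
#' Uniform random DNA.  `no_a_tail` bases at the 3' end are drawn from
#' C/G/T only; the simulator uses this for insert sequences so that the
#' insert/polyA boundary is unambiguous ground truth (an insert ending in
#' an A run is indistinguishable from a longer tail).
#'
#' @param length Sequence length.
#' @param no_a_tail Number of terminal bases restricted to C/G/T.
#' @return A DNA string.
#' @export
random_dna <- function(length, no_a_tail = 0L) {
  stopifnot(length >= no_a_tail)
  body <- sample(c("A", "C", "G", "T"), length - no_a_tail, replace = TRUE)
  tail <- sample(c("C", "G", "T"), no_a_tail, replace = TRUE)
  paste(c(body, tail), collapse = "")
}

#' Build a clean (error-free) library construct
#'
#' Sense layout: front AP, insert, polyA tail, reverse complement of the
#' rear AP.  Minus-strand molecules are the reverse complement of the
#' whole construct.
#'
#' @param insert Insert DNA string.
#' @param schema An [ap_schema()].
#' @param polyA_len PolyA tail length.
#' @param strand `"+"` or `"-"`.
#' @return The construct as a DNA string.
#' @export
build_construct <- function(insert, schema, polyA_len, strand = "+") {
  s <- paste0(schema$front_ap, insert,
              strrep("A", polyA_len),
              reverse_complement(schema$rear_ap))
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Build a truncated molecule
#'
#' Emulates incomplete sequencing: the AP at the sequencing-terminating end
#' is removed entirely, together with the polyA tail and a uniformly random
#' suffix of the insert; the initiating-end AP stays intact.  For a
#' plus-strand molecule the initiating end is the front AP; for a
#' minus-strand molecule it is the rear AP.
#'
#' @inheritParams build_construct
#' @param keep Number of insert bases to keep (default: uniform in
#'   `0:nchar(insert)`).
#' @return The truncated molecule as a DNA string.
#' @export
make_truncated <- function(insert, schema, polyA_len = 30L, strand = "+",
                           keep = NULL) {
  ilen <- nchar(insert)
  if (is.null(keep)) keep <- sample(0:ilen, 1L)
  stopifnot(keep >= 0L, keep <= ilen)
  if (strand == "+") {
    paste0(schema$front_ap, substr(insert, 1L, keep))
  } else {
    frag <- paste0(substr(insert, ilen - keep + 1L, ilen),
                   strrep("A", polyA_len),
                   reverse_complement(schema$rear_ap))
    reverse_complement(frag)
  }
}

#' Build a fusion (chimeric) molecule
#'
#' Concatenation of two complete constructs, so the read carries two full
#' AP sets, two of them away from the read ends.
#'
#' @param construct_a,construct_b Clean constructs from [build_construct()].
#' @return The fusion molecule as a DNA string.
#' @export
make_fusion <- function(construct_a, construct_b) {
  paste0(construct_a, construct_b)
}

#' Corrupt sequences with a substitution/insertion/deletion error model
#'
#' Each position is edited with probability `error_rate`, multiplied by
#' `terminal_error_multiplier` within `terminal_window` bases of either
#' end.  Edits are drawn from `error_mix`: a substitution replaces the base
#' by a different one, an insertion adds a uniform base after it, a
#' deletion drops it.  Unedited bases receive quality `q_clean`;
#' substituted and inserted bases receive `q_error`, so Phred error
#' probabilities track the realised local error rate.
#'
#' @param seqs Character vector of clean sequences.
#' @param config A [sim_config()] (its `seed` is not consumed here; seed
#'   the session or use [generate_dataset()]).
#' @return A tibble with `sequence`, `quality` and `n_edits` per input.
#' @export
corrupt_reads <- function(seqs, config) {
  stopifnot(inherits(config, "sim_config"))
  qc <- intToUtf8(config$q_clean + 33L)
  qe <- intToUtf8(config$q_error + 33L)
  bases <- c("A", "C", "G", "T")
  res_seq <- character(length(seqs))
  res_qual <- character(length(seqs))
  res_n <- integer(length(seqs))
  for (r in seq_along(seqs)) {
    ch <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n == 0L || config$error_rate == 0) {
      res_seq[r] <- seqs[r]
      res_qual[r] <- strrep(qc, n)
      res_n[r] <- 0L
      next
    }
    pos <- seq_len(n)
    w <- config$terminal_window
    p <- config$error_rate *
      ifelse(pos <= w | pos > n - w, config$terminal_error_multiplier, 1)
    p <- pmin(p, 1)
    hit <- runif(n) < p
    out <- ch
    outq <- rep(qc, n)
    idx <- which(hit)
    if (length(idx)) {
      ty <- sample(c("sub", "ins", "del"), length(idx), replace = TRUE,
                   prob = config$error_mix)
      is_sub <- idx[ty == "sub"]
      if (length(is_sub)) {
        # a different base, uniformly: shift by 1..3 in base order
        cur <- match(ch[is_sub], bases)
        out[is_sub] <- bases[((cur - 1L +
                                 sample(1:3, length(is_sub), replace = TRUE)) %% 4L) + 1L]
        outq[is_sub] <- qe
      }
      is_ins <- idx[ty == "ins"]
      if (length(is_ins)) {
        out[is_ins] <- paste0(ch[is_ins],
                              sample(bases, length(is_ins), replace = TRUE))
        outq[is_ins] <- paste0(qc, qe)
      }
      is_del <- idx[ty == "del"]
      if (length(is_del)) {
        out[is_del] <- ""
        outq[is_del] <- ""
      }
    }
    res_seq[r] <- paste(out, collapse = "")
    res_qual[r] <- paste(outq, collapse = "")
    res_n[r] <- length(idx)
  }
  tibble::tibble(sequence = res_seq, quality = res_qual, n_edits = res_n)
}

# Exact category counts by largest-remainder rounding.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Generate a ground-truthed simulated dataset
#'
#' Draws inserts as uniform random DNA (their last 5 bases over C/G/T so
#' the polyA boundary is well-defined truth), builds full-length, fusion
#' and truncated molecules in exactly the configured proportions
#' (largest-remainder allocation), assigns strands Bernoulli(1/2), corrupts
#' every read under the error model, and records per-read ground truth.
#'
#' @param config A [sim_config()].
#' @param schema An [ap_schema()]; default [synthetic_schema()].
#' @return An object of class `sim_dataset`: list with `reads` (a read
#'   tibble as from [read_fastq()]), `truth` (`read_id`, `category`,
#'   `strand`, `insert_sequence`, `insert_len`, `clean_length`,
#'   `n_edits`), `config` and `schema`.
#' @export
generate_dataset <- function(config, schema = synthetic_schema()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_reads
    counts <- largest_remainder(
      n, c(config$frac_full_length, config$frac_fusion, config$frac_truncated))
    category <- sample(rep(c("full_length", "fusion", "truncated"), counts))

    ilr <- config$insert_length_range
    plr <- config$polyA_length_range
    draw_insert <- function() {
      random_dna(sample(ilr[1]:ilr[2], 1L), no_a_tail = 5L)
    }
    clean <- character(n)
    strand <- character(n)
    insert_seq <- character(n)
    insert_len <- integer(n)
    for (i in seq_len(n)) {
      st <- sample(c("+", "-"), 1L)
      pa <- sample(plr[1]:plr[2], 1L)
      if (category[i] == "full_length") {
        ins <- draw_insert()
        clean[i] <- build_construct(ins, schema, pa, st)
        insert_seq[i] <- ins
        insert_len[i] <- nchar(ins)
        strand[i] <- st
      } else if (category[i] == "truncated") {
        ins <- draw_insert()
        clean[i] <- make_truncated(ins, schema, polyA_len = pa, strand = st)
        insert_seq[i] <- ins
        insert_len[i] <- nchar(ins)
        strand[i] <- st
      } else {
        ins_a <- draw_insert()
        ins_b <- draw_insert()
        st2 <- sample(c("+", "-"), 1L)
        pa2 <- sample(plr[1]:plr[2], 1L)
        clean[i] <- make_fusion(build_construct(ins_a, schema, pa, st),
                                build_construct(ins_b, schema, pa2, st2))
        insert_seq[i] <- paste(ins_a, ins_b, sep = ",")
        insert_len[i] <- nchar(ins_a) + nchar(ins_b)
        strand[i] <- NA_character_
      }
    }
    noisy <- corrupt_reads(clean, config)
    read_id <- sprintf("sim%06d", seq_len(n))
    reads <- tibble::tibble(read_id = read_id, sequence = noisy$sequence,
                            quality = noisy$quality, comment = "")
    truth <- tibble::tibble(
      read_id = read_id, category = category, strand = strand,
      insert_sequence = insert_seq, insert_len = insert_len,
      clean_length = nchar(clean), n_edits = noisy$n_edits
    )
    structure(list(reads = reads, truth = truth, config = config,
                   schema = schema),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", nrow(x$reads), "reads\n")
  print(dplyr::count(x$truth, .data$category))
  invisible(x)
}

#' Build a grid of benchmark configurations
#'
#' Cartesian product of composition points and error rates, mirroring a
#' benchmark design with full-length fractions 50--100%, fusion fractions
#' 0--10% (truncated takes the remainder; compositions with a negative
#' remainder are dropped) and error rates 14%, 5% and 0.1%.  Each config
#' receives a distinct seed derived from `base_seed`.
#'
#' @param n_reads Reads per dataset.
#' @param full_length_fracs,fusion_fracs Composition grids.
#' @param error_rates Error-rate grid.
#' @param base_seed Seed from which per-config seeds are derived.
#' @param ... Further arguments passed to [sim_config()].
#' @return A named list of [sim_config()] objects.
#' @export
benchmark_grid <- function(n_reads = 2000L,
                           full_length_fracs = seq(0.5, 1.0, by = 0.1),
                           fusion_fracs = c(0, 0.05, 0.10),
                           error_rates = c(0.14, 0.05, 0.001),
                           base_seed = 1L, ...) {
  combos <- expand.grid(fl = full_length_fracs, fus = fusion_fracs,
                        err = error_rates, KEEP.OUT.ATTRS = FALSE)
  combos$tr <- round(1 - combos$fl - combos$fus, 10)
  combos <- combos[combos$tr >= 0, , drop = FALSE]
  seeds <- withr::with_seed(base_seed,
                            sample.int(.Machine$integer.max, nrow(combos)))
  configs <- vector("list", nrow(combos))
  names(configs) <- sprintf("fl%03.0f_fus%03.0f_err%s",
                            100 * combos$fl, 100 * combos$fus,
                            format(combos$err, trim = TRUE, scientific = FALSE))
  for (i in seq_len(nrow(combos))) {
    configs[[i]] <- sim_config(
      n_reads = n_reads,
      frac_full_length = combos$fl[i], frac_fusion = combos$fus[i],
      frac_truncated = combos$tr[i],
      error_rate = combos$err[i],
      seed = seeds[i], ...
    )
  }
  configs
}
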