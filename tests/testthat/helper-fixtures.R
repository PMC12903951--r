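# Fixtures are built in code; nothing is read from disk.

test_schema <- function() synthetic_schema()

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A clean full-length construct plus uniform qualities, as a read tibble.
clean_read <- function(schema, insert, polyA = 30L, strand = "+",
                       id = "r1", q = 30L) {
  seq <- build_construct(insert, schema, polyA, strand)
  tibble::tibble(read_id = id, sequence = seq,
                 quality = strrep(intToUtf8(q + 33L), nchar(seq)),
                 comment = "")
}

# Stringent hand-set cutoffs for constructed (error-free) fixtures.
strict_cutoffs <- function(schema, L = NULL, s_cut = 0.9, loc = 50L) {
  if (is.null(L)) L <- nchar(schema$front_ap)
  tibble::tibble(
    ap_id = c("front", "rear"),
    similarity_cutoff = s_cut,
    location_cutoff = loc,
    ap_sub_length = c(min(L, nchar(schema$front_ap)),
                      min(L, nchar(schema$rear_ap))),
    beta = 0.2,
    precision = NA_real_, recall = NA_real_, f_beta = NA_real_,
    mid_similarity_cutoff = s_cut
  )
}

# Alignment-sample tibble with random similarities/locations, for
# optimizer tests.
random_samples <- function(n, ap_ids = c("front", "rear"),
                           lengths = c(12L, 18L, 24L)) {
  tibble::tibble(
    read_id = sprintf("s%04d", seq_len(n)),
    read_length = 1000L,
    ap_id = sample(ap_ids, n, replace = TRUE),
    ap_sub_length = sample(lengths, n, replace = TRUE),
    label = sample(c("true", "random"), n, replace = TRUE, prob = c(0.6, 0.4)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    similarity = round(runif(n, 0.3, 1), 3),
    end_distance = sample(0:900, n, replace = TRUE)
  )
}
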