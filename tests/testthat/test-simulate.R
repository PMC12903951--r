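test_that("sim_config validates fractions, mixes and ranges", {
  expect_error(sim_config(frac_full_length = 0.5, frac_fusion = 0.1,
                          frac_truncated = 0.1), "sum to 1")
  expect_error(sim_config(error_mix = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(sim_config(error_rate = 1.5), "\\[0, 1\\]")
  cfg <- sim_config(error_rate = 0.05)
  expect_equal(cfg$q_clean, 13L)  # round(-10 log10(0.05))
})

test_that("constructs concatenate the expected parts", {
  schema <- test_schema()
  ins <- strrep("C", 50)
  plus <- build_construct(ins, schema, 20L, "+")
  expect_equal(nchar(plus),
               nchar(schema$front_ap) + 50L + 20L + nchar(schema$rear_ap))
  expect_equal(substr(plus, 1, nchar(schema$front_ap)), schema$front_ap)
  expect_equal(build_construct(ins, schema, 20L, "-"),
               reverse_complement(plus))
})

test_that("truncated molecules drop the terminating AP entirely", {
  schema <- test_schema()
  withr::with_seed(31, insert <- rand_dna(400))
  tr <- make_truncated(insert, schema, strand = "+", keep = 200L)
  expect_equal(substr(tr, 1, nchar(schema$front_ap)), schema$front_ap)
  expect_lt(nchar(tr), nchar(build_construct(insert, schema, 30L, "+")))
  # no 15-mer of the rear AP (as it appears on a plus read) survives
  rcr <- reverse_complement(schema$rear_ap)
  k15 <- substring(rcr, 1:(nchar(rcr) - 14), 15:nchar(rcr))
  expect_false(any(vapply(k15, grepl, logical(1), x = tr, fixed = TRUE)))
})

test_that("fusions concatenate two full constructs", {
  schema <- test_schema()
  withr::with_seed(32, {
    a <- build_construct(rand_dna(300), schema, 20L, "+")
    b <- build_construct(rand_dna(350), schema, 25L, "-")
  })
  expect_equal(nchar(make_fusion(a, b)), nchar(a) + nchar(b))
  expect_equal(make_fusion(a, b), paste0(a, b))
})

test_that("corrupt_reads: zero noise is the identity", {
  cfg <- sim_config(error_rate = 0, seed = 1)
  withr::with_seed(33, seqs <- replicate(5, rand_dna(200)))
  out <- corrupt_reads(seqs, cfg)
  expect_equal(out$sequence, seqs)
  expect_equal(out$n_edits, rep(0L, 5))
  expect_equal(nchar(out$quality), nchar(seqs))
})

test_that("realized edit rate concentrates on the configured rate", {
  cfg <- sim_config(error_rate = 0.05, terminal_error_multiplier = 1,
                    seed = 1)
  withr::with_seed(34, seqs <- replicate(100, rand_dna(1000)))
  out <- withr::with_seed(35, corrupt_reads(seqs, cfg))
  n_bases <- sum(nchar(seqs))
  rate <- sum(out$n_edits) / n_bases
  se <- sqrt(0.05 * 0.95 / n_bases)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("the terminal window sees elevated error rates", {
  cfg <- sim_config(error_rate = 0.10, terminal_error_multiplier = 2,
                    terminal_window = 30L, error_mix = c(1, 0, 0), seed = 1)
  withr::with_seed(36, seqs <- replicate(300, rand_dna(500)))
  out <- withr::with_seed(37, corrupt_reads(seqs, cfg))
  # substitutions only: positions align, so mismatch profile is measurable
  mm <- function(pos) {
    mean(vapply(seq_along(seqs), function(i) {
      substr(out$sequence[i], pos, pos) != substr(seqs[i], pos, pos)
    }, logical(1)))
  }
  head_rate <- mean(vapply(1:30, mm, numeric(1)))
  body_rate <- mean(vapply(201:230, mm, numeric(1)))
  # substitution to a different base, so realised mismatch ~ error prob
  expect_gt(head_rate, body_rate * 1.4)
})

test_that("corruption and dataset generation are deterministic", {
  cfg <- sim_config(n_reads = 60, error_rate = 0.1, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("category counts follow largest-remainder allocation exactly", {
  cfg <- sim_config(n_reads = 1000L, frac_full_length = 0.5,
                    frac_fusion = 0.1, frac_truncated = 0.4,
                    error_rate = 0.001, seed = 4)
  ds <- generate_dataset(cfg)
  counts <- table(ds$truth$category)
  expect_equal(unname(counts[c("full_length", "fusion", "truncated")]),
               c(500L, 100L, 400L), ignore_attr = TRUE)
  # non-integer expectations: 7/3 categories over 10 reads
  cfg2 <- sim_config(n_reads = 10L, frac_full_length = 0.74,
                     frac_fusion = 0, frac_truncated = 0.26,
                     error_rate = 0, seed = 4)
  ds2 <- generate_dataset(cfg2)
  expect_equal(sum(ds2$truth$category == "full_length"), 7L)
  cfg3 <- sim_config(n_reads = 100L, frac_full_length = 1, frac_fusion = 0,
                     frac_truncated = 0, error_rate = 0, seed = 4)
  expect_true(all(generate_dataset(cfg3)$truth$category == "full_length"))
})

test_that("one truth row per read, consistent with the reads table", {
  cfg <- sim_config(n_reads = 80, error_rate = 0.05, seed = 6)
  ds <- generate_dataset(cfg)
  expect_equal(ds$truth$read_id, ds$reads$read_id)
  expect_equal(anyDuplicated(ds$truth$read_id), 0L)
  # truncated molecules are shorter than their clean full construct
  expect_true(all(nchar(ds$reads$sequence) > 0))
})

test_that("simulated inserts avoid terminal A bases (boundary identifiability)", {
  cfg <- sim_config(n_reads = 50, frac_full_length = 1, frac_fusion = 0,
                    frac_truncated = 0, error_rate = 0, seed = 14)
  ds <- generate_dataset(cfg)
  last5 <- substr(ds$truth$insert_sequence,
                  ds$truth$insert_len - 4L, ds$truth$insert_len)
  expect_false(any(grepl("A", last5, fixed = TRUE)))
})

test_that("the default benchmark grid enumerates 48 valid configurations", {
  grid <- benchmark_grid(n_reads = 100L, base_seed = 3)
  expect_length(grid, 48L)
  fr <- vapply(grid, function(g) {
    g$frac_full_length + g$frac_fusion + g$frac_truncated
  }, numeric(1))
  expect_true(all(abs(fr - 1) < 1e-8))
  expect_true(all(vapply(grid, function(g) g$frac_truncated >= -1e-12,
                         logical(1))))
  seeds <- vapply(grid, function(g) g$seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  # derived deterministically from the base seed
  grid2 <- benchmark_grid(n_reads = 100L, base_seed = 3)
  expect_identical(vapply(grid2, function(g) g$seed, integer(1)), seeds)
})

test_that("zero-noise datasets round-trip through preprocessing", {
  schema <- test_schema()
  cfg <- sim_config(n_reads = 100, frac_full_length = 1, frac_fusion = 0,
                    frac_truncated = 0, error_rate = 0, seed = 44)
  ds <- generate_dataset(cfg, schema)
  res <- preprocess(ds$reads, schema, min_q = 0, seed = 44)
  expect_equal(nrow(res$full_length), 100L)
  m <- match(res$full_length$read_id, ds$truth$read_id)
  expect_equal(res$full_length$sequence, ds$truth$insert_sequence[m])
})
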