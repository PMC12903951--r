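test_that("f_beta arithmetic, ordering and limits", {
  expect_equal(f_beta(1, 1, 0.5), 1)
  expect_equal(f_beta(0.5, 1, 1), 2 / 3)
  expect_equal(f_beta(0.7, 0.7, 1), 0.7)      # F1(P, P) == P
  expect_equal(f_beta(0, 0, 1), 0)            # empty-denominator convention
  # low beta emphasises precision
  expect_gt(f_beta(0.9, 0.5, 0.1), f_beta(0.5, 0.9, 0.1))
  # limits: beta -> 0 gives P, beta -> Inf gives R
  expect_equal(f_beta(0.82, 0.37, 1e-3), 0.82, tolerance = 1e-4)
  expect_equal(f_beta(0.82, 0.37, 1e3), 0.37, tolerance = 1e-4)
  expect_error(f_beta(0.5, 0.5, 0), "> 0")
})

test_that("sample_alignments honours the counting contract on clean reads", {
  schema <- test_schema()
  withr::with_seed(2, {
    reads <- dplyr::bind_rows(lapply(1:10, function(i) {
      clean_read(schema, rand_dna(300), id = sprintf("r%02d", i))
    }))
  })
  s <- sample_alignments(reads, schema, length_grid = 20L, seed = 1)
  front <- s[s$ap_id == "front", ]
  expect_equal(sum(front$label == "true"), 10L)
  expect_lte(sum(front$label == "random"), 10L)
  # exact embedding: every true sample aligns perfectly
  expect_true(all(s$similarity[s$label == "true"] == 1))
  # per (read, ap, L): exactly one true, at most one random sample
  counts <- dplyr::count(s, .data$read_id, .data$ap_id,
                         .data$ap_sub_length, .data$label)
  expect_true(all(counts$n == 1L))
})

test_that("sampling is deterministic under a fixed seed", {
  schema <- test_schema()
  withr::with_seed(8, {
    reads <- dplyr::bind_rows(lapply(1:30, function(i) {
      clean_read(schema, rand_dna(sample(200:400, 1)),
                 id = sprintf("r%02d", i))
    }))
  })
  a <- sample_alignments(reads, schema, sample_size = 12L, seed = 77)
  b <- sample_alignments(reads, schema, sample_size = 12L, seed = 77)
  expect_identical(a, b)
  expect_error(sample_alignments(reads[0, ], schema), "no reads")
})

test_that("evaluate_cutoff counts pass/fail as specified", {
  samples <- tibble::tibble(
    label = c(rep("true", 10), rep("random", 4)),
    similarity = c(rep(0.9, 8), 0.6, 0.6, 0.9, 0.9, 0.3, 0.3),
    end_distance = c(rep(5, 10), 5, 5, 500, 500)
  )
  # 8 true pass, 2 random pass, 2 true fail
  ev <- evaluate_cutoff(samples, 0.8, 50)
  expect_equal(ev$precision, 0.8)
  expect_equal(ev$recall, 0.8)
  # separable: all true pass, all random fail
  ev <- evaluate_cutoff(samples[c(1:8, 13:14), ], 0.8, 50)
  expect_equal(c(ev$precision, ev$recall), c(1, 1))
  # reject everything: R = 0, P = 1 by convention
  ev <- evaluate_cutoff(samples, 1.01, 0)
  expect_equal(c(ev$precision, ev$recall), c(1, 0))
})

test_that("perfectly separable samples give F = 1 and stringent cutoffs", {
  samples <- tibble::tibble(
    read_id = sprintf("r%02d", 1:40), read_length = 1000L,
    ap_id = "front", ap_sub_length = rep(c(14L, 20L), each = 20),
    label = rep(c("true", "random"), 20),
    strand = "+",
    similarity = rep(c(0.9, 0.4), 20),
    end_distance = rep(c(30L, 480L), 20)
  )
  tun <- optimize_cutoffs(samples, beta = 0.5)
  co <- tun$cutoffs
  expect_equal(co$f_beta, 1)
  expect_equal(co$precision, 1)
  expect_equal(co$recall, 1)
  # stringent optimum: highest similarity cutoff that keeps all trues,
  # smallest location window, and the larger L among ties
  expect_equal(co$similarity_cutoff, 0.9)
  expect_equal(co$location_cutoff, 30L)
  expect_equal(co$ap_sub_length, 20L)
})

test_that("the substring length that separates better is selected", {
  # L = 24 separates perfectly; L = 12 has random similarity overlapping true
  samples <- dplyr::bind_rows(
    tibble::tibble(read_id = sprintf("a%02d", 1:30), read_length = 1000L,
                   ap_id = "front", ap_sub_length = 24L,
                   label = rep(c("true", "random"), 15), strand = "+",
                   similarity = rep(c(0.92, 0.5), 15),
                   end_distance = rep(c(10L, 20L), 15)),
    tibble::tibble(read_id = sprintf("b%02d", 1:30), read_length = 1000L,
                   ap_id = "front", ap_sub_length = 12L,
                   label = rep(c("true", "random"), 15), strand = "+",
                   similarity = rep(c(0.92, 0.92), 15),
                   end_distance = rep(c(10L, 20L), 15))
  )
  tun <- optimize_cutoffs(samples, beta = 0.2)
  expect_equal(tun$cutoffs$ap_sub_length, 24L)
  expect_equal(tun$cutoffs$f_beta, 1)
})

test_that("optimizer equals the exhaustive plain-loop oracle", {
  for (seed in c(31, 32)) {
    withr::with_seed(seed, samples <- random_samples(160))
    for (beta in c(0.2, 1)) {
      got <- tidy(optimize_cutoffs(samples, beta = beta))
      want <- oracle_optimize(samples, beta = beta)
      want <- want[match(got$ap_id, want$ap_id), ]
      expect_equal(got$similarity_cutoff, want$similarity_cutoff,
                   info = paste(seed, beta))
      expect_equal(got$location_cutoff, as.integer(want$location_cutoff))
      expect_equal(got$ap_sub_length, want$ap_sub_length)
      expect_equal(got$f_beta, want$f_beta, tolerance = 1e-12)
      expect_equal(got$precision, want$precision, tolerance = 1e-12)
      expect_equal(got$recall, want$recall, tolerance = 1e-12)
    }
  }
})

test_that("smaller beta never decreases achieved precision", {
  for (seed in c(51, 52, 53)) {
    withr::with_seed(seed, samples <- random_samples(200))
    betas <- c(0.1, 0.5, 1, 2)
    prec <- vapply(betas, function(b) {
      mean(tidy(optimize_cutoffs(samples, beta = b))$precision)
    }, numeric(1))
    expect_true(all(diff(prec) <= 1e-12),
                info = paste("seed", seed, ":", paste(round(prec, 4),
                                                      collapse = " ")))
  }
})

test_that("location cutoff is more stable across beta than similarity (diagnostic)", {
  schema <- test_schema()
  cfg <- sim_config(n_reads = 150, frac_full_length = 0.8, frac_fusion = 0.05,
                    frac_truncated = 0.15, error_rate = 0.05, seed = 24)
  ds <- generate_dataset(cfg, schema)
  samples <- sample_alignments(ds$reads, schema, seed = 24)
  grid <- purrr::map_dfr(c(0.1, 0.5, 1, 2), function(b) {
    tidy(optimize_cutoffs(samples, beta = b))
  })
  spread <- grid |>
    dplyr::group_by(.data$ap_id) |>
    dplyr::summarise(
      loc_spread = diff(range(.data$location_cutoff)) / 200,
      sim_spread = diff(range(.data$similarity_cutoff)) / 0.5,
      .groups = "drop")
  # informational only: the trend mirrors the expected behaviour but is not
  # a hard guarantee of the optimizer
  testthat::expect_true(is.finite(sum(spread$loc_spread, spread$sim_spread)))
  if (all(spread$loc_spread <= spread$sim_spread)) succeed()
})

test_that("tuning result methods expose cutoffs, summary and plot", {
  withr::with_seed(41, samples <- random_samples(120))
  tun <- optimize_cutoffs(samples, beta = 0.2)
  td <- tidy(tun)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$ap_id, c("front", "rear"))
  expect_true(all(c("similarity_cutoff", "location_cutoff", "ap_sub_length",
                    "mid_similarity_cutoff") %in% names(td)))
  gl <- glance(tun)
  expect_equal(gl$n_samples, 120L)
  expect_s3_class(autoplot(tun), "ggplot")
})
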