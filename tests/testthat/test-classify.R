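test_that("clean constructs classify as full-length with perfect end hits", {
  schema <- test_schema()
  withr::with_seed(12, insert <- rand_dna(400))
  reads <- dplyr::bind_rows(
    clean_read(schema, insert, strand = "+", id = "plus"),
    clean_read(schema, insert, strand = "-", id = "minus")
  )
  cut <- strict_cutoffs(schema)
  cls <- classify_reads(reads, schema, cut)
  expect_equal(cls$label, c("full_length", "full_length"))
  expect_equal(cls$strand, c("+", "-"))
  expect_equal(cls$front_similarity, c(1, 1))
  expect_equal(cls$rear_similarity, c(1, 1))
  expect_equal(cls$n_mid_hits, c(0L, 0L))
})

test_that("a single accepted end hit yields truncated with its strand", {
  schema <- test_schema()
  withr::with_seed(13, insert <- rand_dna(300))
  trunc_p <- make_truncated(insert, schema, strand = "+", keep = 150L)
  trunc_m <- make_truncated(insert, schema, strand = "-", keep = 150L)
  reads <- tibble::tibble(
    read_id = c("tp", "tm"),
    sequence = c(trunc_p, trunc_m),
    quality = strrep("I", nchar(c(trunc_p, trunc_m))),
    comment = ""
  )
  cls <- classify_reads(reads, schema, strict_cutoffs(schema))
  expect_equal(cls$label, c("truncated", "truncated"))
  expect_equal(cls$strand, c("+", "-"))
})

test_that("fusions are chimeric via similarity-passing, location-failing hits", {
  schema <- test_schema()
  withr::with_seed(14, {
    ins <- replicate(8, rand_dna(350))
  })
  strands <- expand.grid(a = c("+", "-"), b = c("+", "-"),
                         stringsAsFactors = FALSE)
  reads <- purrr::map_dfr(seq_len(nrow(strands)), function(i) {
    fus <- make_fusion(
      build_construct(ins[2 * i - 1], schema, 30L, strands$a[i]),
      build_construct(ins[2 * i], schema, 25L, strands$b[i])
    )
    tibble::tibble(read_id = sprintf("f_%s%s", strands$a[i], strands$b[i]),
                   sequence = fus, quality = strrep("I", nchar(fus)),
                   comment = "")
  })
  cut <- strict_cutoffs(schema)
  cls <- classify_reads(reads, schema, cut)
  expect_equal(cls$label, rep("chimeric", 4))
  expect_true(all(cls$n_mid_hits >= 1L))
  # the evidence is a hit passing similarity but failing location
  hits <- locate_aps(reads, schema, cut)
  mids <- hits[hits$mid, ]
  expect_setequal(unique(mids$read_id), reads$read_id)
  expect_true(all(mids$similarity >= cut$similarity_cutoff[1]))
  expect_true(all(mids$end_distance > cut$location_cutoff[1]))
})

test_that("chimeric takes precedence over full-length", {
  schema <- test_schema()
  withr::with_seed(15, {
    a <- build_construct(rand_dna(400), schema, 30L, "+")
    b <- build_construct(rand_dna(350), schema, 30L, "+")
  })
  reads <- tibble::tibble(read_id = "fus", sequence = paste0(a, b),
                          quality = strrep("I", nchar(a) + nchar(b)),
                          comment = "")
  cls <- classify_reads(reads, schema, strict_cutoffs(schema))
  # both end hits exist, but the mid evidence wins
  expect_equal(cls$label, "chimeric")
})

test_that("random insert-only reads produce no accepted hits", {
  schema <- test_schema()
  withr::with_seed(16, {
    reads <- tibble::tibble(
      read_id = sprintf("n%04d", 1:1000),
      sequence = vapply(1:1000, function(i) rand_dna(600), character(1)),
      quality = strrep("I", 600),
      comment = ""
    )
  })
  cut <- strict_cutoffs(schema, L = 20L, s_cut = 0.9, loc = 50L)
  cls <- classify_reads(reads, schema, cut)
  expect_true(all(cls$label == "truncated"))
  expect_true(all(is.na(cls$front_similarity)))
  expect_true(all(cls$n_mid_hits == 0L))
})

test_that("trimming inverts the construct exactly on both strands", {
  schema <- test_schema()
  withr::with_seed(17, insert <- paste0(rand_dna(395), "CGTGC"))
  for (strand in c("+", "-")) {
    reads <- clean_read(schema, insert, polyA = 30L, strand = strand)
    cls <- classify_reads(reads, schema, strict_cutoffs(schema))
    tr <- trim_reads(reads, cls, schema)
    expect_equal(tr$sequence, insert, info = strand)
    expect_equal(nchar(tr$quality), nchar(insert))
    expect_equal(tr$comment, paste0("strand=", strand))
  }
})

test_that("interrupted polyA tails are trimmed through isolated non-A bases", {
  schema <- test_schema()
  withr::with_seed(18, insert <- paste0(rand_dna(295), "CGTGC"))
  # tail A^10 G A^10: the stated rule consumes the lone G (flanked by >= 4
  # A's insert-ward) and both runs, leaving the insert intact
  seq <- paste0(schema$front_ap, insert, strrep("A", 10), "G",
                strrep("A", 10), reverse_complement(schema$rear_ap))
  reads <- tibble::tibble(read_id = "p", sequence = seq,
                          quality = strrep("I", nchar(seq)), comment = "")
  cls <- classify_reads(reads, schema, strict_cutoffs(schema))
  tr <- trim_reads(reads, cls, schema)
  expect_equal(tr$sequence, insert)
})

test_that("short or absent tails: no trimming without four adjacent A's", {
  schema <- test_schema()
  withr::with_seed(19, insert <- paste0(rand_dna(200), "CGTGC"))
  # only 3 A's adjacent to the rear AP: below the minimum, kept
  seq <- paste0(schema$front_ap, insert, "AAA",
                reverse_complement(schema$rear_ap))
  reads <- tibble::tibble(read_id = "s", sequence = seq,
                          quality = strrep("I", nchar(seq)), comment = "")
  cls <- classify_reads(reads, schema, strict_cutoffs(schema))
  tr <- trim_reads(reads, cls, schema)
  expect_equal(tr$sequence, paste0(insert, "AAA"))
})

test_that("trim_reads rejects classifications for unknown reads", {
  schema <- test_schema()
  reads <- clean_read(schema, strrep("C", 100))
  cls <- classify_reads(reads, schema, strict_cutoffs(schema))
  cls$read_id <- "other"
  expect_error(trim_reads(reads, cls, schema), "not present")
})

test_that("classification is strand-symmetric", {
  schema <- test_schema()
  cfg <- sim_config(n_reads = 30, frac_full_length = 1, frac_fusion = 0,
                    frac_truncated = 0, error_rate = 0, seed = 21)
  ds <- generate_dataset(cfg, schema)
  cut <- strict_cutoffs(schema)
  cls <- classify_reads(ds$reads, schema, cut)
  flipped <- reverse_complement(ds$reads)
  cls2 <- classify_reads(flipped, schema, cut)
  expect_equal(cls2$label, cls$label)
  expect_equal(cls2$strand, chartr("+-", "-+", cls$strand))
  expect_equal(trim_reads(flipped, cls2, schema)$sequence,
               trim_reads(ds$reads, cls, schema)$sequence)
})

test_that("preprocess partitions every read exactly once and filters last", {
  schema <- test_schema()
  cfg <- sim_config(n_reads = 200, frac_full_length = 0.6, frac_fusion = 0.1,
                    frac_truncated = 0.3, error_rate = 0.05, seed = 22)
  ds <- generate_dataset(cfg, schema)
  res <- preprocess(ds$reads, schema, min_q = 0, seed = 22)
  counts <- glance(res)
  expect_equal(counts$full_length + counts$truncated + counts$chimeric +
                 counts$failed_quality, 200L)
  ids <- c(res$full_length$read_id, res$truncated$read_id,
           res$chimeric$read_id, res$failed_quality$read_id)
  expect_setequal(ids, ds$reads$read_id)
  expect_equal(anyDuplicated(ids), 0L)
  cls <- tidy(res)
  expect_setequal(unique(cls$label),
                  intersect(c("full_length", "truncated", "chimeric"),
                            cls$label))
  # trim containment: outputs are contiguous subsequences of oriented input
  m <- match(res$full_length$read_id, ds$reads$read_id)
  ori <- ifelse(cls$strand[match(res$full_length$read_id, cls$read_id)] == "-",
                reverse_complement(ds$reads$sequence[m]),
                ds$reads$sequence[m])
  expect_true(all(mapply(grepl, res$full_length$sequence, ori, fixed = TRUE)))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("the quality filter runs after trimming and routes failures", {
  schema <- test_schema()
  withr::with_seed(23, insert <- paste0(rand_dna(195), "CGTGC"))
  good <- clean_read(schema, insert, id = "good", q = 30L)
  poor <- clean_read(schema, insert, id = "poor", q = 5L)
  reads <- dplyr::bind_rows(good, poor)
  res <- preprocess(reads, schema, cutoffs = strict_cutoffs(schema),
                    min_q = 7)
  expect_equal(res$full_length$read_id, "good")
  expect_equal(res$failed_quality$read_id, "poor")
  # the failed read is still trimmed and oriented
  expect_equal(res$failed_quality$sequence, insert)
  cls <- tidy(res)
  expect_equal(cls$passes_quality[cls$read_id == "poor"], FALSE)
  expect_equal(cls$mean_q[cls$read_id == "good"], 30, tolerance = 1e-9)
})
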