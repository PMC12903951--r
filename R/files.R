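resolve_schema <- function(schema = NULL, kit = NULL, front = NULL,
                           rear = NULL) {
  given <- c(!is.null(schema), !is.null(kit),
             !is.null(front) || !is.null(rear))
  if (sum(given) != 1L) {
    stop("provide exactly one of: a schema object, a kit preset, ",
         "or a front/rear AP pair", call. = FALSE)
  }
  if (!is.null(schema)) {
    stopifnot(inherits(schema, "ap_schema"))
    return(schema)
  }
  if (!is.null(kit)) return(kit_schema(kit))
  if (is.null(front) || is.null(rear)) {
    stop("both --front and --rear AP sequences are required", call. = FALSE)
  }
  ap_schema(front, rear)
}

#' Reservoir-sample reads from a FASTQ file
#'
#' Single streaming pass; memory is bounded by `sample_size` regardless of
#' file size.  Deterministic under `seed`.
#'
#' @inheritParams read_fastq
#' @param sample_size Reservoir capacity.
#' @param seed Integer seed.
#' @return A read tibble with at most `sample_size` rows, in file order.
#' @export
sample_fastq <- function(path, sample_size = 5000L, seed = 1136L) {
  reader <- fastq_reader(path)
  withr::with_seed(seed, {
    reservoir <- NULL
    n_seen <- 0L
    repeat {
      chunk <- reader()
      if (is.null(chunk)) break
      for (i in seq_len(nrow(chunk))) {
        n_seen <- n_seen + 1L
        if (n_seen <= sample_size) {
          reservoir <- dplyr::bind_rows(reservoir, chunk[i, ])
        } else {
          j <- sample.int(n_seen, 1L)
          if (j <= sample_size) reservoir[j, ] <- chunk[i, ]
        }
      }
    }
    if (is.null(reservoir)) stop("no reads to tune on", call. = FALSE)
    reservoir
  })
}

log_line <- function(verbose, stage, ...) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("[%s] nanosift %s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  paste0(...)))
}

#' Preprocess a FASTQ file end to end
#'
#' The file-level pipeline: tune cutoffs on a reservoir sample of the input
#' (unless pre-tuned cutoffs are supplied), then stream the file in bounded
#' chunks through classification, reorientation, trimming and quality
#' filtering, writing one FASTQ per category plus a per-read classification
#' table and the tuning report.
#'
#' @param input Path to FASTQ or FASTQ.gz.
#' @param out_prefix Output path prefix; writes
#'   `<prefix>.full_length.fastq.gz`, `<prefix>.truncated.fastq.gz`,
#'   `<prefix>.chimeric.fastq.gz`, `<prefix>.failed_quality.fastq.gz`,
#'   `<prefix>.classification.tsv`, `<prefix>.report.json` and
#'   `<prefix>.report.html`.
#' @param schema,kit,front,rear Exactly one way of specifying the AP pair.
#' @param cutoffs Optional pre-tuned cutoffs (an `ap_tuning`, a cutoff
#'   tibble, or a path readable by [read_cutoffs()]); skips tuning.
#' @param beta,min_q,sample_size,seed See [preprocess()].
#' @param chunk_size Reads per streamed chunk.
#' @param verbose Log progress to standard error.
#' @return Invisibly, a list with `counts`, `cutoffs` and the output paths.
#' @export
preprocess_fastq <- function(input, out_prefix, schema = NULL, kit = NULL,
                             front = NULL, rear = NULL, cutoffs = NULL,
                             beta = 0.2, min_q = 7, sample_size = 5000L,
                             seed = 1136L, chunk_size = 10000L,
                             verbose = TRUE) {
  schema <- resolve_schema(schema, kit, front, rear)
  if (!file.exists(input)) stop("input file not found: ", input, call. = FALSE)

  tuning <- NULL
  if (is.null(cutoffs)) {
    log_line(verbose, "tune", "sampling up to ", sample_size, " reads")
    sample <- sample_fastq(input, sample_size = sample_size, seed = seed)
    tuning <- tune_cutoffs(sample, schema, beta = beta,
                           sample_size = sample_size, seed = seed)
    cut_tab <- tuning$cutoffs
  } else {
    if (is.character(cutoffs)) cutoffs <- read_cutoffs(cutoffs)
    cut_tab <- as_cutoffs(cutoffs)
    if (inherits(cutoffs, "ap_tuning")) tuning <- cutoffs
  }
  for (i in seq_len(nrow(cut_tab))) {
    log_line(verbose, "tune",
             sprintf("%s AP: similarity >= %.2f, end distance <= %d, L = %d",
                     cut_tab$ap_id[i], cut_tab$similarity_cutoff[i],
                     as.integer(cut_tab$location_cutoff[i]),
                     as.integer(cut_tab$ap_sub_length[i])))
  }

  categories <- c("full_length", "truncated", "chimeric", "failed_quality")
  paths <- setNames(paste0(out_prefix, ".", categories, ".fastq.gz"),
                    categories)
  cons <- lapply(paths, function(p) gzfile(p, open = "wt"))
  on.exit(lapply(cons, close), add = TRUE)

  reader <- fastq_reader(input, chunk_size = chunk_size)
  cls_rows <- list()
  counts <- setNames(rep(0L, 4L), categories)
  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    res <- preprocess(chunk, schema, cutoffs = cut_tab, min_q = min_q)
    for (cat in categories) {
      part <- res[[cat]]
      counts[[cat]] <- counts[[cat]] + nrow(part)
      if (nrow(part)) writeLines(fastq_lines(part), cons[[cat]])
    }
    cls_rows[[length(cls_rows) + 1L]] <- res$classification
  }
  classification <- dplyr::bind_rows(cls_rows)
  cls_path <- paste0(out_prefix, ".classification.tsv")
  readr::write_tsv(classification, cls_path)
  log_line(verbose, "classify",
           paste(sprintf("%s=%d", categories, counts[categories]),
                 collapse = " "))

  report_paths <- NULL
  if (!is.null(tuning)) {
    report_paths <- paste0(out_prefix, c(".report.json", ".report.html"))
    write_report(tuning, counts = as.list(counts),
                 path_json = report_paths[1], path_html = report_paths[2])
    log_line(verbose, "report", "wrote ", report_paths[1])
  }
  log_line(verbose, "done", "total reads = ", sum(counts))
  invisible(list(counts = counts, cutoffs = cut_tab,
                 classification = cls_path,
                 outputs = paths, report = report_paths))
}

fastq_lines <- function(reads) {
  n <- nrow(reads)
  comment <- if ("comment" %in% names(reads)) reads$comment else rep("", n)
  comment[is.na(comment)] <- ""
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <-
    paste0("@", reads$read_id, ifelse(comment == "", "",
                                      paste0(" ", comment)))
  lines[seq(2L, by = 4L, length.out = n)] <- reads$sequence
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- reads$quality
  lines
}

#' Save tuned cutoffs to a YAML file
#'
#' @param cutoffs An `ap_tuning` object or cutoff tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  tab <- as_cutoffs(cutoffs)
  yaml::write_yaml(
    lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ])), path,
    precision = 12L)
  invisible(path)
}

#' Load tuned cutoffs from a YAML file
#'
#' @param path Path written by [write_cutoffs()].
#' @return A cutoff tibble usable wherever tuned cutoffs are accepted.
#' @export
read_cutoffs <- function(path) {
  rows <- yaml::read_yaml(path)
  as_cutoffs(dplyr::bind_rows(lapply(rows, tibble::as_tibble)))
}
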