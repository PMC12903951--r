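#' Read a FASTQ file into a tibble
#'
#' Reads plain or gzip-compressed FASTQ (compression is detected from the
#' file's magic bytes, not its name).  Qualities must be Phred+33, the only
#' encoding emitted by current nanopore basecallers; no attempt is made to
#' guess other encodings.  Sequences are uppercased on input and restricted
#' to the alphabet A/C/G/T/N.
#'
#' Internally the file is consumed in bounded chunks, so arbitrarily large
#' files can be processed through [fastq_reader()] without holding all reads
#' in memory; `read_fastq()` itself materialises the full tibble and is meant
#' for datasets that fit comfortably in RAM.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param n_max Maximum number of records to read (default all).
#' @return A tibble with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 string) and `comment` (text after the first whitespace on the
#'   header line, `""` if absent).
#' @seealso [write_fastq()], [fastq_reader()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' read_fastq(f)
read_fastq <- function(path, n_max = Inf) {
  reader <- fastq_reader(path, chunk_size = 65536L)
  chunks <- list()
  total <- 0
  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    total <- total + nrow(chunk)
    chunks[[length(chunks) + 1L]] <- chunk
    if (total >= n_max) break
  }
  out <- dplyr::bind_rows(chunks)
  if (nrow(out) == 0) {
    out <- tibble::tibble(read_id = character(), sequence = character(),
                          quality = character(), comment = character())
  }
  if (is.finite(n_max) && nrow(out) > n_max) out <- out[seq_len(n_max), ]
  out
}

#' Create a chunked FASTQ reader
#'
#' Returns a closure that yields successive tibbles of at most `chunk_size`
#' records and `NULL` at end of file.  Memory use is bounded by the chunk
#' size regardless of file size; this is the streaming entry point used by
#' [preprocess_fastq()].
#'
#' @inheritParams read_fastq
#' @param chunk_size Records per chunk.
#' @return A function of no arguments returning a tibble (as in
#'   [read_fastq()]) or `NULL` when the file is exhausted.
#' @export
fastq_reader <- function(path, chunk_size = 10000L) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path, call. = FALSE)
  }
  # gzfile() reads both gzip and plain text; record compression explicitly so
  # intent is visible and mis-detected binary files fail early.
  magic <- readBin(path, "raw", n = 2L)
  gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  con <- gzfile(path, open = "rt")
  record_index <- 0L
  done <- FALSE
  force(gz)
  fail <- function(...) {
    done <<- TRUE
    try(close(con), silent = TRUE)
    stop(..., call. = FALSE)
  }
  function() {
    if (done) return(NULL)
    lines <- readLines(con, n = 4L * chunk_size, warn = FALSE)
    if (length(lines) == 0L) {
      done <<- TRUE
      close(con)
      return(NULL)
    }
    if (length(lines) %% 4L != 0L) {
      fail("malformed FASTQ record ", record_index + length(lines) %/% 4L + 1L,
           " in ", path, ": truncated record")
    }
    n <- length(lines) %/% 4L
    hdr <- lines[seq(1L, by = 4L, length.out = n)]
    seq <- lines[seq(2L, by = 4L, length.out = n)]
    plus <- lines[seq(3L, by = 4L, length.out = n)]
    qual <- lines[seq(4L, by = 4L, length.out = n)]
    idx <- record_index + seq_len(n)

    bad <- which(!startsWith(hdr, "@"))
    if (length(bad)) {
      fail("malformed FASTQ record ", idx[bad[1]], " in ", path,
           ": header does not start with '@'")
    }
    bad <- which(!startsWith(plus, "+"))
    if (length(bad)) {
      fail("malformed FASTQ record ", idx[bad[1]], " in ", path,
           ": separator line does not start with '+'")
    }
    bad <- which(nchar(seq) != nchar(qual))
    if (length(bad)) {
      fail("malformed FASTQ record ", idx[bad[1]], " in ", path,
           ": sequence and quality lengths differ")
    }
    seq <- toupper(seq)
    bad <- which(grepl("[^ACGTN]", seq))
    if (length(bad)) {
      fail("malformed FASTQ record ", idx[bad[1]], " in ", path,
           ": sequence contains characters outside A/C/G/T/N")
    }
    bad <- which(grepl("[^\\x21-\\x7e]", qual, perl = TRUE))
    if (length(bad)) {
      fail("malformed FASTQ record ", idx[bad[1]], " in ", path,
           ": quality contains non-printable characters (Phred+33 required)")
    }
    record_index <<- record_index + n
    hdr <- substring(hdr, 2L)
    sp <- regexpr("\\s", hdr)
    read_id <- ifelse(sp > 0L, substr(hdr, 1L, sp - 1L), hdr)
    comment <- ifelse(sp > 0L, substring(hdr, sp + 1L), "")
    tibble::tibble(read_id = read_id, sequence = seq,
                   quality = qual, comment = comment)
  }
}

#' Write reads to a FASTQ file
#'
#' Writes Phred+33 FASTQ; output is gzip-compressed when `path` ends in
#' `.gz`.  Round-trips through [read_fastq()] are identities on
#' (`read_id`, `sequence`, `quality`, `comment`).
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality` and
#'   optionally `comment`.
#' @param path Output path.
#' @return The number of records written, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  gz <- grepl("\\.gz$", path)
  con <- if (gz) gzfile(path, open = "wt") else file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  n <- nrow(reads)
  if (n > 0) {
    comment <- if ("comment" %in% names(reads)) reads$comment else rep("", n)
    comment[is.na(comment)] <- ""
    hdr <- paste0("@", reads$read_id,
                  ifelse(comment == "", "", paste0(" ", comment)))
    lines <- character(4L * n)
    lines[seq(1L, by = 4L, length.out = n)] <- hdr
    lines[seq(2L, by = 4L, length.out = n)] <- reads$sequence
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- reads$quality
    writeLines(lines, con)
  }
  invisible(n)
}

#' Reverse-complement sequences or reads
#'
#' For a character vector, returns the reverse complement (A<->T, C<->G,
#' N<->N).  For a read tibble, reverse-complements `sequence` and reverses
#' `quality` in lockstep.  An involution: applying it twice is the identity.
#'
#' @param x Character vector of DNA strings, or a tibble as returned by
#'   [read_fastq()].
#' @return Same type as `x`.
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.character <- function(x) as.character(cpp_revcomp(x))

#' @export
reverse_complement.data.frame <- function(x) {
  stopifnot(all(c("sequence", "quality") %in% names(x)))
  x$sequence <- as.character(cpp_revcomp(x$sequence))
  x$quality <- as.character(cpp_strrev(x$quality))
  x
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return A list of integer vectors, one per string.
#' @export
phred_to_int <- function(quality) {
  lapply(quality, function(q) {
    if (is.na(q) || nchar(q) == 0L) return(integer())
    utf8ToInt(q) - 33L
  })
}

#' Encode integer Phred scores as Phred+33 strings
#'
#' @param scores A list of integer vectors (or a single integer vector).
#' @return Character vector of quality strings.
#' @export
int_to_phred <- function(scores) {
  if (is.numeric(scores)) scores <- list(scores)
  vapply(scores, function(s) {
    if (length(s) == 0L) return("")
    if (any(s < 0L | s > 93L)) stop("Phred scores must be in [0, 93]", call. = FALSE)
    intToUtf8(as.integer(s) + 33L)
  }, character(1))
}

#' Mean read quality in error-probability space
#'
#' Converts each Phred score Q to its error probability 10^(-Q/10), averages
#' the probabilities over the read, and converts back:
#' \eqn{-10 \log_{10}(\bar p)}.  This penalises stretches of low-quality
#' bases more than a plain mean of Q values would.
#'
#' @param x Character vector of Phred+33 quality strings, or a list of
#'   integer score vectors.
#' @return Numeric vector of mean qualities.
#' @export
#' @examples
#' mean_quality(int_to_phred(list(c(10L, 20L))))  # ~12.59, not 15
mean_quality <- function(x) {
  if (is.character(x)) x <- phred_to_int(x)
  if (is.numeric(x)) x <- list(x)
  vapply(x, function(q) {
    if (length(q) == 0L) stop("mean_quality() of an empty read", call. = FALSE)
    -10 * log10(mean(10^(-q / 10)))
  }, numeric(1))
}
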