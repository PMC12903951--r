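hist_record <- function(values_true, values_random, breaks) {
  list(
    breaks = breaks,
    true = if (length(values_true)) {
      graphics::hist(values_true, breaks = breaks, plot = FALSE)$counts
    } else rep(0L, length(breaks) - 1L),
    random = if (length(values_random)) {
      graphics::hist(values_random, breaks = breaks, plot = FALSE)$counts
    } else rep(0L, length(breaks) - 1L)
  )
}

#' Build a tuning report record
#'
#' Collects, per AP end, the selected cutoffs, the best score per candidate
#' AP substring length, and similarity/location histograms of the true and
#' random alignment samples at the selected length, plus read-category
#' counts.  This is the machine-readable record behind the HTML report;
#' every number shown in the HTML comes from it.
#'
#' @param tuning An `ap_tuning` object.
#' @param counts Optional named list/vector of read-category counts
#'   (e.g. `full_length`, `truncated`, `chimeric`, `failed_quality`).
#' @return A report list (class `nanosift_report`).
#' @export
build_report <- function(tuning, counts = NULL) {
  stopifnot(inherits(tuning, "ap_tuning"))
  aps <- list()
  for (ap in tuning$cutoffs$ap_id) {
    sel <- tuning$cutoffs[tuning$cutoffs$ap_id == ap, ]
    samp <- tuning$samples[tuning$samples$ap_id == ap &
                             tuning$samples$ap_sub_length == sel$ap_sub_length, ]
    max_ed <- max(samp$end_distance, 1)
    loc_breaks <- seq(0, 50 * ceiling(max_ed / 50), length.out = 41L)
    aps[[ap]] <- list(
      cutoffs = as.list(sel[, c("similarity_cutoff", "location_cutoff",
                                "ap_sub_length", "beta", "precision",
                                "recall", "f_beta")]),
      by_length = tuning$by_length[tuning$by_length$ap_id == ap,
                                   c("ap_sub_length", "similarity_cutoff",
                                     "location_cutoff", "precision",
                                     "recall", "f_beta")],
      histograms = list(
        similarity = hist_record(
          samp$similarity[samp$label == "true"],
          samp$similarity[samp$label == "random"],
          seq(-1, 1, by = 0.05)),
        location = hist_record(
          samp$end_distance[samp$label == "true"],
          samp$end_distance[samp$label == "random"],
          loc_breaks)
      )
    )
  }
  rep <- list(
    report_version = 1L,
    beta = tuning$beta,
    n_samples = nrow(tuning$samples),
    aps = aps,
    counts = if (is.null(counts)) NULL else as.list(counts)
  )
  class(rep) <- "nanosift_report"
  rep
}

#' Validate a tuning report against the shipped structural schema
#'
#' Performs the structural checks described by
#' `system.file("extdata", "report-schema.json", package = "nanosift")`:
#' required fields, field types, and histogram consistency (counts sum to
#' the number of contributing samples; one count per bin).
#'
#' @param report A report list (from [build_report()] or parsed from JSON).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  need <- c("report_version", "beta", "n_samples", "aps")
  missing <- setdiff(need, names(report))
  if (length(missing)) {
    stop("report missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(report$beta) || report$beta <= 0) {
    stop("report beta must be a positive number", call. = FALSE)
  }
  if (length(report$aps) < 1) stop("report has no AP entries", call. = FALSE)
  for (ap in names(report$aps)) {
    entry <- report$aps[[ap]]
    cneed <- c("similarity_cutoff", "location_cutoff", "ap_sub_length",
               "beta", "precision", "recall", "f_beta")
    if (!all(cneed %in% names(entry$cutoffs))) {
      stop("AP '", ap, "' cutoffs incomplete", call. = FALSE)
    }
    prf <- unlist(entry$cutoffs[c("precision", "recall", "f_beta")])
    if (any(prf < 0 | prf > 1)) {
      stop("AP '", ap, "' has precision/recall/f_beta outside [0, 1]",
           call. = FALSE)
    }
    for (h in c("similarity", "location")) {
      hh <- entry$histograms[[h]]
      if (is.null(hh)) stop("AP '", ap, "' missing ", h, " histogram",
                            call. = FALSE)
      nb <- length(hh$breaks) - 1L
      if (length(hh$true) != nb || length(hh$random) != nb) {
        stop("AP '", ap, "' ", h, " histogram has wrong bin count",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

fmt_num <- function(x) {
  ifelse(x == round(x), format(x, trim = TRUE, scientific = FALSE),
         sprintf("%.4f", x))
}

svg_hist <- function(hh, title) {
  counts_t <- as.numeric(hh$true)
  counts_r <- as.numeric(hh$random)
  nb <- length(counts_t)
  top <- max(counts_t, counts_r, 1)
  w <- 560; h <- 160; bw <- w / nb
  bars <- character(0)
  for (i in seq_len(nb)) {
    ht <- 140 * counts_t[i] / top
    hr <- 140 * counts_r[i] / top
    x <- sprintf("%.1f", (i - 1) * bw)
    bars <- c(bars,
      sprintf('<rect x="%s" y="%.1f" width="%.1f" height="%.1f" fill="#2aa8a0" fill-opacity="0.65"/>',
              x, 150 - ht, bw * 0.9, ht),
      sprintf('<rect x="%s" y="%.1f" width="%.1f" height="%.1f" fill="#e08a2e" fill-opacity="0.65"/>',
              x, 150 - hr, bw * 0.9, hr))
  }
  paste0('<h4>', title, '</h4>',
         '<svg width="', w, '" height="', h,
         '" role="img" xmlns="http://www.w3.org/2000/svg">',
         paste(bars, collapse = ""), '</svg>',
         '<p class="legend">teal = true alignments, orange = random alignments; ',
         'x from ', fmt_num(hh$breaks[1]), ' to ',
         fmt_num(hh$breaks[length(hh$breaks)]), '</p>')
}

html_table <- function(df) {
  head_row <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""),
                     "</tr>")
  body <- apply(df, 1L, function(r) {
    paste0("<tr>", paste0("<td>", fmt_num(as.numeric(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0('<table>', head_row, paste(body, collapse = ""), '</table>')
}

#' Render a tuning report as self-contained static HTML
#'
#' A pure function of the report record: the same report always renders to
#' byte-identical HTML, and every number shown is taken from the record.
#'
#' @param report A report list (see [build_report()]).
#' @return A single HTML string.
#' @export
render_report_html <- function(report) {
  validate_report(report)
  parts <- c(
    '<!DOCTYPE html><html><head><meta charset="utf-8"/>',
    '<title>nanosift tuning report</title>',
    '<style>body{font-family:sans-serif;margin:2em;max-width:60em}',
    'table{border-collapse:collapse;margin:0.6em 0}',
    'td,th{border:1px solid #999;padding:0.25em 0.6em;text-align:right}',
    '.legend{color:#555;font-size:0.85em}</style></head><body>',
    '<h1>nanosift tuning report</h1>',
    paste0('<p>beta = ', fmt_num(report$beta),
           '; alignment samples = ', report$n_samples, '</p>')
  )
  for (ap in names(report$aps)) {
    entry <- report$aps[[ap]]
    co <- entry$cutoffs
    parts <- c(parts,
      paste0('<h2>', ap, ' AP</h2>'),
      paste0('<p>selected cutoffs: similarity &ge; ',
             fmt_num(co$similarity_cutoff),
             ', end distance &le; ', fmt_num(co$location_cutoff),
             ' nt, AP substring length ', fmt_num(co$ap_sub_length),
             ' nt &mdash; precision ', fmt_num(co$precision),
             ', recall ', fmt_num(co$recall),
             ', F-beta ', fmt_num(co$f_beta), '</p>'),
      '<h3>Best score per AP substring length</h3>',
      html_table(as.data.frame(entry$by_length)),
      svg_hist(entry$histograms$similarity, "Similarity: true vs random"),
      svg_hist(entry$histograms$location, "End distance (nt): true vs random")
    )
  }
  if (!is.null(report$counts)) {
    cdf <- data.frame(as.list(unlist(report$counts)))
    parts <- c(parts, '<h2>Read categories</h2>', html_table(cdf))
  }
  parts <- c(parts, '</body></html>')
  paste(parts, collapse = "\n")
}

#' Write the tuning report to JSON and HTML files
#'
#' @param tuning An `ap_tuning` object.
#' @param counts Optional read-category counts (see [build_report()]).
#' @param path_json Output path for the machine-readable JSON report.
#' @param path_html Optional output path for the static HTML rendering.
#' @return Invisibly, the report list.
#' @export
write_report <- function(tuning, counts = NULL, path_json,
                         path_html = NULL) {
  report <- build_report(tuning, counts)
  out <- unclass(report)
  out$aps <- lapply(out$aps, function(e) {
    e$by_length <- as.data.frame(e$by_length)
    e
  })
  jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  if (!is.null(path_html)) {
    writeLines(render_report_html(report), path_html)
  }
  invisible(report)
}

#' Read a JSON tuning report back into a report list
#'
#' @param path Path to a report JSON written by [write_report()].
#' @return A report list (class `nanosift_report`).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "nanosift_report"
  rep
}
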