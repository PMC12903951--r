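#' Adapter/primer schema
#'
#' Describes the AP pair of a library construction kit.  `front_ap` is the
#' AP expected at the 5' end of a sense-oriented read; `rear_ap` is the AP
#' expected at the 3' end, given in sense orientation so that its reverse
#' complement appears at the end of a plus-strand read as sequenced.  The
#' polyA tail sits between the insert and the rear AP.
#'
#' @param front_ap,rear_ap DNA strings over A/C/G/T.
#' @param kit_name Free-text label.
#' @return An object of class `ap_schema`.
#' @export
ap_schema <- function(front_ap, rear_ap, kit_name = "custom") {
  front_ap <- toupper(front_ap)
  rear_ap <- toupper(rear_ap)
  stopifnot(length(front_ap) == 1L, length(rear_ap) == 1L)
  if (nchar(front_ap) < 1L || nchar(rear_ap) < 1L) {
    stop("AP sequences must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", front_ap) || grepl("[^ACGT]", rear_ap)) {
    stop("AP sequences must be over A/C/G/T", call. = FALSE)
  }
  structure(
    list(kit_name = kit_name, front_ap = front_ap, rear_ap = rear_ap,
         polyA_side = "rear"),
    class = "ap_schema"
  )
}

#' @export
print.ap_schema <- function(x, ...) {
  cat("<ap_schema> kit:", x$kit_name, "\n",
      " front AP (5'):", x$front_ap, paste0("(", nchar(x$front_ap), " nt)"), "\n",
      " rear AP (3'): ", x$rear_ap, paste0("(", nchar(x$rear_ap), " nt)"), "\n")
  invisible(x)
}

kit_table <- function() {
  path <- system.file("extdata", "kits.tsv", package = "nanosift")
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' List shipped kit presets
#'
#' Kit presets are configuration data (a plain-text table installed with the
#' package); edit or extend them freely, and verify the sequences against
#' your kit's documentation.
#'
#' @return A tibble with columns `kit`, `front_ap`, `rear_ap`.
#' @export
list_kits <- function() kit_table()

#' Load an AP schema from a kit preset
#'
#' @param kit Kit name, e.g. `"PCS109"`; see [list_kits()].
#' @return An [ap_schema()].
#' @export
kit_schema <- function(kit) {
  tab <- kit_table()
  row <- tab[tab$kit == kit, ]
  if (nrow(row) != 1L) {
    stop("unknown kit preset '", kit, "'; available: ",
         paste(tab$kit, collapse = ", "), call. = FALSE)
  }
  ap_schema(row$front_ap, row$rear_ap, kit_name = kit)
}

#' Synthetic AP schema for simulation and testing
#'
#' A fixed pair of 25 nt synthetic adapter/primer sequences, selected so
#' that no end-anchored substring of either AP (on either strand) aligns
#' with more than 0.6 similarity into the other AP, its own off-site
#' regions, or a polyA tract -- the mutual-dissimilarity property real kit
#' adapters are designed for.  Used as the default schema of the read
#' simulator so that no vendor sequence is load-bearing anywhere.
#'
#' @return An [ap_schema()].
#' @export
synthetic_schema <- function() {
  ap_schema(
    front_ap = "CGTGATAAGGATGACAGGAGTTTCT",
    rear_ap  = "GGCAATACAGGTAGGCACAGCAAGC",
    kit_name = "synthetic"
  )
}

# Pattern for one AP end / substring length / strand, anchored so the
# insert-proximal boundary of the AP is always inside the alignment:
# the front pattern keeps the 3' end of front_ap, the rear pattern keeps
# the insert-proximal end of rc(rear_ap).
ap_pattern <- function(schema, ap_id, L, strand) {
  if (ap_id == "front") {
    full <- schema$front_ap
    L <- min(L, nchar(full))
    pat <- substr(full, nchar(full) - L + 1L, nchar(full))
  } else {
    full <- reverse_complement(schema$rear_ap)
    L <- min(L, nchar(full))
    pat <- substr(full, 1L, L)
  }
  if (strand == "-") pat <- reverse_complement(pat)
  pat
}

ap_full_length <- function(schema, ap_id) {
  nchar(if (ap_id == "front") schema$front_ap else schema$rear_ap)
}

# Distance from a hit to its expected read terminus, on the forward read as
# sequenced.  front/+ and rear/- hits are expected at the read start;
# front/- and rear/+ hits at the read end.  Absolute bases, not normalised
# by read length.
end_distance <- function(ap_id, strand, read_start, read_end, read_length) {
  near_start <- (ap_id == "front" & strand == "+") |
    (ap_id == "rear" & strand == "-")
  near_start <- rep_len(near_start, length(read_start))
  ifelse(near_start, read_start, read_length - read_end)
}
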