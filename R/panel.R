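#' Construct an amplicon panel
#'
#' An amplicon panel is the ordered set of target regions that defines the
#' coordinate frame for depth normalization and variant intersection.
#' Internally coordinates are 1-based inclusive (VCF convention); BED input
#' is converted at parse time by [read_panel_bed()].
#'
#' @param amplicon_id character vector of unique amplicon identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based inclusive, `start < end`.
#' @return A `data.frame` of class `amplicon_panel` with columns
#'   `amplicon_id`, `chrom`, `start`, `end`, sorted by `(chrom, start)`.
#' @export
amplicon_panel <- function(amplicon_id, chrom, start, end) {
  panel <- data.frame(
    amplicon_id = as.character(amplicon_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  if (nrow(panel) < 2L) {
    stop("an amplicon panel needs at least 2 amplicons (ratio normalization is undefined for n < 2)")
  }
  if (anyDuplicated(panel$amplicon_id)) {
    dup <- unique(panel$amplicon_id[duplicated(panel$amplicon_id)])
    stop("duplicate amplicon id(s): ", paste(dup, collapse = ", "))
  }
  bad <- which(!(panel$start < panel$end))
  if (length(bad)) {
    stop("amplicon(s) with start >= end: ", paste(panel$amplicon_id[bad], collapse = ", "))
  }
  # canonical ordering: stable sort by (chrom, start)
  panel <- panel[order(panel$chrom, panel$start, method = "radix"), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("amplicon_panel", "data.frame")
  panel
}

#' Read an amplicon panel from a BED file
#'
#' BED coordinates are 0-based half-open on disk; they are converted to the
#' internal 1-based inclusive convention (`start + 1`, `end`) so that
#' variant positions (VCF, 1-based) compare directly. Amplicon ids come from
#' the BED name column when present, otherwise they are auto-generated as
#' `amp_<k>` in file order.
#'
#' @param path path to a BED file with at least 3 columns
#'   (chrom, start, end) and optionally a name column.
#' @return An [amplicon_panel()].
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) stop("panel BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  data_idx <- which(keep)
  if (length(data_idx) < 2L) stop("panel BED needs at least 2 data lines: ", path)
  fields <- strsplit(lines[data_idx], "\t| +")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad)) {
    stop("malformed BED line ", data_idx[bad[1L]], " in ", path,
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop("malformed BED line ", data_idx[bad[1L]], " in ", path,
         ": non-numeric coordinates")
  }
  ids <- vapply(seq_along(fields), function(i) {
    if (n_fields[i] >= 4L && nzchar(fields[[i]][4L])) fields[[i]][4L]
    else sprintf("amp_%d", i)
  }, "")
  # BED half-open 0-based -> 1-based inclusive
  amplicon_panel(ids, chrom, start0 + 1L, end0)
}

#' Write an amplicon panel to a BED file
#'
#' Inverse of [read_panel_bed()]: internal 1-based inclusive coordinates are
#' written back as 0-based half-open BED.
#'
#' @param panel an [amplicon_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "amplicon_panel"))
  out <- data.frame(panel$chrom, panel$start - 1L, panel$end, panel$amplicon_id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

panel_granges <- function(panel) {
  GenomicRanges::GRanges(
    seqnames = panel$chrom,
    ranges = IRanges::IRanges(start = panel$start, end = panel$end),
    amplicon_id = panel$amplicon_id
  )
}

#' Intersect variant calls with an amplicon panel
#'
#' Keeps exactly the calls whose position falls inside at least one amplicon
#' interval (1-based inclusive on both sides). Input order is preserved; the
#' operation is idempotent.
#'
#' @param calls a variant-call `data.frame` (see [read_variants()]).
#' @param panel an [amplicon_panel()].
#' @return The subset of `calls` on the panel.
#' @export
intersect_panel <- function(calls, panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  if (nrow(calls) == 0L) return(calls)
  # calls may sit on chromosomes the panel does not target; differing
  # seqlevels are expected, not an error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(calls$chrom,
                           IRanges::IRanges(calls$pos, width = 1L)),
    panel_granges(panel)
  ))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
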