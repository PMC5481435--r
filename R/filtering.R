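#' Variant retention rules
#'
#' Before any bias analysis, calls are filtered to those with DP4 strand
#' counts present (samtools-style callers only emit DP4 for sites they
#' genotyped confidently), a total depth of at least `min_depth` reads
#' (reference plus alternate), and a VAF strictly greater than
#' `min_vaf_exclusive`. The depth cut is inclusive ("at least 50x"), the
#' VAF cut strict ("> 0.04").
#'
#' @param min_depth minimum total read depth, inclusive. Default 50.
#' @param min_vaf_exclusive VAF must exceed this value. Default 0.04.
#' @param require_dp4 drop calls without DP4 strand counts. Default `TRUE`.
#' @param homopolymer_flag_len single-base run length at or above which a
#'   variant is flagged by [flag_homopolymer()]; 0 disables. Default 0.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_depth = 50L, min_vaf_exclusive = 0.04,
                          require_dp4 = TRUE, homopolymer_flag_len = 0L) {
  stopifnot(min_depth >= 0, min_vaf_exclusive >= 0, min_vaf_exclusive < 1,
            homopolymer_flag_len >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_vaf_exclusive = min_vaf_exclusive,
                 require_dp4 = isTRUE(require_dp4),
                 homopolymer_flag_len = as.integer(homopolymer_flag_len)),
            class = "filter_config")
}

#' Filter variant calls on DP4 presence, depth and VAF
#'
#' Checks run in order dp4, depth, vaf; each rejected call carries the first
#' failing reason. The kept and rejected sets partition the input.
#'
#' @param calls a [variant_calls()] data.frame, already panel-intersected.
#' @param cfg a [filter_config()].
#' @return list with elements `kept` (data.frame) and `rejected`
#'   (data.frame with an extra `reason` column: `"dp4"`, `"depth"` or
#'   `"vaf"`).
#' @export
filter_variants <- function(calls, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  reason <- rep(NA_character_, nrow(calls))
  if (cfg$require_dp4) reason[is.na(calls$alt_fwd)] <- "dp4"
  reason[is.na(reason) & calls$depth < cfg$min_depth] <- "depth"
  reason[is.na(reason) & !(calls$vaf > cfg$min_vaf_exclusive)] <- "vaf"
  kept <- calls[is.na(reason), , drop = FALSE]
  rejected <- calls[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

# Is the center base of `context` inside, or adjacent to, a single-base run
# of length >= run_len? `context` is the reference sequence centered on the
# variant position.
.homopolymer_hit <- function(context, run_len) {
  chars <- strsplit(context, "")[[1L]]
  n <- length(chars)
  center <- (n + 1L) %/% 2L
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a run qualifies if it covers the center or touches it on either side
  any(r$lengths >= run_len & starts <= center + 1L & ends >= center - 1L)
}

#' Flag variants in or adjacent to homopolymer runs
#'
#' A reproducible surrogate for manual review of alignment artifacts:
#' amplicon sequencing is error-prone at single-base runs, so variants
#' lying inside or immediately adjacent to a run of length >= `run_len`
#' are flagged. The flag is an annotation only; removal is left to the
#' caller.
#'
#' @param calls a [variant_calls()] data.frame.
#' @param reference_context named character vector mapping `"chrom:pos"` to
#'   the reference sequence centered on that position (at least `run_len`
#'   bases each side).
#' @param run_len minimum single-base run length to flag.
#' @return `calls` with a logical `homopolymer` column (`NA` when no
#'   context is available for a call).
#' @export
flag_homopolymer <- function(calls, reference_context, run_len) {
  stopifnot(run_len >= 1)
  key <- paste0(calls$chrom, ":", calls$pos)
  ctx <- reference_context[key]
  calls$homopolymer <- vapply(seq_along(ctx), function(i) {
    if (is.na(ctx[i])) return(NA)
    .homopolymer_hit(ctx[[i]], run_len)
  }, NA)
  calls
}
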