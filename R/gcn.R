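#' Per-amplicon average of depth ratios (AVRT)
#'
#' The intra-sample normalization step of the MLPA-style gene-copy-number
#' method. For each amplicon \eqn{i}, the depth ratio against every other
#' amplicon is averaged:
#' \deqn{AVRT_i = \frac{1}{n-1} \sum_{j \ne i} d_i / d_j}
#' i.e. the column means of the \eqn{n \times n} depth-ratio matrix with the
#' diagonal excluded. An amplicon at the sample's typical depth has AVRT
#' near 1; a selectively over-amplified amplicon has AVRT above 1.
#'
#' The arithmetic mean of ratios is used (not the geometric mean): that is
#' the calculation the dosage-quotient convention prescribes, and the
#' downstream dosage bands are calibrated to it.
#'
#' @param depths named numeric vector of per-amplicon depths, all > 0.
#' @param panel an [amplicon_panel()]; depths must cover exactly its
#'   amplicons.
#' @return named numeric vector of AVRT values in panel order.
#' @export
avrt <- function(depths, panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  ids <- panel$amplicon_id
  if (!setequal(names(depths), ids)) {
    stop("depth profile does not cover the panel's amplicons")
  }
  d <- depths[ids]
  zero <- which(d <= 0)
  if (length(zero)) {
    stop("zero or negative depth at amplicon(s) ",
         paste(ids[zero], collapse = ", "),
         "; depth ratios are undefined (consider impute_floor)")
  }
  n <- length(d)
  # AVRT_i = mean_j!=i d_i/d_j = (d_i * sum(1/d) - 1) / (n - 1)
  s_inv <- sum(1 / d)
  stats::setNames((d * s_inv - 1) / (n - 1), ids)
}

#' Replace zero depths by a one-read floor
#'
#' Optional preprocessing for [avrt()]: zero-depth amplicons make depth
#' ratios undefined, so an explicit policy replaces them with 1 read. Kept
#' separate from [avrt()] so the imputation is always a visible, logged
#' choice rather than a silent default.
#'
#' @param depths named numeric depth vector.
#' @return depths with zeros replaced by 1.
#' @export
impute_floor <- function(depths) {
  zero <- depths <= 0
  if (any(zero)) {
    message("impute_floor: ", sum(zero), " zero-depth amplicon(s) set to 1 read")
    depths[zero] <- 1
  }
  depths
}

#' Normalize gene copy number against a reference sample
#'
#' The inter-sample step: each amplicon's AVRT in the test sample is divided
#' by its AVRT in the reference sample. GCN = 1 means the same dosage as the
#' reference (diploid if the reference is diploid), 0.5 a single-allele
#' loss, 2 a doubling. The statistic is invariant to uniform rescaling of
#' either profile (library size cancels).
#'
#' @param test,reference named numeric depth vectors covering `panel`.
#' @param panel an [amplicon_panel()].
#' @param test_sample_id,reference_sample_id optional labels stored on the
#'   result.
#' @return a `gcn_table`: data.frame with columns `amplicon_id`, `gcn`,
#'   `avrt_test`, `avrt_ref`, plus `test_sample_id` / `reference_sample_id`
#'   attributes.
#' @export
normalize_gcn <- function(test, reference, panel,
                          test_sample_id = NA_character_,
                          reference_sample_id = NA_character_) {
  at <- avrt(test, panel)
  ar <- avrt(reference, panel)
  out <- data.frame(
    amplicon_id = panel$amplicon_id,
    gcn = unname(at / ar),
    avrt_test = unname(at),
    avrt_ref = unname(ar),
    stringsAsFactors = FALSE
  )
  attr(out, "test_sample_id") <- test_sample_id
  attr(out, "reference_sample_id") <- reference_sample_id
  class(out) <- c("gcn_table", "data.frame")
  out
}

#' Call per-amplicon dosage from GCN values
#'
#' Normal dosage is the closed band `1 +/- half_width` (band edges
#' inclusive); below it is a loss, above it a gain. The default half-width
#' of 0.25 brackets diploid dosage while leaving single-allele loss (0.5)
#' and single-copy gain (1.5) outside the band.
#'
#' @param gcn a `gcn_table` from [normalize_gcn()], or a named numeric
#'   vector of GCN values.
#' @param half_width half-width of the normal band around 1. Default 0.25.
#' @return named character vector: `"loss"`, `"normal"` or `"gain"` per
#'   amplicon.
#' @export
call_dosage <- function(gcn, half_width = 0.25) {
  stopifnot(half_width > 0, half_width < 1)
  values <- if (inherits(gcn, "gcn_table")) {
    stats::setNames(gcn$gcn, gcn$amplicon_id)
  } else {
    gcn
  }
  out <- ifelse(values < 1 - half_width, "loss",
                ifelse(values > 1 + half_width, "gain", "normal"))
  stats::setNames(out, names(values))
}

#' Compare GCN value ranges between two conditions
#'
#' Amplicon-matched comparison of two GCN tables with the two-tailed
#' Wilcoxon matched-pairs signed-rank test. Zero differences are dropped
#' before ranking; the exact distribution is used for up to 25 informative
#' pairs with untied absolute differences, and the normal approximation
#' with continuity correction otherwise.
#'
#' @param gcn_a,gcn_b `gcn_table`s (or named numeric vectors) over the same
#'   amplicons.
#' @return list with `p` (two-tailed), `n_pairs` (informative pairs after
#'   dropping zeros), `exact` (logical), `degenerate` (`TRUE` when all
#'   differences are zero, in which case `p = 1`), and `summary` (min,
#'   median, max of each condition).
#' @export
gcn_range_comparison <- function(gcn_a, gcn_b) {
  va <- if (inherits(gcn_a, "gcn_table")) stats::setNames(gcn_a$gcn, gcn_a$amplicon_id) else gcn_a
  vb <- if (inherits(gcn_b, "gcn_table")) stats::setNames(gcn_b$gcn, gcn_b$amplicon_id) else gcn_b
  if (!setequal(names(va), names(vb))) stop("GCN tables cover different amplicons")
  vb <- vb[names(va)]
  diffs <- va - vb
  nz <- diffs[diffs != 0]
  summary_tab <- data.frame(
    condition = c("a", "b"),
    min = c(min(va), min(vb)),
    median = c(stats::median(va), stats::median(vb)),
    max = c(max(va), max(vb))
  )
  if (length(nz) == 0L) {
    return(list(p = 1, n_pairs = 0L, exact = TRUE, degenerate = TRUE,
                summary = summary_tab))
  }
  use_exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    wilcox.test(unname(va), unname(vb), paired = TRUE,
                exact = use_exact, correct = TRUE)
  )
  list(p = unname(wt$p.value), n_pairs = length(nz), exact = use_exact,
       degenerate = FALSE, summary = summary_tab)
}

#' Coverage uniformity of a depth profile
#'
#' Percentage of amplicons whose mean depth reaches at least
#' `fraction_of_mean` times the profile's mean depth (the conventional 0.2x
#' threshold). Defined on per-amplicon mean depths, not raw bases, so it is
#' comparable across profiles but not identical to instrument-pipeline
#' uniformity metrics computed per base.
#'
#' @param depths named numeric vector of per-amplicon depths.
#' @param fraction_of_mean threshold as a fraction of mean depth.
#'   Default 0.2.
#' @return uniformity percentage in `[0, 100]`.
#' @export
coverage_uniformity <- function(depths, fraction_of_mean = 0.2) {
  stopifnot(length(depths) >= 1L)
  if (all(depths == 0)) {
    warning("all depths zero; coverage uniformity reported as 0")
    return(0)
  }
  100 * mean(depths >= fraction_of_mean * mean(depths))
}
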