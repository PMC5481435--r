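variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Replicate VAF noise estimate
#'
#' Quantifies the VAF variability introduced by library preparation alone,
#' from independent replicate preps of the same sample: for every variant
#' found in \emph{all} replicates, the sample standard deviation (n-1
#' denominator) of its VAF across replicates is computed, and those SDs are
#' averaged. Variants missing from any replicate do not contribute. The
#' suggested bias threshold is the mean SD rounded \emph{up} to the next
#' multiple of 0.05 -- a deliberately conservative round figure, exposed so
#' the user can see how it was reached rather than having it applied
#' silently.
#'
#' @param replicates list of two or more [variant_calls()] data.frames from
#'   replicate preps of one sample (already filtered).
#' @return list with `per_variant_sd` (named numeric), `mean_sd`,
#'   `n_consistent_variants`, and `suggested_threshold`.
#' @export
replicate_vaf_noise <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  keys <- lapply(replicates, variant_key)
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L) {
    stop("no variant is shared by all replicates; noise estimate undefined")
  }
  vafs <- vapply(seq_along(replicates), function(i) {
    calls <- replicates[[i]]
    stats::setNames(calls$vaf, keys[[i]])[shared]
  }, numeric(length(shared)))
  if (is.null(dim(vafs))) vafs <- matrix(vafs, nrow = 1L)
  per_sd <- apply(vafs, 1L, sd)
  names(per_sd) <- shared
  mean_sd <- mean(per_sd)
  list(
    per_variant_sd = per_sd,
    mean_sd = mean_sd,
    n_consistent_variants = length(shared),
    suggested_threshold = max(0.05, ceiling(mean_sd / 0.05) * 0.05)
  )
}

#' Classify variants as germline, somatic or WGA-created
#'
#' Class assignment for one sample set, anchored on the non-WGA FFPE
#' reference samples: a variant key present in the non-WGA FFPE
#' \emph{normal} reference is germline; one present in the non-WGA FFPE
#' \emph{tumor} reference but not the normal is somatic; one seen only in a
#' WGA sample -- absent from both references -- is WGA-created, i.e. a false
#' positive manufactured by the amplification. Classes are mutually
#' exclusive per key.
#'
#' @param normal_ref_calls,tumor_ref_calls filtered, panel-intersected
#'   [variant_calls()] for the non-WGA FFPE normal and tumor references.
#' @param wga_calls a single data.frame or a list of data.frames of calls
#'   from WGA samples of the same set.
#' @return data.frame with columns `key`, `chrom`, `pos`, `ref`, `alt`,
#'   `class`.
#' @export
classify_variants <- function(normal_ref_calls, tumor_ref_calls, wga_calls) {
  if (is.null(normal_ref_calls) || is.null(tumor_ref_calls)) {
    stop("both non-WGA FFPE reference call sets are required")
  }
  if (is.data.frame(wga_calls)) wga_calls <- list(wga_calls)
  germ <- unique(variant_key(normal_ref_calls))
  som <- setdiff(unique(variant_key(tumor_ref_calls)), germ)
  wga_keys <- unique(unlist(lapply(wga_calls, variant_key)))
  created <- setdiff(wga_keys, c(germ, som))
  all_calls <- rbind(normal_ref_calls, tumor_ref_calls,
                     do.call(rbind, wga_calls))
  all_keys <- variant_key(all_calls)
  idx <- !duplicated(all_keys)
  tab <- data.frame(
    key = all_keys[idx],
    chrom = all_calls$chrom[idx],
    pos = all_calls$pos[idx],
    ref = all_calls$ref[idx],
    alt = all_calls$alt[idx],
    stringsAsFactors = FALSE
  )
  tab$class <- ifelse(tab$key %in% germ, "germline",
                      ifelse(tab$key %in% som, "somatic", "wga_created"))
  tab <- tab[tab$key %in% c(germ, som, created), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Delta-VAF records for one WGA sample
#'
#' For every variant in a WGA sample, the VAF shift against the matched
#' non-WGA FFPE reference: `delta = vaf_test - vaf_ref`. A variant is
#' \emph{biased} when `|delta| > threshold`, with direction positive
#' (`delta > threshold`) or negative (`delta < -threshold`). WGA-created
#' variants have no reference VAF; they are biased by definition with
#' positive direction (the call appeared from nothing). Variants of a known
#' class that happen to be absent from this sample's matched reference
#' (e.g. filtered out there) get `NA` delta and are excluded from biased
#' counts.
#'
#' The default threshold of 0.05 is chosen to sit above the replicate
#' library-prep VAF noise (mean per-variant SDs around 0.02-0.03, see
#' [replicate_vaf_noise()]); 0.10 is a documented stricter alternative.
#'
#' @param wga_calls filtered calls from one WGA sample.
#' @param matched_ref_calls filtered calls from its matched non-WGA FFPE
#'   reference (same tissue).
#' @param classes class table from [classify_variants()].
#' @param threshold bias threshold on `|delta|`. Default 0.05.
#' @param kit,tissue labels recorded on each record.
#' @return data.frame of delta-VAF records: `key`, `ref`, `alt`, `class`,
#'   `vaf_test`, `vaf_ref`, `delta`, `biased`, `direction`, `kit`,
#'   `tissue`, `sample_id`.
#' @export
delta_vaf <- function(wga_calls, matched_ref_calls, classes,
                      threshold = 0.05, kit = NA_character_,
                      tissue = NA_character_) {
  stopifnot(threshold > 0)
  key_test <- variant_key(wga_calls)
  ref_vaf <- stats::setNames(matched_ref_calls$vaf, variant_key(matched_ref_calls))
  cls <- stats::setNames(classes$class, classes$key)[key_test]
  cls[is.na(cls)] <- "wga_created"
  vaf_ref <- unname(ref_vaf[key_test])
  delta <- wga_calls$vaf - vaf_ref
  biased <- ifelse(cls == "wga_created" & is.na(vaf_ref), TRUE,
                   abs(delta) > threshold)
  direction <- rep("none", length(delta))
  direction[!is.na(delta) & delta > threshold] <- "positive"
  direction[!is.na(delta) & delta < -threshold] <- "negative"
  direction[cls == "wga_created" & is.na(vaf_ref)] <- "positive"
  out <- data.frame(
    key = key_test,
    ref = wga_calls$ref,
    alt = wga_calls$alt,
    class = unname(cls),
    vaf_test = wga_calls$vaf,
    vaf_ref = vaf_ref,
    delta = delta,
    biased = biased,
    direction = direction,
    kit = rep(kit, length.out = nrow(wga_calls)),
    tissue = rep(tissue, length.out = nrow(wga_calls)),
    sample_id = wga_calls$sample_id,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Count biased variants per sample and class
#'
#' @param records delta-VAF records, possibly pooled over samples.
#' @return data.frame with one row per `(sample_id, kit, tissue, class)`
#'   and the count of biased records (`NA`-delta records excluded unless
#'   WGA-created).
#' @export
count_biased <- function(records) {
  biased <- records[!is.na(records$biased) & records$biased, , drop = FALSE]
  if (nrow(biased) == 0L) {
    return(data.frame(sample_id = character(), kit = character(),
                      tissue = character(), class = character(),
                      n_biased = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(n_biased = biased$key),
    by = list(sample_id = biased$sample_id, kit = biased$kit,
              tissue = biased$tissue, class = biased$class),
    FUN = length
  )
  agg <- agg[order(agg$sample_id, agg$class), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Exact Mann-Whitney by full enumeration of group labelings, using
# mid-ranks so tied observations are handled. Two-tailed p as
# 2 * min(P(U <= u), P(U >= u)), capped at 1 (the usual convention).
.mw_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_le <- mean(u_all <= u_obs + eps)
  p_ge <- mean(u_all >= u_obs - eps)
  list(p = min(1, 2 * min(p_le, p_ge)), u = u_obs)
}

#' Two-tailed Mann-Whitney comparison of two groups
#'
#' Rank-sum comparison used for per-sample biased-variant counts and
#' delta-VAF magnitudes between kits. For small groups the exact null
#' distribution is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group labelings with mid-ranks, so ties are
#' handled exactly (for two non-overlapping groups of 5 this gives
#' p = 2/choose(10,5) = 0.0079); for larger groups the mid-rank normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y numeric observation vectors (each non-empty).
#' @param max_enumeration largest number of labelings enumerated exactly.
#' @return list with `p`, `statistic` (Mann-Whitney U of `x`), `mean_x`,
#'   `mean_y`, `n_x`, `n_y`, `exact`.
#' @export
mann_whitney <- function(x, y, max_enumeration = 2e5) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group in Mann-Whitney comparison")
  exact <- choose(length(x) + length(y), length(x)) <= max_enumeration
  if (exact) {
    en <- .mw_enumerate(x, y)
    p <- en$p
    u <- en$u
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- unname(wt$p.value)
    u <- unname(wt$statistic)
  }
  list(p = p, statistic = u, mean_x = mean(x), mean_y = mean(y),
       n_x = length(x), n_y = length(y), exact = exact)
}

#' Compare per-sample biased-variant counts between kits
#'
#' For each variant class, the per-sample (or per-replicate) biased counts
#' of the two kits are compared with [mann_whitney()]. Samples with no
#' biased variant of a class count as 0 for that class.
#'
#' @param counts output of [count_biased()] pooled over samples; must carry
#'   `kit` values `"kitA"` and `"kitB"`.
#' @param sample_ids_a,sample_ids_b the full rosters of kitA and kitB
#'   sample ids (so zero counts are represented).
#' @return data.frame with one row per class: group means, n, U statistic
#'   and two-tailed p.
#' @export
biased_count_comparison <- function(counts, sample_ids_a, sample_ids_b) {
  classes <- c("germline", "somatic", "wga_created")
  rows <- lapply(classes, function(cl) {
    sub <- counts[counts$class == cl, , drop = FALSE]
    grab <- function(ids) {
      v <- stats::setNames(rep(0L, length(ids)), ids)
      hit <- sub$sample_id %in% ids
      v[sub$sample_id[hit]] <- sub$n_biased[hit]
      unname(v)
    }
    a <- grab(sample_ids_a)
    b <- grab(sample_ids_b)
    mw <- mann_whitney(a, b)
    data.frame(class = cl, mean_kitA = mw$mean_x, mean_kitB = mw$mean_y,
               n_kitA = mw$n_x, n_kitB = mw$n_y,
               U = mw$statistic, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' VAF concordance between two call sets
#'
#' Ordinary least-squares regression of the second sample's VAF on the
#' first's over their shared variant keys; `r_squared` is the squared
#' Pearson correlation. Used to show that, e.g., frozen and FFPE VAFs from
#' the same patient agree before any WGA is applied.
#'
#' @param calls_x,calls_y [variant_calls()] data.frames.
#' @return list with `slope`, `intercept`, `r_squared`, `n_shared`.
#' @export
vaf_concordance <- function(calls_x, calls_y) {
  kx <- variant_key(calls_x)
  ky <- variant_key(calls_y)
  shared <- intersect(kx, ky)
  if (length(shared) < 3L) stop("fewer than 3 shared variants; concordance undefined")
  x <- stats::setNames(calls_x$vaf, kx)[shared]
  y <- stats::setNames(calls_y$vaf, ky)[shared]
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = stats::cor(x, y)^2,
       n_shared = length(shared))
}
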