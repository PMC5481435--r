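#' The 12 ordered substitution types
#'
#' All ordered ref>alt pairs over {A,C,G,T}. No strand collapsing: C>T and
#' G>A are kept separate here and only pooled by [cgta_fraction()].
#'
#' @return character vector of length 12, e.g. `"C>T"`.
#' @export
substitution_types <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(alt = bases, ref = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, , drop = FALSE]
  sort(paste0(grid$ref, ">", grid$alt))
}

#' Substitution type of a ref/alt pair
#'
#' @param ref,alt single bases among A/C/G/T, `ref != alt`. Vectorized.
#' @return character vector of ordered types, e.g. `"G>A"`.
#' @export
substitution_type <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases) || any(!alt %in% bases)) {
    stop("ref and alt must be single bases among A, C, G, T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  paste0(ref, ">", alt)
}

#' Tabulate the substitution spectrum of biased variants
#'
#' Counts biased delta-VAF records by substitution type, kit and stratum:
#' `all_altered` pools biased germline, biased somatic and WGA-created
#' records; `germline_plus_somatic` excludes the WGA-created ones;
#' `wga_created` keeps only those. All 12 types appear for every kit
#' present (zero counts included), so totals are conserved and tables from
#' different runs align.
#'
#' @param records delta-VAF records ([delta_vaf()]), pooled over samples.
#' @param stratum `"all_altered"`, `"germline_plus_somatic"` or
#'   `"wga_created"`.
#' @return data.frame of class `substitution_spectrum` with columns `kit`,
#'   `stratum`, `substitution`, `count`.
#' @export
tabulate_spectrum <- function(records,
                              stratum = c("all_altered",
                                          "germline_plus_somatic",
                                          "wga_created")) {
  stratum <- match.arg(stratum)
  sel <- !is.na(records$biased) & records$biased
  sel <- sel & switch(stratum,
    all_altered = TRUE,
    germline_plus_somatic = records$class %in% c("germline", "somatic"),
    wga_created = records$class == "wga_created"
  )
  sub <- records[sel, , drop = FALSE]
  kits <- sort(unique(records$kit))
  if (length(kits) == 0L) kits <- NA_character_
  types <- substitution_types()
  out <- expand.grid(substitution = types, kit = kits,
                     stringsAsFactors = FALSE)[, c("kit", "substitution")]
  out$stratum <- stratum
  out$count <- 0L
  if (nrow(sub)) {
    sub_type <- substitution_type(sub$ref, sub$alt)
    tab <- table(kit = sub$kit, substitution = factor(sub_type, levels = types))
    for (k in rownames(tab)) {
      idx <- out$kit == k
      out$count[idx] <- as.integer(tab[k, out$substitution[idx]])
    }
  }
  out <- out[, c("kit", "stratum", "substitution", "count")]
  class(out) <- c("substitution_spectrum", "data.frame")
  out
}

#' Per-reference-base counts of a substitution spectrum
#'
#' @param spectrum a `substitution_spectrum`.
#' @return data.frame with columns `kit`, `base`, `count`, where `count`
#'   sums the three substitutions with that reference base.
#' @export
base_counts <- function(spectrum) {
  base <- substr(spectrum$substitution, 1L, 1L)
  agg <- stats::aggregate(list(count = spectrum$count),
                          by = list(kit = spectrum$kit, base = base), FUN = sum)
  agg <- agg[order(agg$kit, agg$base), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Two-count z-test for comparing substitution counts
#'
#' Compares two event counts (e.g. how many biased G>A variants each kit
#' produced) with the normal approximation for the difference of two
#' Poisson counts: \deqn{z = (a - b) / \sqrt{a + b}} and a two-tailed
#' standard-normal p-value, without continuity correction.
#'
#' By convention z statistics are reported to two decimals and the tail
#' probability is read off at that precision (the workflow of looking a
#' reported z value up in a table or web calculator); `z_digits = 2`
#' reproduces that. Set `z_digits = NULL` for the full-precision p-value.
#' The `z` component of the result is always full precision.
#'
#' @param a,b non-negative integer counts.
#' @param z_digits decimals the z statistic is reported to before
#'   conversion to p, or `NULL` for full precision. Default 2.
#' @return list with `a`, `b`, `z` (full precision), `p_two_tailed`, and
#'   `degenerate` (`TRUE` when `a + b == 0`, where z is defined as 0 and
#'   p as 1).
#' @export
count_z_test <- function(a, b, z_digits = 2) {
  stopifnot(length(a) == 1L, length(b) == 1L, a >= 0, b >= 0,
            a == round(a), b == round(b))
  if (a + b == 0) {
    message("count_z_test: both counts zero; z = 0, p = 1 by convention")
    return(list(a = a, b = b, z = 0, p_two_tailed = 1, degenerate = TRUE))
  }
  z <- (a - b) / sqrt(a + b)
  z_rep <- if (is.null(z_digits)) z else round(z, z_digits)
  p <- 2 * pnorm(-abs(z_rep))
  list(a = a, b = b, z = z, p_two_tailed = p, degenerate = FALSE)
}

#' Test every substitution type between two kits
#'
#' Applies [count_z_test()] to each of the 12 substitution types of one
#' stratum, kit vs kit.
#'
#' @param spectrum a `substitution_spectrum` containing both kits.
#' @param kit_a,kit_b kit labels to contrast. Defaults `"kitB"` vs
#'   `"kitA"` (the MDA kit first, matching the direction in which the
#'   excess occurs).
#' @return data.frame: `substitution`, `count_a`, `count_b`, `z`, `p`.
#' @export
spectrum_comparison <- function(spectrum, kit_a = "kitB", kit_b = "kitA") {
  types <- substitution_types()
  ca <- stats::setNames(spectrum$count[spectrum$kit == kit_a],
                        spectrum$substitution[spectrum$kit == kit_a])[types]
  cb <- stats::setNames(spectrum$count[spectrum$kit == kit_b],
                        spectrum$substitution[spectrum$kit == kit_b])[types]
  rows <- lapply(types, function(tp) {
    a <- ca[[tp]] %||% 0L
    b <- cb[[tp]] %||% 0L
    if (is.na(a)) a <- 0L
    if (is.na(b)) b <- 0L
    if (a + b == 0) {
      data.frame(substitution = tp, count_a = a, count_b = b,
                 z = 0, p = 1, stringsAsFactors = FALSE)
    } else {
      zt <- count_z_test(a, b)
      data.frame(substitution = tp, count_a = a, count_b = b,
                 z = zt$z, p = zt$p_two_tailed, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled C:G>T:A fraction of a spectrum
#'
#' The fraction of counts that are G>A or C>T -- the two complementary
#' faces of cytosine deamination, the signature FFPE artifact. Pooling
#' happens only here; the 12-type table stays unpooled.
#'
#' @param spectrum a `substitution_spectrum`.
#' @param kit kit label to restrict to; `NULL` pools all kits present.
#' @return fraction in `[0, 1]`.
#' @export
cgta_fraction <- function(spectrum, kit = NULL) {
  sub <- if (is.null(kit)) spectrum else spectrum[spectrum$kit == kit, , drop = FALSE]
  total <- sum(sub$count)
  if (total == 0) stop("zero total count; C:G>T:A fraction undefined")
  sum(sub$count[sub$substitution %in% c("G>A", "C>T")]) / total
}
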