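# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, full enumeration) so they cannot share a
# bug with the implementation paths they check.

# quick variant-call data.frame builder; dp4 derived from depth/vaf unless
# dp4 = NA is requested
make_calls <- function(chrom, pos, ref, alt, depth, vaf,
                       sample_id = "s1", dp4 = TRUE) {
  alt_n <- as.integer(round(depth * vaf))
  vaf <- alt_n / depth
  alt_fwd <- alt_n %/% 2L
  ref_n <- as.integer(depth) - alt_n
  ref_fwd <- ref_n %/% 2L
  df <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    ref_fwd = ref_fwd, ref_rev = ref_n - ref_fwd,
    alt_fwd = alt_fwd, alt_rev = alt_n - alt_fwd,
    depth = as.integer(depth), vaf = vaf,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
  if (identical(dp4, FALSE)) {
    df$ref_fwd <- df$ref_rev <- df$alt_fwd <- df$alt_rev <- NA_integer_
  }
  variant_calls(df)
}

# AVRT by explicit construction of the n x n ratio matrix, diagonal excluded
oracle_avrt <- function(d) {
  n <- length(d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + d[i] / d[j]
    }
    out[i] <- acc / (n - 1)
  }
  stats::setNames(out, names(d))
}

# point-in-interval scan over every call x amplicon pair
oracle_intersect <- function(calls, panel) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(panel))) {
      if (calls$chrom[i] == panel$chrom[j] &&
          calls$pos[i] >= panel$start[j] && calls$pos[i] <= panel$end[j]) {
        keep[i] <- TRUE
      }
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force homopolymer check: enumerate every maximal single-base run and
# test whether it covers or touches the center position
oracle_homopolymer <- function(context, run_len) {
  chars <- strsplit(context, "")[[1L]]
  n <- length(chars)
  center <- (n + 1L) %/% 2L
  for (s in seq_len(n)) {
    e <- s
    while (e < n && chars[e + 1L] == chars[s]) e <- e + 1L
    if (s == 1L || chars[s - 1L] != chars[s]) {      # maximal run start
      if ((e - s + 1L) >= run_len && s <= center + 1L && e >= center - 1L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# exact two-tailed Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments (requires no zero differences and untied |d|)
oracle_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1L, function(s) sum(r[unlist(s)]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# closed-form ordinary least squares of y on x
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- (sxy / sqrt(sxx * sum((y - mean(y))^2)))^2
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# a scaled-down simulation configuration for fast unit tests (the default
# configuration is exercised in the acceptance suite)
small_config <- function(seed = 1L, ...) {
  simulation_config(
    seed = seed, n_amplicons = 24L, n_amplicons_alt = 16L,
    mean_depth = 600,
    cn_events = data.frame(amplicon_index = c(3L, 9L), factor = c(2, 0.5)),
    n_germline = 8L, n_somatic = 6L,
    fp_rate = c(kitA = 0.2, kitB = 8),
    ...
  )
}

# minimal VCF fixture used by the reader tests
fixture_vcf_lines <- function() {
  c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="depth">',
    '##INFO=<ID=DP4,Number=4,Type=Integer,Description="strand counts">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="allele freq">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t150\t.\tG\tA\t60\tPASS\tDP=100;DP4=30,30,20,20",
    "chr1\t400\t.\tC\tT\t60\tPASS\tDP=80;AF=0.25",
    "chr2\t90\t.\tA\tAT\t60\tPASS\tDP=120;DP4=40,40,20,20",
    "chr2\t200\t.\tT\tC,G\t60\tPASS\tDP=200;DP4=60,60,40,40;AF=0.4,0.1"
  )
}
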