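calls_at <- function(pos, vaf, sample_id = "s", depth = 200L) {
  make_calls(rep("chr1", length(pos)), pos, rep("G", length(pos)),
             rep("A", length(pos)), rep(depth, length(pos)), vaf,
             sample_id = sample_id)
}

test_that("replicate VAF noise uses only variants shared by all replicates", {
  r1 <- calls_at(c(10L, 20L, 30L), c(0.4, 0.5, 0.9), "r1")
  r2 <- calls_at(c(10L, 20L, 30L), c(0.5, 0.5, 0.9), "r2")
  r3 <- calls_at(c(10L, 20L), c(0.6, 0.5), "r3")   # variant at 30 missing

  est <- replicate_vaf_noise(list(r1, r2, r3))
  expect_equal(est$n_consistent_variants, 2L)
  expect_equal(unname(est$per_variant_sd["chr1:10:G:A"]), 0.1, tolerance = 1e-9)
  expect_equal(unname(est$per_variant_sd["chr1:20:G:A"]), 0)
  expect_equal(est$mean_sd, 0.05, tolerance = 1e-9)
  expect_equal(est$suggested_threshold, 0.05)

  ident <- replicate_vaf_noise(list(r1, r1, r1))
  expect_equal(ident$mean_sd, 0)

  expect_error(replicate_vaf_noise(list(r1)), "at least 2")
  expect_error(replicate_vaf_noise(list(calls_at(1L, 0.5),
                                        calls_at(2L, 0.5))), "shared")
})

test_that("variant classes follow the reference-presence definitions", {
  normal_ref <- calls_at(c(10L, 20L), c(0.5, 1.0), "nref")
  tumor_ref <- calls_at(c(10L, 20L, 30L), c(0.5, 1.0, 0.3), "tref")
  wga <- calls_at(c(10L, 30L, 40L), c(0.5, 0.3, 0.1), "wga")

  classes <- classify_variants(normal_ref, tumor_ref, wga)
  cls <- stats::setNames(classes$class, classes$key)
  expect_equal(unname(cls["chr1:10:G:A"]), "germline")   # in both refs
  expect_equal(unname(cls["chr1:20:G:A"]), "germline")   # in normal ref
  expect_equal(unname(cls["chr1:30:G:A"]), "somatic")    # tumor ref only
  expect_equal(unname(cls["chr1:40:G:A"]), "wga_created")

  # classes partition: one class per key
  expect_equal(anyDuplicated(classes$key), 0L)
  expect_error(classify_variants(NULL, tumor_ref, wga), "reference")
})

test_that("delta-VAF records carry bias flags, directions, and definitions", {
  ref <- calls_at(c(1L, 2L, 3L), c(0.50, 0.50, 0.52), "ref")
  wga <- calls_at(c(1L, 2L, 3L, 4L), c(0.50, 0.60, 0.56, 0.12), "wga")
  classes <- classify_variants(ref, ref, wga)
  rec <- delta_vaf(wga, ref, classes, threshold = 0.05,
                   kit = "kitB", tissue = "normal")

  expect_equal(rec$delta[rec$key == "chr1:1:G:A"], 0)
  expect_false(rec$biased[rec$key == "chr1:1:G:A"])
  expect_equal(rec$delta[rec$key == "chr1:2:G:A"], 0.10)
  expect_equal(rec$direction[rec$key == "chr1:2:G:A"], "positive")
  expect_equal(rec$delta[rec$key == "chr1:3:G:A"], 0.04, tolerance = 1e-9)
  expect_false(rec$biased[rec$key == "chr1:3:G:A"])     # below 0.05
  # created variant: no reference VAF, biased by definition
  created <- rec[rec$key == "chr1:4:G:A", ]
  expect_true(is.na(created$vaf_ref))
  expect_true(created$biased)
  expect_equal(created$direction, "positive")
  expect_equal(created$class, "wga_created")
})

test_that("delta is antisymmetric and the biased set shrinks with the threshold", {
  set.seed(21)
  a <- calls_at(1:12, runif(12, 0.1, 0.9), "a")
  b <- calls_at(1:12, runif(12, 0.1, 0.9), "b")
  classes <- classify_variants(a, a, b)
  fwd <- delta_vaf(b, a, classes)
  bwd <- delta_vaf(a, b, classify_variants(b, b, a))
  m <- match(fwd$key, bwd$key)
  expect_equal(fwd$delta, -bwd$delta[m], tolerance = 1e-12)

  n_biased <- vapply(c(0.02, 0.05, 0.1, 0.2),
                     function(th) sum(delta_vaf(b, a, classes, threshold = th)$biased),
                     0)
  expect_true(all(diff(n_biased) <= 0))
})

test_that("Mann-Whitney enumeration agrees with wilcox.test when tie-free", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(9)
  for (i in 1:15) {
    x <- runif(4); y <- runif(4)
    got <- mann_whitney(x, y)
    expect_true(got$exact)
    expect_equal(got$p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # complete separation of two groups of five: smallest attainable p
  expect_equal(mann_whitney(c(0, 0, 0, 0, 1), c(26, 26, 28, 30, 30))$p,
               2 / choose(10, 5), tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("per-class biased counts are compared with zero-filled rosters", {
  counts <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "b3"),
    kit = c("kitA", "kitA", "kitB", "kitB", "kitB"),
    tissue = "tumor",
    class = "wga_created",
    n_biased = c(1L, 0L, 26L, 28L, 30L),
    stringsAsFactors = FALSE
  )
  cmp <- biased_count_comparison(counts, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  wrow <- cmp[cmp$class == "wga_created", ]
  expect_equal(wrow$n_kitA, 3L)            # a3 counted as zero
  expect_equal(wrow$mean_kitA, 1 / 3)
  expect_equal(wrow$mean_kitB, 28)
  expect_equal(wrow$p, 2 / choose(6, 3), tolerance = 1e-12)  # separation
  # classes with no biased calls anywhere give p = 1
  expect_equal(cmp$p[cmp$class == "germline"], 1)
})

test_that("VAF concordance matches closed-form least squares", {
  x <- calls_at(1:5, c(0.1, 0.2, 0.4, 0.6, 0.9), "x")
  expect_equal(vaf_concordance(x, x)$slope, 1, tolerance = 1e-12)
  expect_equal(vaf_concordance(x, x)$r_squared, 1, tolerance = 1e-12)

  y <- x
  y$vaf <- 0.5 * x$vaf
  fit <- vaf_concordance(x, y)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(14)
  xs <- calls_at(1:20, runif(20, 0.05, 0.95), "xs")
  ys <- calls_at(1:20, pmin(0.99, pmax(0.01, 0.8 * xs$vaf + rnorm(20, 0, 0.05))), "ys")
  fit <- vaf_concordance(xs, ys)
  orc <- oracle_ols(xs$vaf, ys$vaf)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-9)

  expect_error(vaf_concordance(calls_at(1:2, c(0.1, 0.2)),
                               calls_at(1:2, c(0.1, 0.2))), "3 shared")
})
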