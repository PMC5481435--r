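biased_records <- function(ref, alt, kit, class = "wga_created") {
  n <- length(ref)
  data.frame(
    key = if (n) paste0("chr1:", seq_len(n), ":", ref, ":", alt) else character(0),
    ref = ref, alt = alt, class = rep(class, length.out = n),
    vaf_test = rep(0.2, n), vaf_ref = rep(NA_real_, n),
    delta = rep(NA_real_, n), biased = rep(TRUE, n),
    direction = rep("positive", n), kit = kit,
    tissue = rep("tumor", n), sample_id = rep("s", n),
    stringsAsFactors = FALSE
  )
}

test_that("substitution types are the 12 ordered pairs and validate input", {
  expect_length(substitution_types(), 12L)
  expect_equal(substitution_type("G", "A"), "G>A")
  expect_equal(substitution_type("C", "T"), "C>T")
  expect_error(substitution_type("A", "A"), "differ")
  expect_error(substitution_type("N", "A"), "single bases")
})

test_that("spectrum tabulation counts by type and conserves totals", {
  empty <- tabulate_spectrum(biased_records(character(0), character(0), character(0)),
                             "wga_created")
  expect_true(all(empty$count == 0L))

  rec <- biased_records(c("G", "G", "G", "T"), c("A", "A", "A", "C"), "kitB")
  tab <- tabulate_spectrum(rec, "wga_created")
  expect_equal(tab$count[tab$substitution == "G>A"], 3L)
  expect_equal(tab$count[tab$substitution == "T>C"], 1L)
  expect_equal(sum(tab$count), nrow(rec))
  bc <- base_counts(tab)
  expect_equal(bc$count[bc$base == "G"], 3L)
  expect_equal(bc$count[bc$base == "T"], 1L)

  # strata: germline_plus_somatic excludes created; all_altered pools both
  mixed <- rbind(biased_records("G", "A", "kitB", "germline"),
                 biased_records("C", "T", "kitB", "wga_created"))
  expect_equal(sum(tabulate_spectrum(mixed, "germline_plus_somatic")$count), 1L)
  expect_equal(sum(tabulate_spectrum(mixed, "wga_created")$count), 1L)
  expect_equal(sum(tabulate_spectrum(mixed, "all_altered")$count), 2L)

  # random records vs an independent tally
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 200L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  kit <- sample(c("kitA", "kitB"), 200L, replace = TRUE)
  rec <- biased_records(ref, alt, kit)
  tab <- tabulate_spectrum(rec, "all_altered")
  indep <- table(paste(kit, ref, alt))
  for (i in seq_len(nrow(tab))) {
    nm <- paste(tab$kit[i], substr(tab$substitution[i], 1, 1),
                substr(tab$substitution[i], 3, 3))
    expected <- if (nm %in% names(indep)) unname(indep[nm]) else 0L
    expect_equal(tab$count[i], as.integer(expected))
  }
})

test_that("two-count z-test: symmetry, monotonicity, degenerate input", {
  expect_equal(count_z_test(5, 5)$z, 0)
  expect_equal(count_z_test(5, 5)$p_two_tailed, 1)

  for (ab in list(c(7, 1), c(12, 3), c(56, 16))) {
    f <- count_z_test(ab[1], ab[2])
    r <- count_z_test(ab[2], ab[1])
    expect_equal(f$p_two_tailed, r$p_two_tailed)
    expect_equal(f$z, -r$z)
  }

  # |z| grows with |a - b| at fixed a + b
  zs <- vapply(0:10, function(a) abs(count_z_test(a, 20 - a)$z), 0)
  expect_true(all(diff(zs) <= 1e-12))  # a from 0..10 approaches balance

  expect_equal(suppressMessages(count_z_test(0, 0))$p_two_tailed, 1)
  expect_true(suppressMessages(count_z_test(0, 0))$degenerate)
  expect_error(count_z_test(-1, 2))

  # full-precision option matches the closed form directly
  full <- count_z_test(7, 1, z_digits = NULL)
  expect_equal(full$p_two_tailed, 2 * pnorm(-6 / sqrt(8)), tolerance = 1e-12)
})

test_that("kit-vs-kit spectrum tests cover all 12 types", {
  rec <- rbind(biased_records(rep("G", 7), rep("A", 7), "kitB"),
               biased_records("G", "A", "kitA"))
  cmp <- spectrum_comparison(tabulate_spectrum(rec, "wga_created"))
  expect_equal(nrow(cmp), 12L)
  ga <- cmp[cmp$substitution == "G>A", ]
  expect_equal(ga$count_a, 7L)
  expect_equal(ga$count_b, 1L)
  expect_equal(ga$p, count_z_test(7, 1)$p_two_tailed)
  expect_true(all(cmp$p[cmp$count_a + cmp$count_b == 0] == 1))
})

test_that("C:G>T:A pooling happens only at the fraction stage", {
  rec <- biased_records(c("G", "G", "C", "T"), c("A", "A", "T", "C"), "kitB")
  tab <- tabulate_spectrum(rec, "wga_created")
  expect_equal(cgta_fraction(tab, "kitB"), 3 / 4)

  none <- biased_records(c("A", "T"), c("G", "C"), "kitB")
  expect_equal(cgta_fraction(tabulate_spectrum(none, "wga_created"), "kitB"), 0)

  uniform <- biased_records(
    ref = substr(substitution_types(), 1, 1),
    alt = substr(substitution_types(), 3, 3), kit = "kitB"
  )
  expect_equal(cgta_fraction(tabulate_spectrum(uniform, "wga_created")), 2 / 12)

  expect_error(cgta_fraction(tabulate_spectrum(none[0L, ], "wga_created")),
               "zero total")
})
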