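test_that("simulated panels are valid, sized, and deterministic under seed", {
  p97 <- simulate_panel(97L, seed = 4L)
  expect_equal(nrow(p97), 97L)
  expect_equal(p97, simulate_panel(97L, seed = 4L))
  expect_false(identical(p97, simulate_panel(97L, seed = 5L)))
  expect_equal(nrow(simulate_panel(2L, seed = 1L)), 2L)

  widths <- p97$end - p97$start + 1L
  expect_true(all(widths >= 120L & widths <= 180L))
  # non-overlapping within chromosome
  for (ch in unique(p97$chrom)) {
    sub <- p97[p97$chrom == ch, ]
    if (nrow(sub) > 1L) {
      expect_true(all(sub$start[-1L] > sub$end[-nrow(sub)]))
    }
  }
})

test_that("depth simulation applies dispersion and tumor-only CN events", {
  cfg <- small_config()
  cfg$depth_sigma[] <- 0
  panel <- simulate_panel(cfg$n_amplicons, seed = 2L)
  cfg$cn_events <- data.frame(amplicon_index = integer(), factor = double())
  d <- simulate_depths(panel, list(tissue = "normal", preservation = "ffpe",
                                   wga = "none"), cfg)
  expect_equal(unname(d), rep(cfg$mean_depth, cfg$n_amplicons))

  cfg$cn_events <- data.frame(amplicon_index = 5L, factor = 2)
  dt <- simulate_depths(panel, list(tissue = "tumor", preservation = "ffpe",
                                    wga = "none"), cfg)
  expect_equal(unname(dt[5L]), 2 * cfg$mean_depth)
  dn <- simulate_depths(panel, list(tissue = "normal", preservation = "ffpe",
                                    wga = "none"), cfg)
  expect_equal(unname(dn[5L]), cfg$mean_depth)  # normal tissue untouched

  # empirical log-depth SD recovers sigma within 20%
  cfg2 <- small_config()
  set.seed(8)
  draws <- replicate(200, {
    sd(log(simulate_depths(panel, list(tissue = "normal",
                                       preservation = "ffpe", wga = "kitB"),
                           cfg2)))
  })
  expect_equal(mean(draws), cfg2$depth_sigma[["kitB"]], tolerance = 0.2)
})

test_that("variant simulation respects truth sharing and kit FP rates", {
  cfg <- small_config()
  panel <- simulate_panel(cfg$n_amplicons, seed = 3L)
  set.seed(10)
  truth <- simulate_truth(panel, cfg)
  expect_equal(sum(truth$class == "germline"), cfg$n_germline)
  expect_equal(sum(truth$class == "somatic"), cfg$n_somatic)

  # no noise, no FPs: WGA tumor calls carry exactly the truth keys, and
  # VAFs sit at the true values up to read-sampling error
  quiet <- cfg
  quiet$replicate_vaf_sd <- 0
  quiet$kit_shift_sd[] <- 0
  quiet$fp_rate[] <- 0
  sim <- simulate_variants(panel, list(tissue = "tumor", preservation = "ffpe",
                                       wga = "kitA"), truth, quiet, "s1")
  expect_setequal(paste(sim$calls$chrom, sim$calls$pos),
                  paste(truth$chrom, truth$pos))
  m <- match(paste(sim$calls$chrom, sim$calls$pos),
             paste(truth$chrom, truth$pos))
  se <- sqrt(truth$true_vaf[m] * (1 - truth$true_vaf[m]) / sim$calls$depth)
  expect_true(all(abs(sim$calls$vaf - truth$true_vaf[m]) <= 5 * se + 1e-12))

  # normal samples omit somatic truths
  simn <- simulate_variants(panel, list(tissue = "normal", preservation = "ffpe",
                                        wga = "none"), truth, quiet, "s2")
  expect_equal(nrow(simn$calls), cfg$n_germline)

  # created-variant count recovers the Poisson mean over 50 samples
  fp_n <- replicate(50, {
    nrow(simulate_variants(panel, list(tissue = "tumor", preservation = "ffpe",
                                       wga = "kitB"), truth, cfg, "s")$fp_truth)
  })
  rate <- cfg$fp_rate[["kitB"]]
  expect_lt(abs(mean(fp_n) - rate), 3 * sqrt(rate / 50))

  # created-variant spectrum is deamination-dominated as configured
  types <- replicate(40, {
    fp <- simulate_variants(panel, list(tissue = "tumor", preservation = "ffpe",
                                        wga = "kitB"), truth, cfg, "s")$fp_truth
    paste0(fp$ref, ">", fp$alt)
  })
  types <- unlist(types)
  share <- mean(types %in% c("G>A", "C>T"))
  p0 <- 0.92
  expect_lt(abs(share - p0), 3 * sqrt(p0 * (1 - p0) / length(types)))
})

test_that("a full study is deterministic, well-formed, and round-trips", {
  cfg <- small_config(seed = 6L)
  study <- simulate_study(cfg)
  expect_s3_class(study$sample_sheet, "data.frame")
  # three sets; LC1 in triplicate; EC1 on two panels
  sheet <- study$sample_sheet
  expect_setequal(unique(sheet$set_id), c("LC1", "LC2", "EC1"))
  expect_equal(sort(unique(sheet$replicate[sheet$set_id == "LC1"])), 1:3)
  expect_equal(length(unique(sheet$panel_id[sheet$set_id == "EC1"])), 2L)

  study2 <- simulate_study(cfg)
  expect_equal(study, study2)

  dir <- tempfile()
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(back$sample_sheet, sheet)
  expect_equal(back$panels, study$panels)
  sid <- sheet$sample_id[10L]
  expect_equal(back$depths[[sid]], study$depths[[sid]])
  expect_equal(back$variants[[sid]], study$variants[[sid]])
})

test_that("the pipeline runs end-to-end on simulated data", {
  study <- simulate_study(small_config(seed = 12L))
  run <- run_pipeline(study)
  expect_s3_class(run, "wga_run")
  expect_gt(nrow(run$records), 0L)
  # every record in a WGA sample has exactly one class
  expect_true(all(run$records$class %in% c("germline", "somatic", "wga_created")))
  # kitB exceeds kitA in created variants by construction
  created <- run$counts[run$counts$class == "wga_created", ]
  expect_gt(sum(created$n_biased[created$kit == "kitB"]),
            sum(created$n_biased[created$kit == "kitA"]))
  expect_true(all(c("contrast", "p") %in% names(run$comparisons)))
})
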