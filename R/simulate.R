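#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults emulate the study
#' design the pipeline targets: a 97-amplicon panel sequenced to a mean
#' depth around 1500x; library-prep VAF noise with per-variant SD around
#' 0.025 (between the 0.0316 and 0.0219 observed in normal and tumor
#' replicate preps); 14 germline and 11 somatic true variants; amplicon
#' depth dispersion that grows from non-WGA (lognormal sigma 0.05) through
#' the hybrid PCR kit ("kitA", 0.25) to the MDA kit ("kitB", 0.60); kit VAF
#' shifts with SD 0.04 (kitA) and 0.09 (kitB); and false-positive creation
#' rates of 0.2 (kitA) and 28 (kitB) variants per sample, with a
#' deamination-dominated substitution spectrum (G>A 0.55 + C>T 0.37, so
#' the pooled C:G>T:A share is 0.92).
#'
#' @param seed integer RNG seed.
#' @param n_amplicons amplicons on the main panel.
#' @param n_amplicons_alt amplicons on the secondary panel used for one
#'   sample set.
#' @param mean_depth mean on-target depth in reads.
#' @param depth_sigma named numeric: multiplicative lognormal depth SD for
#'   `none`, `kitA`, `kitB`.
#' @param cn_events data.frame with columns `amplicon_index` and `factor`:
#'   copy-number events planted in tumor samples.
#' @param n_germline,n_somatic number of true germline/somatic variants.
#' @param het_fraction probability that a germline variant is heterozygous
#'   (true VAF 0.5) rather than homozygous (true VAF 1).
#' @param somatic_vaf_range range of true somatic VAFs (uniform).
#' @param replicate_vaf_sd per-replicate additive VAF noise SD.
#' @param kit_shift_sd named numeric: extra additive VAF shift SD per kit.
#' @param fp_rate named numeric: Poisson mean of WGA-created variants per
#'   sample per kit.
#' @param fp_spectrum named numeric over the 12 substitution types, summing
#'   to 1: distribution of created-variant substitutions.
#' @param fp_vaf_range range of true created-variant VAFs (uniform); the
#'   default 0.05-0.25 keeps them above the 0.04 VAF filter while looking
#'   artifactual.
#' @param ffpe_extra_fp_rate Poisson mean of fixation-induced false
#'   positives added to non-WGA FFPE samples (default 0: FFPE alone shows
#'   none or minimal bias; raise to stress-test).
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_amplicons = 97L,
                              n_amplicons_alt = 74L,
                              mean_depth = 1500,
                              depth_sigma = c(none = 0.05, kitA = 0.25, kitB = 0.60),
                              cn_events = data.frame(amplicon_index = c(10L, 40L),
                                                     factor = c(2, 0.5)),
                              n_germline = 14L,
                              n_somatic = 11L,
                              het_fraction = 0.6,
                              somatic_vaf_range = c(0.10, 0.60),
                              replicate_vaf_sd = 0.025,
                              kit_shift_sd = c(kitA = 0.04, kitB = 0.09),
                              fp_rate = c(kitA = 0.2, kitB = 28),
                              fp_spectrum = NULL,
                              fp_vaf_range = c(0.05, 0.25),
                              ffpe_extra_fp_rate = 0) {
  if (is.null(fp_spectrum)) {
    types <- substitution_types()
    fp_spectrum <- stats::setNames(rep(0.02 / 9, 12L), types)
    fp_spectrum["G>A"] <- 0.55
    fp_spectrum["C>T"] <- 0.37
    fp_spectrum["C>A"] <- 0.06
  }
  stopifnot(abs(sum(fp_spectrum) - 1) < 1e-9,
            all(depth_sigma >= 0), all(fp_rate >= 0),
            n_germline >= 0, n_somatic >= 0,
            all(c("none", "kitA", "kitB") %in% names(depth_sigma)),
            all(c("kitA", "kitB") %in% names(kit_shift_sd)),
            all(c("kitA", "kitB") %in% names(fp_rate)))
  structure(list(
    seed = as.integer(seed), n_amplicons = as.integer(n_amplicons),
    n_amplicons_alt = as.integer(n_amplicons_alt),
    mean_depth = mean_depth, depth_sigma = depth_sigma,
    cn_events = cn_events, n_germline = as.integer(n_germline),
    n_somatic = as.integer(n_somatic), het_fraction = het_fraction,
    somatic_vaf_range = somatic_vaf_range,
    replicate_vaf_sd = replicate_vaf_sd, kit_shift_sd = kit_shift_sd,
    fp_rate = fp_rate, fp_spectrum = fp_spectrum,
    fp_vaf_range = fp_vaf_range, ffpe_extra_fp_rate = ffpe_extra_fp_rate
  ), class = "sim_config")
}

#' Simulate an amplicon panel
#'
#' Non-overlapping target intervals of 120-180 bp laid out along synthetic
#' chromosomes with random inter-amplicon gaps, mimicking a single-pool
#' PCR panel. Deterministic under `seed`.
#'
#' @param n_amplicons number of amplicons (>= 2).
#' @param seed RNG seed, or `NULL` to draw from the current RNG state.
#' @param panel_prefix prefix for amplicon ids.
#' @return an [amplicon_panel()].
#' @export
simulate_panel <- function(n_amplicons = 97L, seed = NULL, panel_prefix = "amp") {
  stopifnot(n_amplicons >= 2L)
  with_rng(seed, {
    n_chrom <- min(8L, n_amplicons)
    chrom_of <- sort(rep_len(sprintf("chr%02d", seq_len(n_chrom)), n_amplicons))
    widths <- sample(120:180, n_amplicons, replace = TRUE)
    gaps <- sample(200:2000, n_amplicons, replace = TRUE)
    start <- integer(n_amplicons)
    pos <- 0L
    cur <- ""
    for (i in seq_len(n_amplicons)) {
      if (chrom_of[i] != cur) {
        cur <- chrom_of[i]
        pos <- 1000L
      }
      start[i] <- pos + gaps[i]
      pos <- start[i] + widths[i]
    }
    amplicon_panel(
      sprintf("%s_%03d", panel_prefix, seq_len(n_amplicons)),
      chrom_of, start, start + widths - 1L
    )
  })
}

sigma_for <- function(cfg, wga) unname(cfg$depth_sigma[[if (wga == "none") "none" else wga]])

#' Simulate a per-amplicon depth profile
#'
#' `depth[i] = mean_depth * cn_factor[i] * exp(N(0, sigma^2))` where
#' `sigma` depends on the WGA condition and planted copy-number factors
#' apply to tumor samples only. Draws from the current RNG state.
#'
#' @param panel an [amplicon_panel()].
#' @param condition list with elements `tissue`, `preservation`, `wga`.
#' @param cfg a [simulation_config()].
#' @return named numeric depth vector over the panel.
#' @export
simulate_depths <- function(panel, condition, cfg) {
  n <- nrow(panel)
  sigma <- sigma_for(cfg, condition$wga)
  cn <- rep(1, n)
  if (condition$tissue == "tumor" && nrow(cfg$cn_events)) {
    idx <- cfg$cn_events$amplicon_index
    ok <- idx >= 1L & idx <= n
    cn[idx[ok]] <- cfg$cn_events$factor[ok]
  }
  d <- cfg$mean_depth * cn * exp(rnorm(n, 0, sigma))
  stats::setNames(d, panel$amplicon_id)
}

# All 1-based positions covered by the panel, as a data.frame(chrom, pos).
panel_positions <- function(panel) {
  widths <- panel$end - panel$start + 1L
  data.frame(
    chrom = rep(panel$chrom, widths),
    pos = unlist(Map(seq.int, panel$start, panel$end), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulate the ground-truth variants of one sample set
#'
#' Draws germline and somatic variant positions on the panel with their
#' true VAFs: germline variants are heterozygous (VAF 0.5) with probability
#' `het_fraction`, homozygous (VAF 1) otherwise; somatic VAFs are uniform
#' over `somatic_vaf_range`.
#'
#' @param panel an [amplicon_panel()].
#' @param cfg a [simulation_config()].
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `true_vaf`.
#' @export
simulate_truth <- function(panel, cfg) {
  positions <- panel_positions(panel)
  n_var <- cfg$n_germline + cfg$n_somatic
  stopifnot(n_var <= nrow(positions))
  pick <- sample.int(nrow(positions), n_var)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  cls <- c(rep("germline", cfg$n_germline), rep("somatic", cfg$n_somatic))
  true_vaf <- c(
    ifelse(runif(cfg$n_germline) < cfg$het_fraction, 0.5, 1.0),
    runif(cfg$n_somatic, cfg$somatic_vaf_range[1L], cfg$somatic_vaf_range[2L])
  )
  data.frame(chrom = positions$chrom[pick], pos = positions$pos[pick],
             ref = ref, alt = unname(alt), class = cls, true_vaf = true_vaf,
             stringsAsFactors = FALSE)
}

# Turn per-variant target VAFs into read-count-level calls: draw a depth,
# binomially sample alternate reads, split both alleles over strands.
realize_calls <- function(chrom, pos, ref, alt, p, sigma, cfg, sample_id) {
  m <- length(pos)
  if (m == 0L) {
    return(variant_calls(data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), depth = integer(), vaf = double(),
      stringsAsFactors = FALSE
    )))
  }
  p <- pmin(pmax(p, 0), 1)
  depth <- pmax(1L, as.integer(round(cfg$mean_depth * exp(rnorm(m, 0, sigma)))))
  alt_n <- rbinom(m, depth, p)
  ref_n <- depth - alt_n
  alt_fwd <- rbinom(m, alt_n, 0.5)
  ref_fwd <- rbinom(m, ref_n, 0.5)
  variant_calls(data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    ref_fwd = ref_fwd, ref_rev = ref_n - ref_fwd,
    alt_fwd = alt_fwd, alt_rev = alt_n - alt_fwd,
    depth = depth, vaf = alt_n / depth,
    sample_id = sample_id, stringsAsFactors = FALSE
  ))
}

#' Simulate the variant calls of one sample
#'
#' Germline truths appear in normal and tumor samples, somatic truths in
#' tumor only; each call's VAF is the true VAF plus replicate library-prep
#' noise, plus an extra kit shift for WGA samples, truncated to `[0, 1]`
#' and then realized as binomial read counts at a lognormally drawn depth
#' (so DP4, depth and VAF are mutually consistent). WGA samples
#' additionally acquire `Poisson(fp_rate)` created variants at unused panel
#' positions, with substitution type drawn from `fp_spectrum` and true VAF
#' uniform over `fp_vaf_range`. Draws from the current RNG state.
#'
#' @param panel an [amplicon_panel()].
#' @param condition list with `tissue`, `preservation`, `wga`.
#' @param truth output of [simulate_truth()] for this set.
#' @param cfg a [simulation_config()].
#' @param sample_id label stored on the calls.
#' @return list with `calls` (a [variant_calls()] data.frame) and
#'   `fp_truth` (data.frame of this sample's realized created variants).
#' @export
simulate_variants <- function(panel, condition, truth, cfg,
                              sample_id = NA_character_) {
  sigma <- sigma_for(cfg, condition$wga)
  present <- truth[truth$class == "germline" |
                     condition$tissue == "tumor", , drop = FALSE]
  p <- present$true_vaf + rnorm(nrow(present), 0, cfg$replicate_vaf_sd)
  if (condition$wga != "none") {
    p <- p + rnorm(nrow(present), 0, unname(cfg$kit_shift_sd[[condition$wga]]))
  }
  calls <- realize_calls(present$chrom, present$pos, present$ref, present$alt,
                         p, sigma, cfg, sample_id)
  fp_rate <- if (condition$wga != "none") {
    unname(cfg$fp_rate[[condition$wga]])
  } else if (condition$preservation == "ffpe") {
    cfg$ffpe_extra_fp_rate
  } else {
    0
  }
  fp_truth <- data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         true_vaf = double(), stringsAsFactors = FALSE)
  if (fp_rate > 0) {
    n_fp <- rpois(1L, fp_rate)
    if (n_fp > 0L) {
      positions <- panel_positions(panel)
      used <- paste(truth$chrom, truth$pos)
      free <- which(!(paste(positions$chrom, positions$pos) %in% used))
      pick <- free[sample.int(length(free), min(n_fp, length(free)))]
      types <- sample(names(cfg$fp_spectrum), length(pick), replace = TRUE,
                      prob = cfg$fp_spectrum)
      fp_truth <- data.frame(
        chrom = positions$chrom[pick], pos = positions$pos[pick],
        ref = substr(types, 1L, 1L), alt = substr(types, 3L, 3L),
        true_vaf = runif(length(pick), cfg$fp_vaf_range[1L], cfg$fp_vaf_range[2L]),
        stringsAsFactors = FALSE
      )
      fp_calls <- realize_calls(fp_truth$chrom, fp_truth$pos, fp_truth$ref,
                                fp_truth$alt, fp_truth$true_vaf, sigma, cfg,
                                sample_id)
      calls <- rbind(calls, fp_calls)
    }
  }
  calls <- calls[order(calls$chrom, calls$pos, method = "radix"), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, fp_truth = fp_truth)
}

#' Simulate a complete paired WGA study
#'
#' Reproduces the full study design: three patient sample sets -- two lung
#' cancer sets (LC1, LC2) on a 97-amplicon panel and one esophageal set
#' (EC1) run on both the 97-amplicon panel and a 74-amplicon panel. Each
#' set/panel combination carries eight conditions: frozen and FFPE, normal
#' and tumor, non-WGA, plus kitA and kitB WGA products of the FFPE samples.
#' Set LC1 is generated in triplicate library preps. Ground truth (true
#' variants with classes and VAFs, planted copy-number events, realized
#' per-sample created variants) is emitted alongside.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `wga_study`: `sample_sheet`, `panels` (named list
#'   of panels), `depths` (named list of depth vectors), `variants` (named
#'   list of call data.frames), `truth` (per set/panel: true variants,
#'   cn_events, per-sample `fp` tables), and `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  with_rng(cfg$seed, {
    panels <- list(
      panelA = simulate_panel(cfg$n_amplicons, seed = NULL, panel_prefix = "ampA"),
      panelB = simulate_panel(cfg$n_amplicons_alt, seed = NULL, panel_prefix = "ampB")
    )
    design <- rbind(
      data.frame(set_id = "LC1", panel_id = "panelA", replicate = rep(1:3, 1),
                 stringsAsFactors = FALSE),
      data.frame(set_id = "LC2", panel_id = "panelA", replicate = 1L,
                 stringsAsFactors = FALSE),
      data.frame(set_id = "EC1", panel_id = "panelA", replicate = 1L,
                 stringsAsFactors = FALSE),
      data.frame(set_id = "EC1", panel_id = "panelB", replicate = 1L,
                 stringsAsFactors = FALSE)
    )
    conditions <- expand.grid(
      preservation = c("frozen", "ffpe"), tissue = c("normal", "tumor"),
      wga = c("none", "kitA", "kitB"),
      stringsAsFactors = FALSE
    )
    # WGA is applied to FFPE DNA only
    conditions <- conditions[conditions$wga == "none" |
                               conditions$preservation == "ffpe", , drop = FALSE]

    sheet_rows <- list()
    depths <- list()
    variants <- list()
    truth <- list()

    for (g in unique(paste(design$set_id, design$panel_id))) {
      parts <- strsplit(g, " ")[[1L]]
      set_id <- parts[1L]; panel_id <- parts[2L]
      panel <- panels[[panel_id]]
      set_truth <- simulate_truth(panel, cfg)
      fp_by_sample <- list()
      reps <- design$replicate[design$set_id == set_id & design$panel_id == panel_id]
      for (rep_i in reps) {
        for (ci in seq_len(nrow(conditions))) {
          cond <- as.list(conditions[ci, ])
          sid <- sprintf("%s_%s_%s_%s_%s_r%d", set_id, panel_id,
                         cond$preservation, cond$tissue, cond$wga, rep_i)
          sheet_rows[[sid]] <- data.frame(
            sample_id = sid, set_id = set_id, panel_id = panel_id,
            tissue = cond$tissue, preservation = cond$preservation,
            wga = cond$wga, replicate = rep_i, stringsAsFactors = FALSE
          )
          depths[[sid]] <- simulate_depths(panel, cond, cfg)
          sim <- simulate_variants(panel, cond, set_truth, cfg, sample_id = sid)
          variants[[sid]] <- sim$calls
          fp_by_sample[[sid]] <- sim$fp_truth
        }
      }
      truth[[g]] <- list(set_id = set_id, panel_id = panel_id,
                         variants = set_truth, cn_events = cfg$cn_events,
                         fp = fp_by_sample)
    }
    sheet <- do.call(rbind, sheet_rows)
    rownames(sheet) <- NULL
    structure(list(sample_sheet = validate_sample_sheet(sheet),
                   panels = panels, depths = depths, variants = variants,
                   truth = truth, config = cfg),
              class = "wga_study")
  })
}

#' Write a simulated study to disk
#'
#' Emits the study in exactly the dialects the readers accept: one BED per
#' panel, a TSV sample sheet, one depth TSV and one variant TSV per sample.
#'
#' @param study a `wga_study` from [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "wga_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(study$panels)) {
    write_panel_bed(study$panels[[pid]], file.path(outdir, paste0(pid, ".bed")))
  }
  write.table(study$sample_sheet, file.path(outdir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (sid in study$sample_sheet$sample_id) {
    write_depth_tsv(study$depths[[sid]],
                    file.path(outdir, paste0(sid, ".depth.tsv")))
    write_variants_tsv(study$variants[[sid]],
                       file.path(outdir, paste0(sid, ".variants.tsv")))
  }
  invisible(outdir)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory containing `samples.tsv`, `<panel>.bed` and
#'   per-sample depth/variant TSVs.
#' @return a `wga_study` (without ground truth, which only the generator
#'   knows).
#' @export
read_study <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  panels <- lapply(
    stats::setNames(nm = unique(sheet$panel_id)),
    function(pid) read_panel_bed(file.path(dir, paste0(pid, ".bed")))
  )
  depths <- lapply(stats::setNames(nm = sheet$sample_id), function(sid) {
    read_depth_tsv(file.path(dir, paste0(sid, ".depth.tsv")))
  })
  variants <- lapply(stats::setNames(nm = sheet$sample_id), function(sid) {
    calls <- read_variants(file.path(dir, paste0(sid, ".variants.tsv")),
                           dialect = "tsv", sample_id = sid)
    calls
  })
  structure(list(sample_sheet = sheet, panels = panels, depths = depths,
                 variants = variants, truth = NULL, config = NULL),
            class = "wga_study")
}
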