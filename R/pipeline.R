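fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

report_header <- function(seed) {
  c(sprintf("# wgabias %s", as.character(utils::packageVersion("wgabias"))),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else seed))
}

write_report_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(seed), con)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (col in names(df)[num]) df[[col]] <- fmt_num(df[[col]])
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline reports
#'
#' Emits one TSV per report (GCN tables, delta-VAF records, substitution
#' spectra) with a fixed column order, deterministic row order and floats
#' at 6 significant digits, each headed by a comment carrying the package
#' version and the run seed. Identical inputs produce byte-identical files.
#'
#' @param gcn named list of `gcn_table`s (names are ignored; sample ids are
#'   taken from the tables' attributes).
#' @param bias data.frame of delta-VAF records ([delta_vaf()]).
#' @param spectra list of `substitution_spectrum` tables.
#' @param outdir output directory (created if needed).
#' @param seed seed recorded in the report headers.
#' @return named character vector of the written paths, invisibly.
#' @export
write_reports <- function(gcn, bias, spectra, outdir, seed = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gcn_df <- do.call(rbind, lapply(gcn, function(tab) {
    data.frame(test_sample_id = attr(tab, "test_sample_id"),
               reference_sample_id = attr(tab, "reference_sample_id"),
               amplicon_id = tab$amplicon_id, gcn = tab$gcn,
               avrt_test = tab$avrt_test, avrt_ref = tab$avrt_ref,
               stringsAsFactors = FALSE)
  }))
  if (is.null(gcn_df)) {
    gcn_df <- data.frame(test_sample_id = character(),
                         reference_sample_id = character(),
                         amplicon_id = character(), gcn = double(),
                         avrt_test = double(), avrt_ref = double())
  }
  gcn_df <- gcn_df[order(gcn_df$test_sample_id, gcn_df$amplicon_id), , drop = FALSE]
  bias_cols <- c("sample_id", "kit", "tissue", "key", "ref", "alt", "class",
                 "vaf_test", "vaf_ref", "delta", "biased", "direction")
  if (nrow(bias)) {
    bias <- bias[order(bias$sample_id, bias$key), bias_cols, drop = FALSE]
  } else {
    bias <- stats::setNames(
      data.frame(matrix(ncol = length(bias_cols), nrow = 0L)), bias_cols)
  }
  spec_df <- do.call(rbind, lapply(spectra, as.data.frame))
  if (is.null(spec_df)) {
    spec_df <- data.frame(kit = character(), stratum = character(),
                          substitution = character(), count = integer())
  }
  spec_df <- spec_df[order(spec_df$stratum, spec_df$kit, spec_df$substitution), ,
                     drop = FALSE]
  paths <- c(
    gcn = file.path(outdir, "gcn.tsv"),
    bias = file.path(outdir, "bias_records.tsv"),
    spectrum = file.path(outdir, "spectrum.tsv")
  )
  write_report_tsv(gcn_df, paths[["gcn"]], seed)
  write_report_tsv(bias, paths[["bias"]], seed)
  write_report_tsv(spec_df, paths[["spectrum"]], seed)
  invisible(paths)
}

ref_id_or_stop <- function(sheet, sid) {
  ref <- find_reference_sample(sheet, sid)
  if (is.na(ref)) stop("no matched non-WGA FFPE reference for ", sid)
  ref
}

#' Run the full bias-quantification pipeline on a study
#'
#' Orchestrates, in fixed order: panel intersection and variant filtering;
#' replicate VAF-noise estimation (on the triplicated non-WGA FFPE
#' samples, when present); GCN normalization of every WGA sample against
#' its matched non-WGA FFPE reference and of every non-WGA FFPE sample
#' against its frozen counterpart; variant classification and delta-VAF
#' records per WGA sample; biased-variant counting; substitution spectra
#' for the three strata; and the cross-condition statistical summary.
#' When `outdir` is given, reports and a JSON manifest (seed, package
#' version, record counts) are written; reruns with the same study and
#' configuration are bit-identical.
#'
#' @param study a `wga_study` from [simulate_study()] or [read_study()].
#' @param filter_cfg a [filter_config()].
#' @param vaf_threshold bias threshold for [delta_vaf()]. Default 0.05.
#' @param dosage_half_width half-width of the normal dosage band.
#'   Default 0.25.
#' @param outdir optional output directory for reports.
#' @param seed seed recorded in the manifest and report headers (the
#'   pipeline itself draws no random numbers).
#' @return list of class `wga_run` with elements `filtered` (named list of
#'   kept call sets), `noise` (replicate VAF noise estimate or `NULL`),
#'   `gcn_tables`, `dosage`, `records` (all delta-VAF records), `counts`
#'   (per-sample biased counts), `spectra` (the three strata),
#'   `spectrum_tests`, `comparisons` (from [compare_conditions()]) and
#'   `paths` (written files, when `outdir` was given).
#' @export
run_pipeline <- function(study, filter_cfg = filter_config(),
                         vaf_threshold = 0.05, dosage_half_width = 0.25,
                         outdir = NULL, seed = NULL) {
  stopifnot(inherits(study, "wga_study"))
  sheet <- study$sample_sheet
  seed <- seed %||% (study$config$seed %||% NULL)

  filtered <- lapply(stats::setNames(nm = sheet$sample_id), function(sid) {
    panel <- study$panels[[sheet$panel_id[sheet$sample_id == sid]]]
    calls <- intersect_panel(study$variants[[sid]], panel)
    filter_variants(calls, filter_cfg)$kept
  })

  # replicate VAF noise from the triplicated non-WGA FFPE samples
  noise <- NULL
  rep_groups <- sheet[sheet$wga == "none" & sheet$preservation == "ffpe", , drop = FALSE]
  key <- paste(rep_groups$set_id, rep_groups$panel_id, rep_groups$tissue)
  for (g in unique(key)) {
    ids <- rep_groups$sample_id[key == g]
    if (length(ids) >= 2L) {
      est <- try(replicate_vaf_noise(filtered[ids]), silent = TRUE)
      if (!inherits(est, "try-error")) {
        est$group <- g
        noise <- c(noise, list(est))
      }
    }
  }

  # GCN: WGA vs matched non-WGA FFPE; non-WGA FFPE vs frozen counterpart
  gcn_tables <- list()
  dosage <- list()
  for (i in seq_len(nrow(sheet))) {
    s <- sheet[i, ]
    panel <- study$panels[[s$panel_id]]
    ref_id <- if (s$wga != "none") {
      ref_id_or_stop(sheet, s$sample_id)
    } else if (s$preservation == "ffpe") {
      frozen <- sheet$sample_id[sheet$set_id == s$set_id &
                                  sheet$panel_id == s$panel_id &
                                  sheet$tissue == s$tissue &
                                  sheet$preservation == "frozen" &
                                  sheet$wga == "none" &
                                  sheet$replicate == s$replicate]
      if (length(frozen)) frozen[1L] else NA_character_
    } else {
      NA_character_
    }
    if (is.na(ref_id)) next
    tab <- normalize_gcn(study$depths[[s$sample_id]], study$depths[[ref_id]],
                         panel, test_sample_id = s$sample_id,
                         reference_sample_id = ref_id)
    gcn_tables[[s$sample_id]] <- tab
    dosage[[s$sample_id]] <- call_dosage(tab, dosage_half_width)
  }

  # classification and delta-VAF per WGA sample
  records <- list()
  grp <- sheet[sheet$wga != "none", , drop = FALSE]
  gkey <- paste(grp$set_id, grp$panel_id, grp$replicate)
  for (g in unique(gkey)) {
    sub <- grp[gkey == g, , drop = FALSE]
    s1 <- sub[1L, ]
    pick_ref <- function(tissue) {
      id <- sheet$sample_id[sheet$set_id == s1$set_id &
                              sheet$panel_id == s1$panel_id &
                              sheet$tissue == tissue &
                              sheet$preservation == "ffpe" &
                              sheet$wga == "none" &
                              sheet$replicate == s1$replicate]
      if (!length(id)) stop("missing non-WGA FFPE ", tissue, " reference in set ",
                            s1$set_id)
      id[1L]
    }
    normal_ref <- pick_ref("normal")
    tumor_ref <- pick_ref("tumor")
    classes <- classify_variants(filtered[[normal_ref]], filtered[[tumor_ref]],
                                 filtered[sub$sample_id])
    for (j in seq_len(nrow(sub))) {
      s <- sub[j, ]
      ref_id <- if (s$tissue == "normal") normal_ref else tumor_ref
      records[[s$sample_id]] <- delta_vaf(
        filtered[[s$sample_id]], filtered[[ref_id]], classes,
        threshold = vaf_threshold, kit = s$wga, tissue = s$tissue
      )
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    delta_vaf(filtered[[1L]][0L, ], filtered[[1L]][0L, ],
              data.frame(key = character(), class = character()),
              threshold = vaf_threshold)
  rownames(records) <- NULL

  counts <- count_biased(records)
  spectra <- list(
    all_altered = tabulate_spectrum(records, "all_altered"),
    germline_plus_somatic = tabulate_spectrum(records, "germline_plus_somatic"),
    wga_created = tabulate_spectrum(records, "wga_created")
  )
  spectrum_tests <- lapply(spectra, spectrum_comparison)

  run <- structure(list(
    study = study, filtered = filtered, noise = noise,
    gcn_tables = gcn_tables, dosage = dosage, records = records,
    counts = counts, spectra = spectra, spectrum_tests = spectrum_tests,
    vaf_threshold = vaf_threshold, seed = seed
  ), class = "wga_run")
  run$comparisons <- compare_conditions(run)

  if (!is.null(outdir)) {
    paths <- write_reports(gcn_tables, records, spectra, outdir, seed = seed)
    manifest <- list(
      package = "wgabias",
      version = as.character(utils::packageVersion("wgabias")),
      seed = seed,
      n_samples = nrow(sheet),
      n_filtered_calls = sum(vapply(filtered, nrow, 0L)),
      n_bias_records = nrow(records),
      vaf_threshold = vaf_threshold,
      files = as.list(basename(paths))
    )
    manifest_path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
    run$paths <- c(paths, manifest = manifest_path)
  }
  run
}

#' Cross-condition statistical summary of a pipeline run
#'
#' One row per contrast: per-class biased-variant counts kitA vs kitB
#' (two-tailed Mann-Whitney on per-sample counts), delta-VAF magnitudes by
#' bias direction kitA vs kitB (Mann-Whitney on `|delta|`), and
#' amplicon-matched GCN range contrasts kitA vs kitB and each kit vs its
#' non-WGA FFPE baseline (Wilcoxon matched-pairs signed-rank, pooled over
#' sets and replicates by averaging per-amplicon GCN within kit). Raw
#' p-values are reported (no multiplicity correction, matching how such
#' panels of contrasts are conventionally read); an optional
#' Benjamini-Hochberg column can be added.
#'
#' @param run a `wga_run` from [run_pipeline()].
#' @param adjust add a Benjamini-Hochberg adjusted-p column. Default
#'   `FALSE`.
#' @return data.frame with columns `contrast`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `statistic`, `p` (and `p_bh` when
#'   `adjust`).
#' @export
compare_conditions <- function(run, adjust = FALSE) {
  stopifnot(inherits(run, "wga_run"))
  sheet <- run$study$sample_sheet
  rows <- list()
  add_row <- function(contrast, group_a, group_b, a, b, stat, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contrast = contrast, group_a = group_a, group_b = group_b,
      n_a = length(a), n_b = length(b),
      mean_a = if (length(a)) mean(a) else NA_real_,
      mean_b = if (length(b)) mean(b) else NA_real_,
      statistic = stat, p = p, stringsAsFactors = FALSE
    )
  }

  ids_a <- sheet$sample_id[sheet$wga == "kitA"]
  ids_b <- sheet$sample_id[sheet$wga == "kitB"]
  if (length(ids_a) && length(ids_b)) {
    bc <- biased_count_comparison(run$counts, ids_a, ids_b)
    for (i in seq_len(nrow(bc))) {
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste0("biased_count_", bc$class[i]),
        group_a = "kitA", group_b = "kitB",
        n_a = bc$n_kitA[i], n_b = bc$n_kitB[i],
        mean_a = bc$mean_kitA[i], mean_b = bc$mean_kitB[i],
        statistic = bc$U[i], p = bc$p[i], stringsAsFactors = FALSE
      )
    }
  }

  rec <- run$records
  for (dir in c("positive", "negative")) {
    a <- abs(rec$delta[rec$kit == "kitA" & rec$direction == dir & !is.na(rec$delta)])
    b <- abs(rec$delta[rec$kit == "kitB" & rec$direction == dir & !is.na(rec$delta)])
    if (length(a) >= 1L && length(b) >= 1L) {
      mw <- mann_whitney(a, b)
      add_row(paste0("delta_vaf_", dir), "kitA", "kitB", a, b, mw$statistic, mw$p)
    } else {
      add_row(paste0("delta_vaf_", dir), "kitA", "kitB", a, b, NA_real_, NA_real_)
      warning("delta_vaf_", dir, " contrast has an empty group; NA row emitted")
    }
  }

  # mean per-amplicon GCN per WGA condition (pooled over samples), matched
  # by amplicon for the signed-rank contrasts
  mean_gcn <- function(ids) {
    tabs <- run$gcn_tables[names(run$gcn_tables) %in% ids]
    if (!length(tabs)) return(NULL)
    m <- sapply(tabs, function(t) stats::setNames(t$gcn, t$amplicon_id)[tabs[[1L]]$amplicon_id])
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L, dimnames = list(tabs[[1L]]$amplicon_id, NULL))
    rowMeans(m)
  }
  ffpe_ids <- sheet$sample_id[sheet$wga == "none" & sheet$preservation == "ffpe"]
  # restrict pooling to the main panel so amplicons match across conditions
  main_panel <- names(run$study$panels)[1L]
  on_main <- function(ids) ids[ids %in% sheet$sample_id[sheet$panel_id == main_panel]]
  g_a <- mean_gcn(on_main(ids_a)); g_b <- mean_gcn(on_main(ids_b))
  g_0 <- mean_gcn(on_main(ffpe_ids))
  pairs <- list(c("kitA", "kitB"), c("nonWGA_ffpe", "kitA"), c("nonWGA_ffpe", "kitB"))
  vals <- list(kitA = g_a, kitB = g_b, nonWGA_ffpe = g_0)
  for (pr in pairs) {
    va <- vals[[pr[1L]]]; vb <- vals[[pr[2L]]]
    if (is.null(va) || is.null(vb)) next
    cmp <- gcn_range_comparison(va, vb[names(va)])
    add_row(paste0("gcn_range_", pr[1L], "_vs_", pr[2L]), pr[1L], pr[2L],
            va, vb, NA_real_, cmp$p)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
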