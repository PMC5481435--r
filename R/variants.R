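#' Construct a table of variant calls
#'
#' The working representation of variant calls is a plain `data.frame` with
#' one row per biallelic SNV and columns `sample_id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev` (the DP4 strand
#' counts, `NA` when the caller did not emit DP4), `depth` and `vaf`.
#' When DP4 is present, `depth` must equal its sum and `vaf` must equal
#' `(alt_fwd + alt_rev) / depth`.
#'
#' @param df a data.frame with the columns above (`sample_id` optional).
#' @return the validated data.frame.
#' @export
variant_calls <- function(df) {
  needed <- c("chrom", "pos", "ref", "alt", "depth", "vaf")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("variant table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_integer_, nrow(df))
  }
  if (is.null(df$sample_id)) df$sample_id <- rep(NA_character_, nrow(df))
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  bases <- c("A", "C", "G", "T")
  if (any(!df$ref %in% bases) || any(!df$alt %in% bases)) {
    stop("variant table contains non-SNV ref/alt alleles; indels must be dropped upstream")
  }
  if (any(df$ref == df$alt)) stop("variant with ref == alt")
  if (any(df$vaf < 0 | df$vaf > 1)) stop("VAF outside [0, 1]")
  has_dp4 <- !is.na(df$alt_fwd)
  if (any(has_dp4)) {
    d <- df[has_dp4, , drop = FALSE]
    dp4_sum <- d$ref_fwd + d$ref_rev + d$alt_fwd + d$alt_rev
    bad <- abs(dp4_sum - d$depth) > 0 |
      abs((d$alt_fwd + d$alt_rev) / dp4_sum - d$vaf) > 1e-9
    if (any(bad)) {
      warning(sum(bad), " call(s) had depth/vaf inconsistent with DP4; DP4 kept authoritative")
      df$depth[has_dp4] <- as.integer(dp4_sum)
      df$vaf[has_dp4] <- (d$alt_fwd + d$alt_rev) / dp4_sum
    }
  }
  cols <- c("sample_id", "chrom", "pos", "ref", "alt",
            "ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "depth", "vaf")
  df <- df[, cols]
  rownames(df) <- NULL
  df
}

#' Read variant calls from a VCF or TSV file
#'
#' The VCF dialect expects the DP4 INFO field (ref-forward, ref-reverse,
#' alt-forward, alt-reverse read counts) as emitted by samtools/bcftools;
#' records without DP4 are kept with `NA` strand counts so the downstream
#' DP4 filter can remove them explicitly. Multi-allelic records are split
#' into one row per alternate allele: the first alternate keeps the
#' DP4-derived depth and VAF, secondary alternates take their VAF from the
#' INFO `AF` field when present and are otherwise dropped with a message.
#' Non-SNV records (indels, symbolic alleles) are skipped with a message.
#'
#' The TSV dialect has columns `chrom`, `pos`, `ref`, `alt`, `depth`, `vaf`
#' and optionally `dp4` (four comma-separated counts).
#'
#' @param path input file path.
#' @param dialect `"vcf"` or `"tsv"`.
#' @param sample_id sample label to attach to every call.
#' @return a [variant_calls()] data.frame.
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv"), sample_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (dialect == "tsv") read_variants_tsv(path, sample_id)
  else read_variants_vcf(path, sample_id)
}

read_variants_tsv <- function(path, sample_id) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("chrom", "pos", "ref", "alt", "depth", "vaf")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("variant TSV ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(df$dp4) && nrow(df)) {
    parts <- strsplit(as.character(df$dp4), ",")
    ok <- lengths(parts) == 4L
    mat <- matrix(NA_integer_, nrow(df), 4L)
    if (any(ok)) {
      mat[ok, ] <- t(vapply(parts[ok], function(p) as.integer(p), integer(4L)))
    }
    df$ref_fwd <- mat[, 1L]; df$ref_rev <- mat[, 2L]
    df$alt_fwd <- mat[, 3L]; df$alt_rev <- mat[, 4L]
  }
  df$dp4 <- NULL
  df$sample_id <- sample_id
  variant_calls(df)
}

read_variants_vcf <- function(path, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  empty <- variant_calls(data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    depth = integer(), vaf = double(), stringsAsFactors = FALSE
  ))
  if (n == 0L) return(empty)
  dp4 <- vcfR::extract.info(vcf, "DP4")
  af <- vcfR::extract.info(vcf, "AF")
  rows <- vector("list", n)
  n_skipped <- 0L
  n_dropped_alt <- 0L
  for (i in seq_len(n)) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",")[[1L]]
    afs <- if (!is.null(af) && !is.na(af[i])) suppressWarnings(as.numeric(strsplit(af[i], ",")[[1L]])) else NULL
    dp4_i <- if (!is.null(dp4) && !is.na(dp4[i])) as.integer(strsplit(dp4[i], ",")[[1L]]) else NULL
    recs <- list()
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (k == 1L && !is.null(dp4_i)) {
        depth <- sum(dp4_i)
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = ref, alt = alt,
          ref_fwd = dp4_i[1L], ref_rev = dp4_i[2L],
          alt_fwd = dp4_i[3L], alt_rev = dp4_i[4L],
          depth = depth, vaf = (dp4_i[3L] + dp4_i[4L]) / depth,
          stringsAsFactors = FALSE
        )
      } else if (k == 1L) {
        dp <- vcfR::extract.info(vcf, "DP")
        depth <- if (!is.null(dp) && !is.na(dp[i])) as.integer(dp[i]) else NA_integer_
        vaf <- if (!is.null(afs) && length(afs) >= 1L) afs[1L] else NA_real_
        if (is.na(depth) || is.na(vaf)) {
          # keep the record: DP4 absence is handled by the explicit filter
          depth <- if (is.na(depth)) 0L else depth
          vaf <- if (is.na(vaf)) 0 else vaf
        }
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = ref, alt = alt,
          ref_fwd = NA_integer_, ref_rev = NA_integer_,
          alt_fwd = NA_integer_, alt_rev = NA_integer_,
          depth = depth, vaf = vaf, stringsAsFactors = FALSE
        )
      } else if (!is.null(afs) && length(afs) >= k && !is.na(afs[k])) {
        dp <- vcfR::extract.info(vcf, "DP")
        depth <- if (!is.null(dp) && !is.na(dp[i])) as.integer(dp[i])
                 else if (!is.null(dp4_i)) sum(dp4_i) else 0L
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = ref, alt = alt,
          ref_fwd = NA_integer_, ref_rev = NA_integer_,
          alt_fwd = NA_integer_, alt_rev = NA_integer_,
          depth = depth, vaf = afs[k], stringsAsFactors = FALSE
        )
      } else {
        n_dropped_alt <- n_dropped_alt + 1L
      }
    }
    rows[[i]] <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  if (n_skipped) message(n_skipped, " non-SNV record(s) skipped in ", path)
  if (n_dropped_alt) {
    message(n_dropped_alt, " secondary alternate allele(s) without AF dropped in ", path)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$sample_id <- sample_id
  variant_calls(out)
}

#' Write variant calls in the TSV dialect
#'
#' Writes the columns `chrom`, `pos`, `ref`, `alt`, `depth`, `vaf`, `dp4`
#' (four comma-separated counts, empty when absent). VAF is written at full
#' double precision so that write-then-read round-trips exactly.
#'
#' @param calls a [variant_calls()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(calls, path) {
  dp4 <- ifelse(is.na(calls$alt_fwd), "",
                paste(calls$ref_fwd, calls$ref_rev, calls$alt_fwd, calls$alt_rev,
                      sep = ","))
  out <- data.frame(
    chrom = calls$chrom, pos = calls$pos, ref = calls$ref, alt = calls$alt,
    depth = calls$depth, vaf = sprintf("%.17g", calls$vaf), dp4 = dp4,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-amplicon depth tables
#'
#' A depth profile is a named numeric vector of mean on-target depths, one
#' entry per amplicon. On disk it is a two-column TSV
#' (`amplicon_id <TAB> depth`).
#'
#' @param path input/output path.
#' @return `read_depth_tsv`: a named numeric vector of depths.
#' @export
read_depth_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("amplicon_id", "depth") %in% names(df))) {
    stop("depth table ", path, " needs columns amplicon_id and depth")
  }
  if (any(df$depth < 0)) stop("negative depth in ", path)
  stats::setNames(as.numeric(df$depth), df$amplicon_id)
}

#' @param depths named numeric vector of per-amplicon depths.
#' @rdname read_depth_tsv
#' @export
write_depth_tsv <- function(depths, path) {
  out <- data.frame(amplicon_id = names(depths),
                    depth = sprintf("%.17g", unname(depths)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet describes each sequenced library: `sample_id`, `set_id`
#' (patient sample set, e.g. LC1), `panel_id`, `tissue` (`normal`/`tumor`),
#' `preservation` (`frozen`/`ffpe`), `wga` (`none`, `kitA` for the hybrid
#' PCR-based kit, `kitB` for the MDA kit) and `replicate` (integer, library
#' prep replicate). Every WGA sample must have a matched non-WGA FFPE sample
#' of the same tissue, set, panel and replicate: its reference for both GCN
#' normalization and delta-VAF.
#'
#' @param path TSV file with the columns above.
#' @return a validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_sheet(df)
}

#' @param sheet a sample-sheet data.frame.
#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "set_id", "panel_id", "tissue", "preservation",
              "wga", "replicate")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet")
  stopifnot(all(sheet$tissue %in% c("normal", "tumor")),
            all(sheet$preservation %in% c("frozen", "ffpe")),
            all(sheet$wga %in% c("none", "kitA", "kitB")))
  wga <- sheet[sheet$wga != "none", , drop = FALSE]
  if (nrow(wga)) {
    for (i in seq_len(nrow(wga))) {
      ref <- find_reference_sample(sheet, wga$sample_id[i])
      if (is.na(ref)) {
        stop("WGA sample ", wga$sample_id[i],
             " has no matched non-WGA FFPE reference sample")
      }
    }
  }
  sheet
}

#' Locate the matched non-WGA FFPE reference for a WGA sample
#'
#' The reference is the non-amplified FFPE sample of the same tissue, sample
#' set, panel and replicate.
#'
#' @param sheet a sample sheet.
#' @param sample_id id of a WGA sample.
#' @return the reference `sample_id`, or `NA` if none exists.
#' @export
find_reference_sample <- function(sheet, sample_id) {
  s <- sheet[sheet$sample_id == sample_id, , drop = FALSE]
  if (nrow(s) != 1L) stop("unknown sample_id: ", sample_id)
  ref <- sheet[sheet$set_id == s$set_id & sheet$panel_id == s$panel_id &
                 sheet$tissue == s$tissue & sheet$preservation == "ffpe" &
                 sheet$wga == "none" & sheet$replicate == s$replicate, , drop = FALSE]
  if (nrow(ref) == 0L) NA_character_ else ref$sample_id[1L]
}
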