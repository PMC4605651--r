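# Pipeline driver: consensus -> annotation -> subsample -> collapse ->
# summary per sample, cohort statistics against clinical metadata, and the
# on-disk artifact/manifest layer.

#' Process one sample from read pairs to a repertoire summary
#'
#' Runs UID extraction, consensus calling, annotation, depth subsampling and
#' clone collapsing for a single sample held in memory.
#'
#' @param reads data.frame with seq1, qual1, seq2, qual2 (e.g. from
#'   [synthesize_reads()] or [read_paired_fastq()]).
#' @param refs Germline references ([make_germline_refs()] or equivalent).
#' @param config A [pipeline_config()].
#' @param sample_id Sample identifier (also seeds the subsampling).
#' @return List of class `sample_result`: consensus and annotated-molecule
#'   tables, the subsampled molecule table (or `sample_discarded`), the
#'   clone table, the `repertoire_summary` (NULL when discarded), and a
#'   `tally` of read/molecule accounting.
#' @export
process_sample <- function(reads, refs, config = pipeline_config(),
                           sample_id = "sample") {
  extracted <- extract_uid_and_trim(reads$seq1, reads$seq2, reads$qual1,
                                    reads$qual2, primers = refs$primers,
                                    uid_len_each = config$uid_len_each,
                                    max_primer_mismatches =
                                      config$max_primer_mismatches)
  consensus <- build_consensus_table(extracted)
  molecules <- annotate_molecules(consensus, refs, config$align,
                                  config$mutated_igm_min_rate)
  sub <- subsample_molecules(molecules, depth = config$subsample_depth,
                             sample_id = sample_id)
  tally <- c(attr(consensus, "tally"), attr(molecules, "tally"))
  if (inherits(sub, "sample_discarded")) {
    out <- list(sample_id = sample_id, consensus = consensus,
                molecules = molecules, subsampled = sub, clones = NULL,
                summary = NULL, discarded = TRUE, tally = tally)
  } else {
    clones <- collapse_clones(sub)
    out <- list(sample_id = sample_id, consensus = consensus,
                molecules = molecules, subsampled = sub, clones = clones,
                summary = repertoire_summary(clones, sample_id,
                                             config$highly_expressed_min),
                discarded = FALSE, tally = tally)
  }
  class(out) <- "sample_result"
  out
}

#' @export
print.sample_result <- function(x, ...) {
  if (x$discarded) print(x$subsampled) else print(x$summary)
  invisible(x)
}

#' Cohort-level diagnostic statistics
#'
#' Joins per-sample ABS levels to clinical metadata and computes the
#' cohort statistics: Pearson correlation of ABS with tacrolimus (Fisher
#' r-to-z CI), one-sided Mann-Whitney tests of each rejection category
#' against the non-rejection group, ROC c-statistics of ABS against
#' cfdDNA-defined and biopsy-defined rejection, threshold metrics at the
#' configured ABS cutoff, and pre-rejection exponential trend fits (time
#' aligned at the event, samples within the configured window).
#'
#' @param cohort data.frame with sample_id, patient, day, abs_level.
#' @param metadata data.frame from [read_metadata()] (sample_id, tacrolimus,
#'   biopsy_grade, cfddna_pct, ...).
#' @param config A [pipeline_config()].
#' @return List of class `cohort_statistics`.
#' @export
cohort_statistics <- function(cohort, metadata, config = pipeline_config()) {
  m <- merge(cohort, metadata[, setdiff(names(metadata),
                                        c("patient", "day"))],
             by = "sample_id", sort = TRUE)
  cats <- lapply(seq_len(nrow(m)), function(i) {
    if (is.na(m$biopsy_grade[i]) && is.na(m$cfddna_pct[i])) return("unclassifiable")
    classify_rejection(m$biopsy_grade[i], m$cfddna_pct[i],
                       config$cfddna_threshold)
  })
  has <- function(lbl) vapply(cats, function(x) lbl %in% x, logical(1))
  none <- has("none")
  groups <- list(mild_ACR = has("mild_ACR"),
                 mod_severe_ACR = has("mod_severe_ACR"),
                 elevated_cfdDNA = has("elevated_cfdDNA"))
  group_tests <- lapply(groups, function(g) {
    if (!any(g) || !any(none)) return(NULL)
    mann_whitney_one_sided(m$abs_level[g], m$abs_level[none])
  })
  tac_cor <- {
    ok <- is.finite(m$tacrolimus) & is.finite(m$abs_level)
    if (sum(ok) >= 4 && stats::sd(m$tacrolimus[ok]) > 0) {
      pearson_with_fisher_ci(m$abs_level[ok], m$tacrolimus[ok])
    } else NULL
  }
  roc_vs <- function(lab) {
    if (!any(lab, na.rm = TRUE) || all(lab, na.rm = TRUE)) return(NULL)
    keep <- !is.na(lab)
    roc_c_statistic(m$abs_level[keep], lab[keep], n_boot = config$n_boot,
                    seed = config$boot_seed)
  }
  lab_cfddna <- ifelse(is.na(m$cfddna_pct), NA,
                       m$cfddna_pct > config$cfddna_threshold)
  lab_biopsy <- ifelse(is.na(m$biopsy_grade), NA,
                       m$biopsy_grade %in% c("2R", "3R"))
  roc_cfddna <- roc_vs(lab_cfddna)
  roc_biopsy <- roc_vs(lab_biopsy)
  metrics <- if (!is.null(roc_cfddna)) {
    keep <- !is.na(lab_cfddna)
    binary_metrics_at_threshold(m$abs_level[keep], lab_cfddna[keep],
                                threshold = config$abs_threshold)
  } else NULL
  # pre-rejection trend: each patient's first rejection-positive day
  event_day <- tapply(seq_len(nrow(m)), m$patient, function(i) {
    pos <- i[(!is.na(lab_cfddna[i]) & lab_cfddna[i]) |
               (!is.na(lab_biopsy[i]) & lab_biopsy[i])]
    if (length(pos)) min(m$day[pos]) else NA_real_
  })
  t_rel <- m$day - unname(event_day[m$patient])
  w <- config$prerejection_window
  pre <- !is.na(t_rel) & t_rel >= w[1] & t_rel <= w[2] & m$abs_level > 0
  pre_fit <- if (sum(pre) >= 3) {
    fit_exponential_trend(t_rel[pre], m$abs_level[pre])
  } else NULL
  structure(list(samples = m, categories = cats, group_tests = group_tests,
                 tacrolimus_correlation = tac_cor,
                 roc_cfddna = roc_cfddna, roc_biopsy = roc_biopsy,
                 threshold_metrics = metrics,
                 prerejection_fit = pre_fit,
                 n_prerejection = sum(pre)),
            class = "cohort_statistics")
}

#' @export
print.cohort_statistics <- function(x, ...) {
  cat("Cohort statistics over", nrow(x$samples), "samples\n")
  if (!is.null(x$tacrolimus_correlation)) {
    tc <- x$tacrolimus_correlation
    cat(sprintf("  ABS vs tacrolimus: r = %.3f (95%% CI %.3f to %.3f, n = %d)\n",
                tc$r, tc$lo, tc$hi, tc$n))
  }
  for (g in names(x$group_tests)) {
    t <- x$group_tests[[g]]
    if (!is.null(t)) {
      cat(sprintf("  %s vs none: U = %.1f, one-sided p = %.4g (%s)\n",
                  g, t$U, t$p, t$method))
    }
  }
  if (!is.null(x$roc_cfddna)) {
    cat("  vs cfdDNA: "); print(x$roc_cfddna)
  }
  if (!is.null(x$roc_biopsy)) {
    cat("  vs biopsy: "); print(x$roc_biopsy)
  }
  if (!is.null(x$prerejection_fit)) {
    cat("  pre-rejection trend: "); print(x$prerejection_fit)
  }
  invisible(x)
}

#' Run the full pipeline over FASTQ samples and write all artifacts
#'
#' Executes consensus, annotation, subsampling, clone collapsing and the
#' repertoire summary for every sample, then cohort statistics against the
#' metadata, writing TSV/CSV/JSON artifacts plus a run manifest (config
#' hash, seeds, input checksums, package version). Identical inputs, config
#' and seeds produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param samples data.frame with sample_id, fastq1, fastq2 (paths).
#' @param refs Germline references.
#' @param metadata Clinical metadata data.frame (see [read_metadata()]),
#'   or NULL to skip cohort statistics.
#' @param out_dir Output directory (created if needed).
#' @return The `cohort_statistics` object (or NULL), invisibly; artifacts
#'   on disk under `out_dir`.
#' @export
run_pipeline <- function(config, samples, refs, metadata = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"),
            all(c("sample_id", "fastq1", "fastq2") %in% names(samples)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_rows <- list()
  discarded <- list()
  tallies <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    res <- tryCatch(
      process_sample(read_paired_fastq(samples$fastq1[i], samples$fastq2[i]),
                     refs, config, sample_id = sid),
      error = function(e) stop("sample ", sid, ": pipeline stage failed: ",
                               conditionMessage(e)))
    write_tsv_commented(res$consensus,
                        file.path(out_dir, paste0(sid, ".consensus.tsv")),
                        comment = "uid / coverage (read pairs) / corrected / consensus sequences")
    write_tsv_commented(res$molecules,
                        file.path(out_dir, paste0(sid, ".molecules.tsv")),
                        comment = "annotated molecules; mutation_rate = V mismatches per aligned base")
    tallies[[sid]] <- as.list(res$tally)
    if (res$discarded) {
      discarded[[sid]] <- res$subsampled$n_aligned
      next
    }
    write_tsv_commented(res$clones,
                        file.path(out_dir, paste0(sid, ".clones.tsv")),
                        comment = "clone table; molecule_count = UID groups combined")
    s <- res$summary
    jsonlite::write_json(
      list(sample_id = s$sample_id, total_molecules = s$total_molecules,
           n_sequences = s$n_sequences,
           n_highly_expressed = s$n_highly_expressed,
           abs_numerator = s$abs_numerator, abs_level = s$abs_level),
      file.path(out_dir, paste0(sid, ".summary.json")),
      auto_unbox = TRUE, digits = NA)
    cohort_rows[[sid]] <- data.frame(
      sample_id = sid, total_molecules = s$total_molecules,
      n_sequences = s$n_sequences,
      n_highly_expressed = s$n_highly_expressed,
      abs_numerator = s$abs_numerator, abs_level = s$abs_level,
      stringsAsFactors = FALSE)
  }
  if (length(cohort_rows) == 0L) stop("all samples were discarded")
  cohort <- do.call(rbind, cohort_rows)
  rownames(cohort) <- NULL
  if (!is.null(metadata)) {
    cohort <- merge(cohort,
                    metadata[, intersect(names(metadata),
                                         c("sample_id", "patient", "day"))],
                    by = "sample_id", all.x = TRUE, sort = TRUE)
  }
  utils::write.csv(cohort, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  stats_out <- NULL
  if (!is.null(metadata) && all(c("patient", "day") %in% names(cohort))) {
    stats_out <- cohort_statistics(cohort, metadata, config)
    report <- list(
      tacrolimus_correlation = stats_out$tacrolimus_correlation,
      group_tests = stats_out$group_tests,
      roc_cfddna = if (!is.null(stats_out$roc_cfddna))
        stats_out$roc_cfddna[c("auc", "lo", "hi", "n_pos", "n_neg")],
      roc_biopsy = if (!is.null(stats_out$roc_biopsy))
        stats_out$roc_biopsy[c("auc", "lo", "hi", "n_pos", "n_neg")],
      threshold_metrics = if (!is.null(stats_out$threshold_metrics))
        unclass(stats_out$threshold_metrics),
      prerejection_fit = if (!is.null(stats_out$prerejection_fit))
        stats_out$prerejection_fit[c("a", "b", "rss", "n")])
    jsonlite::write_json(report, file.path(out_dir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(stats_out$roc_cfddna)) {
      write_tsv_commented(stats_out$roc_cfddna$roc_points,
                          file.path(out_dir, "roc_cfddna.tsv"),
                          comment = "ROC of ABS level vs elevated cfdDNA; positive call: ABS >= threshold")
    }
    if (!is.null(stats_out$prerejection_fit)) {
      f <- stats_out$prerejection_fit
      write_tsv_commented(data.frame(window = "prerejection", a = f$a,
                                     b = f$b, rss = f$rss, n = f$n),
                          file.path(out_dir, "trend_fits.tsv"),
                          comment = "y = a*exp(b*t); t in days relative to rejection event")
    }
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ighseq")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    inputs = data.frame(sample_id = samples$sample_id,
                        fastq1_md5 = unname(tools::md5sum(samples$fastq1)),
                        fastq2_md5 = unname(tools::md5sum(samples$fastq2)),
                        stringsAsFactors = FALSE),
    tallies = tallies,
    discarded_samples = discarded)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stats_out)
}
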