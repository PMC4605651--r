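# File formats and configuration: paired FASTQ, FASTA references, tabular
# artifacts (TSV with a commented header), clinical metadata CSV, YAML
# config round-trip.

#' Pipeline configuration
#'
#' All tunable constants of the pipeline in one validated, serialisable
#' object. Defaults are the pipeline's operating points: depth
#' standardisation at 4,000 aligned consensus read pairs, highly expressed
#' means two or more molecules, ABS decision threshold 0.023, cfdDNA
#' elevation threshold 1\% donor DNA.
#'
#' @param uid_len_each UID bases per mate (default 8).
#' @param max_primer_mismatches Primer-matching tolerance.
#' @param align Alignment parameters, an [align_params()].
#' @param mutated_igm_min_rate Mutation-rate threshold for mutated IgM.
#' @param subsample_depth Depth standardisation (molecules).
#' @param highly_expressed_min Highly-expressed cutoff (molecules/clone).
#' @param abs_threshold ABS decision threshold for rejection calls.
#' @param cfddna_threshold cfdDNA elevation threshold (percent donor DNA).
#' @param n_boot,boot_seed Bootstrap resamples and seed for c-statistic CIs.
#' @param prerejection_window Days (relative to the event at t = 0) of
#'   samples entering the pre-rejection exponential fit.
#' @param seed Global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(uid_len_each = 8L, max_primer_mismatches = 2L,
                            align = align_params(),
                            mutated_igm_min_rate = 0.01,
                            subsample_depth = 4000L,
                            highly_expressed_min = 2L,
                            abs_threshold = 0.023,
                            cfddna_threshold = 1.0,
                            n_boot = 2000L, boot_seed = 1L,
                            prerejection_window = c(-240, 0),
                            seed = 1L) {
  stopifnot(uid_len_each >= 1, max_primer_mismatches >= 0,
            inherits(align, "align_params"), mutated_igm_min_rate >= 0,
            mutated_igm_min_rate <= 1, subsample_depth >= 1,
            highly_expressed_min >= 1, abs_threshold >= 0, abs_threshold <= 1,
            cfddna_threshold >= 0, n_boot >= 1,
            length(prerejection_window) == 2L,
            prerejection_window[1] <= prerejection_window[2])
  structure(list(uid_len_each = as.integer(uid_len_each),
                 max_primer_mismatches = as.integer(max_primer_mismatches),
                 align = align,
                 mutated_igm_min_rate = mutated_igm_min_rate,
                 subsample_depth = as.integer(subsample_depth),
                 highly_expressed_min = as.integer(highly_expressed_min),
                 abs_threshold = abs_threshold,
                 cfddna_threshold = cfddna_threshold,
                 n_boot = as.integer(n_boot), boot_seed = as.integer(boot_seed),
                 prerejection_window = as.numeric(prerejection_window),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip `read_config(write_config(cfg))` reproduces the
#' configuration exactly.
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x$align <- unclass(x$align)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$align <- do.call(align_params, x$align)
  do.call(pipeline_config, x)
}

#' Read synchronised paired FASTQ files
#'
#' @param path1,path2 Mate FASTQ files (plain or gzip).
#' @return data.frame with id, seq1, qual1, seq2, qual2 in file order.
#' @export
read_paired_fastq <- function(path1, path2) {
  rd <- function(p) {
    tryCatch(Biostrings::readDNAStringSet(p, format = "fastq",
                                          with.qualities = TRUE),
             error = function(e) stop("malformed FASTQ in ", p, ": ",
                                      conditionMessage(e)))
  }
  x1 <- rd(path1); x2 <- rd(path2)
  if (length(x1) != length(x2)) {
    stop("desynchronised mates: ", path1, " has ", length(x1),
         " records but ", path2, " has ", length(x2),
         " (first missing record at index ", min(length(x1), length(x2)) + 1L,
         ")")
  }
  data.frame(id = names(x1),
             seq1 = as.character(x1),
             qual1 = as.character(S4Vectors::mcols(x1)$qualities),
             seq2 = as.character(x2),
             qual2 = as.character(S4Vectors::mcols(x2)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write paired FASTQ files
#'
#' @param reads data.frame with id, seq1, qual1, seq2, qual2 (e.g. from
#'   [synthesize_reads()]).
#' @param path1,path2 Output paths (gzip when ending in .gz).
#' @return c(path1, path2), invisibly.
#' @export
write_paired_fastq <- function(reads, path1, path2) {
  wr <- function(seqs, quals, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", reads$id, "\n", seqs, "\n+\n", quals), con)
  }
  wr(reads$seq1, reads$qual1, path1)
  wr(reads$seq2, reads$qual2, path2)
  invisible(c(path1, path2))
}

#' Write reference sets as FASTA
#'
#' @param refs A [make_germline_refs()] result.
#' @param v_path,c_path Output FASTA paths.
#' @return Paths, invisibly.
#' @export
write_reference_fasta <- function(refs, v_path, c_path) {
  Biostrings::writeXStringSet(refs$v, v_path)
  Biostrings::writeXStringSet(refs$c, c_path)
  invisible(c(v_path, c_path))
}

#' Read clinical metadata
#'
#' CSV with header; required columns `patient`, `day`; optional
#' `sample_id`, `tacrolimus` (ng/ml), `biopsy_grade` (0/1R/2R/3R) and
#' `cfddna_pct` (percent donor DNA). Rows with an unparseable grade or
#' negative cfdDNA are rejected with their line numbers.
#'
#' @param path CSV path.
#' @return data.frame of typed records; attribute `rejected` lists rejected
#'   line numbers and reasons.
#' @export
read_metadata <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("patient", "day")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  to_num <- function(x) suppressWarnings(as.numeric(x))
  grade <- if ("biopsy_grade" %in% names(raw)) {
    g <- trimws(raw$biopsy_grade)
    g[g == ""] <- NA_character_
    g
  } else rep(NA_character_, n)
  cfddna <- if ("cfddna_pct" %in% names(raw)) to_num(raw$cfddna_pct)
    else rep(NA_real_, n)
  tac <- if ("tacrolimus" %in% names(raw)) to_num(raw$tacrolimus)
    else rep(NA_real_, n)
  day <- to_num(raw$day)
  bad_grade <- !is.na(grade) & !grade %in% c("0", "1R", "2R", "3R")
  bad_day <- is.na(day)
  bad_cfddna <- !is.na(cfddna) & cfddna < 0
  bad <- bad_grade | bad_day | bad_cfddna
  rejected <- data.frame(
    line = which(bad) + 1L,  # header is line 1
    reason = ifelse(bad_grade[bad], "invalid biopsy grade",
                    ifelse(bad_day[bad], "invalid day", "negative cfdDNA")))
  if (nrow(rejected)) {
    warning("rejected ", nrow(rejected), " metadata row(s) at line(s) ",
            paste(rejected$line, collapse = ", "))
  }
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(raw)) raw$sample_id
      else paste0(raw$patient, "_d", raw$day),
    patient = raw$patient, day = day, tacrolimus = tac,
    biopsy_grade = grade, cfddna_pct = cfddna,
    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a data.frame as TSV with a commented header line
#'
#' @param df data.frame.
#' @param path Output path.
#' @param comment Header comment (units/provenance), written as "# ...".
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
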