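# Per-sample repertoire metrics: fixed-depth subsampling, clone collapsing,
# the ABS level and the isotype-resolved expression histogram.

#' Subsample annotated molecules to a fixed depth
#'
#' Uniform sampling without replacement to exactly `depth` molecules, the
#' depth standardisation that makes ABS levels comparable across samples.
#' Samples with fewer aligned molecules than `depth` are discarded.
#'
#' @param molecules data.frame of annotated molecules
#'   ([annotate_molecules()]).
#' @param depth Target depth (default 4000 molecules).
#' @param seed Subsampling seed; defaults to a hash of `sample_id` so reruns
#'   are reproducible per sample.
#' @param sample_id Sample identifier used for the default seed.
#' @return The subsampled data.frame (row order preserved), or an object of
#'   class `sample_discarded` (with `n_aligned` and `depth`) when the sample
#'   is too shallow.
#' @export
subsample_molecules <- function(molecules, depth = 4000, seed = NULL,
                                sample_id = "sample") {
  if (depth < 1) stop("depth must be a positive count")
  n <- nrow(molecules)
  if (n < depth) {
    return(structure(list(sample_id = sample_id, n_aligned = n,
                          depth = depth), class = "sample_discarded"))
  }
  if (n == depth) return(molecules)
  seed <- seed %||% id_seed(sample_id)
  keep <- with_seed(seed, sort(sample.int(n, depth)))
  molecules[keep, , drop = FALSE]
}

#' @export
print.sample_discarded <- function(x, ...) {
  cat("Sample", x$sample_id, "discarded:", x$n_aligned,
      "aligned molecules <", x$depth, "required\n")
  invisible(x)
}

#' Collapse annotated molecules into clones
#'
#' Molecules with an identical forward consensus (sequence key, carrying
#' the CDR3) and isotype are assumed to originate from the same B cell
#' clone and are combined; the clone's expression level is its molecule
#' count. The clone is flagged mutated if any member molecule is mutated,
#' and its V segment is the most frequent member assignment (ties broken by
#' name order).
#'
#' @param molecules data.frame of (subsampled) annotated molecules.
#' @return data.frame of clones: sequence_key, isotype, v_segment, mutated,
#'   molecule_count.
#' @export
collapse_clones <- function(molecules) {
  if (nrow(molecules) == 0L) {
    return(data.frame(sequence_key = character(0), isotype = character(0),
                      v_segment = character(0), mutated = logical(0),
                      molecule_count = integer(0), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(
    molecules[, c("sequence_key", "isotype", "v_segment", "mutated")])
  sequence_key <- isotype <- v_segment <- mutated <- NULL  # NSE note
  N <- molecule_count <- NULL
  cl <- dt[, list(molecule_count = .N, mutated = sum(mutated) > 0L),
           keyby = list(sequence_key, isotype)]
  # majority V segment per clone, ties broken by segment name order
  vs <- dt[, list(N = .N), by = list(sequence_key, isotype, v_segment)]
  data.table::setorder(vs, sequence_key, isotype, -N, v_segment)
  vs <- vs[!duplicated(vs[, list(sequence_key, isotype)])]
  cl <- vs[, list(sequence_key, isotype, v_segment)][cl,
         on = c("sequence_key", "isotype")]
  out <- as.data.frame(cl)[, c("sequence_key", "isotype", "v_segment",
                               "mutated", "molecule_count")]
  out <- out[order(out$sequence_key, out$isotype), , drop = FALSE]
  out$molecule_count <- as.integer(out$molecule_count)
  rownames(out) <- NULL
  out
}

# numerator / highly-expressed / total decomposition of the ABS definition
abs_components <- function(clones, highly_expressed_min = 2) {
  total <- sum(clones$molecule_count)
  he <- clones$molecule_count >= highly_expressed_min
  qualifies <- clones$isotype != "IgM" | clones$mutated
  list(total_molecules = total,
       n_sequences = nrow(clones),
       n_highly_expressed = sum(he),
       abs_numerator = sum(he & qualifies))
}

#' ABS level of a clone table
#'
#' The activated B cell sequence (ABS) level: the number of highly
#' expressed clones (molecule count >= `highly_expressed_min`) that are
#' class-switched (IgA/IgD/IgE/IgG) or mutated IgM, divided by the total
#' number of molecules.
#'
#' @param clones data.frame from [collapse_clones()].
#' @param highly_expressed_min Minimum molecule count of a highly expressed
#'   clone (default 2, i.e. "more than one molecule").
#' @return ABS level as a single fraction.
#' @export
abs_level <- function(clones, highly_expressed_min = 2) {
  if (nrow(clones) == 0L) stop("empty clone table; ABS level undefined")
  k <- abs_components(clones, highly_expressed_min)
  k$abs_numerator / k$total_molecules
}

#' Clone counts per expression level and isotype
#'
#' Tabulates, for every molecule-count value present, the number of clones
#' per isotype class, with mutated IgM distinguished from unmutated IgM.
#'
#' @param clones data.frame from [collapse_clones()].
#' @return data.frame with columns molecule_count, isotype_class, n_clones;
#'   the n_clones sum equals the number of clones.
#' @export
expression_histogram <- function(clones) {
  if (nrow(clones) == 0L) {
    return(data.frame(molecule_count = integer(0), isotype_class = character(0),
                      n_clones = integer(0), stringsAsFactors = FALSE))
  }
  cls <- ifelse(clones$isotype == "IgM",
                ifelse(clones$mutated, "IgM_mutated", "IgM_unmutated"),
                clones$isotype)
  tab <- table(molecule_count = clones$molecule_count, isotype_class = cls)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  out <- out[out$Freq > 0, , drop = FALSE]
  names(out)[3] <- "n_clones"
  out$molecule_count <- as.integer(out$molecule_count)
  out <- out[order(out$molecule_count, out$isotype_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool clone tables across samples
#'
#' Concatenates per-sample clone tables without cross-sample collapsing
#' (IGH sequences are personal; identical keys in different samples remain
#' distinct clones). Pooled ratios are computed over summed numerators and
#' summed molecule totals.
#'
#' @param clone_tables List of clone tables ([collapse_clones()]).
#' @param sample_ids Character vector of the same length.
#' @return data.frame with a `sample` column prepended; attribute `pooled`
#'   holds the summed [abs_components()] decomposition.
#' @export
pool_samples <- function(clone_tables, sample_ids = names(clone_tables)) {
  stopifnot(length(clone_tables) >= 1L,
            length(sample_ids) == length(clone_tables))
  tagged <- mapply(function(tab, id) cbind(sample = id, tab,
                                           stringsAsFactors = FALSE),
                   clone_tables, sample_ids, SIMPLIFY = FALSE)
  out <- do.call(rbind, tagged)
  rownames(out) <- NULL
  parts <- lapply(clone_tables, abs_components)
  pooled <- Reduce(function(a, b) Map(`+`, a, b), parts)
  attr(out, "pooled") <- pooled
  out
}

#' Summarise one sample's repertoire
#'
#' @param clones data.frame from [collapse_clones()] at fixed depth.
#' @param sample_id Sample identifier.
#' @param highly_expressed_min Highly-expressed cutoff (see [abs_level()]).
#' @return An object of class `repertoire_summary` with total_molecules,
#'   n_sequences, n_highly_expressed, abs_numerator, abs_level and the
#'   isotype-resolved expression histogram. Internal consistency invariants
#'   are asserted.
#' @export
repertoire_summary <- function(clones, sample_id = "sample",
                               highly_expressed_min = 2) {
  if (nrow(clones) == 0L) stop("empty clone table for sample ", sample_id)
  k <- abs_components(clones, highly_expressed_min)
  out <- c(list(sample_id = sample_id), k,
           list(abs_level = k$abs_numerator / k$total_molecules,
                histogram = expression_histogram(clones)))
  stopifnot(out$abs_numerator <= out$n_highly_expressed,
            out$n_highly_expressed <= out$n_sequences,
            out$n_sequences <= out$total_molecules,
            sum(clones$molecule_count) == out$total_molecules,
            out$abs_level >= 0, out$abs_level <= 1,
            sum(out$histogram$n_clones) == out$n_sequences)
  class(out) <- "repertoire_summary"
  out
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat("Repertoire summary for", x$sample_id, "\n")
  cat(sprintf("  molecules: %d  clones: %d  highly expressed: %d\n",
              x$total_molecules, x$n_sequences, x$n_highly_expressed))
  cat(sprintf("  ABS level: %d/%d = %.4f\n", x$abs_numerator,
              x$total_molecules, x$abs_level))
  invisible(x)
}
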