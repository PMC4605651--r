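# Synthetic longitudinal cohort: per-sample simulation parameters, clinical
# metadata and planted rejection events, emulating a transplant monitoring
# study with serial repertoire samples per patient.

#' Design a synthetic transplant cohort
#'
#' Lays out patients, sampling days, planted rejection events and the
#' clinical covariates tied to them. Half the patients (by default 6 of 12)
#' experience one moderate-to-severe rejection event at a random day; in a
#' window around the event (60 days before to 30 days after) the B cell
#' compartment is activated (higher `p_activated`, i.e. elevated true ABS),
#' cfdDNA is elevated above 1\% and biopsies grade 1R/2R, while tacrolimus
#' runs lower. Outside the window, samples sit at the immunosuppressed
#' baseline with occasional mild (1R) grades.
#'
#' @param n_patients Number of patients.
#' @param n_rejectors Patients with a planted rejection event.
#' @param days Sampling days post-transplant common to all patients.
#' @param p_activated_baseline,p_activated_rejection Activated-clone
#'   probability outside / inside the rejection window.
#' @param window Days around the event (relative) defining the activated
#'   window and the planted positive label.
#' @param seed RNG seed.
#' @return data.frame with one row per sample: sample_id, patient, day,
#'   rejection_event_day (NA when none), planted_positive,
#'   p_activated, tacrolimus, biopsy_grade, cfddna_pct, sim_seed.
#' @export
simulate_cohort_design <- function(n_patients = 12, n_rejectors = 6,
                                   days = c(30, 60, 90, 150, 210, 270),
                                   p_activated_baseline = 0.05,
                                   p_activated_rejection = 0.35,
                                   window = c(-60, 30), seed = 1L) {
  stopifnot(n_rejectors <= n_patients, length(days) >= 2)
  with_seed(seed, {
    patients <- sprintf("P%02d", seq_len(n_patients))
    event_day <- rep(NA_real_, n_patients)
    rejectors <- seq(n_patients - n_rejectors + 1L, n_patients)
    event_day[rejectors] <- round(stats::runif(n_rejectors, 120, 250))
    rows <- list()
    for (i in seq_len(n_patients)) {
      for (d in days) {
        in_window <- !is.na(event_day[i]) &&
          d >= event_day[i] + window[1] && d <= event_day[i] + window[2]
        p_act <- if (in_window) p_activated_rejection else p_activated_baseline
        tac_target <- if (d <= 180) 12.5 else 8.5
        tac <- max(2, stats::rnorm(1, tac_target - if (in_window) 3 else 0,
                                   1.5))
        cfddna <- if (in_window) {
          exp(stats::rnorm(1, log(2.5), 0.4))
        } else {
          exp(stats::rnorm(1, log(0.2), 0.5))
        }
        grade <- if (in_window) {
          sample(c("1R", "2R", "3R"), 1, prob = c(0.3, 0.55, 0.15))
        } else {
          sample(c("0", "1R", NA), 1, prob = c(0.82, 0.08, 0.10))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_d%03d", patients[i], d),
          patient = patients[i], day = d,
          rejection_event_day = event_day[i],
          planted_positive = in_window, p_activated = p_act,
          tacrolimus = round(tac, 1), biopsy_grade = grade,
          cfddna_pct = round(cfddna, 2),
          stringsAsFactors = FALSE)
      }
    }
    design <- do.call(rbind, rows)
    design$sim_seed <- vapply(design$sample_id, id_seed, integer(1),
                              offset = seed)
    rownames(design) <- NULL
    design
  })
}

#' Simulate one cohort sample's repertoire and reads
#'
#' @param design_row One row of [simulate_cohort_design()].
#' @param refs Germline references shared by the cohort.
#' @param base_cfg A [sim_config()] supplying everything except
#'   `p_activated` and `seed`, which come from the design row.
#' @return List with `truth` (the `true_repertoire`) and `reads`
#'   (the [synthesize_reads()] data.frame).
#' @export
simulate_cohort_sample <- function(design_row, refs, base_cfg = sim_config()) {
  cfg <- base_cfg
  cfg$p_activated <- design_row$p_activated
  cfg$seed <- design_row$sim_seed
  truth <- sample_true_repertoire(cfg, refs)
  list(truth = truth, reads = synthesize_reads(truth, cfg))
}
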