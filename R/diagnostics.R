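# Cohort-level diagnostic statistics relating per-sample ABS levels to
# clinical metadata: rejection classification, correlation with drug level,
# group tests, ROC/c-statistic, threshold metrics with Wilson intervals and
# exponential trend fits.

REJECTION_CATEGORIES <- c("none", "mild_ACR", "mod_severe_ACR",
                          "elevated_cfdDNA")

#' Classify a sample's rejection status
#'
#' Biopsy-based categories from the ISHLT grade (1R -> mild ACR, >= 2R ->
#' moderate-to-severe ACR) and an elevated-cfdDNA category when the
#' cell-free donor DNA fraction exceeds `cfddna_threshold`. The categories
#' may overlap (a sample can be both biopsy-proven and cfdDNA-positive), so
#' the full set of applicable labels is returned; a sample with at least one
#' observed field and no positive label is "none".
#'
#' @param biopsy_grade One of "0", "1R", "2R", "3R" or NA.
#' @param cfddna_pct Donor DNA fraction in percent, or NA.
#' @param cfddna_threshold Elevation threshold in percent (default 1.0).
#' @return Character vector of applicable category labels.
#' @export
classify_rejection <- function(biopsy_grade, cfddna_pct,
                               cfddna_threshold = 1.0) {
  if (length(biopsy_grade) != 1L || length(cfddna_pct) != 1L) {
    stop("classify_rejection takes one record at a time")
  }
  if (is.na(biopsy_grade) && is.na(cfddna_pct)) {
    stop("Unclassifiable: both biopsy grade and cfdDNA are missing")
  }
  if (!is.na(biopsy_grade) &&
      !biopsy_grade %in% c("0", "1R", "2R", "3R")) {
    stop("invalid biopsy grade: ", biopsy_grade)
  }
  labels <- character(0)
  if (!is.na(biopsy_grade)) {
    if (biopsy_grade == "1R") labels <- c(labels, "mild_ACR")
    if (biopsy_grade %in% c("2R", "3R")) labels <- c(labels, "mod_severe_ACR")
  }
  if (!is.na(cfddna_pct) && cfddna_pct > cfddna_threshold) {
    labels <- c(labels, "elevated_cfdDNA")
  }
  if (length(labels) == 0L) labels <- "none"
  labels
}

#' Pearson correlation with a Fisher r-to-z confidence interval
#'
#' @param x,y Paired numeric vectors (n >= 4, finite, non-degenerate).
#' @param alpha Two-sided error rate (default 0.05 for a 95\% CI).
#' @return List with r, lo, hi, n and the two-sided p-value from the
#'   t-distribution. When |r| = 1 the z-transform diverges and the interval
#'   degenerates to (r, r).
#' @export
pearson_with_fisher_ci <- function(x, y, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  r <- stats::cor(x, y)
  z <- stats::qnorm(1 - alpha / 2)
  if (abs(r) >= 1) {
    lo <- hi <- r  # degenerate: atanh unbounded at |r| = 1
  } else {
    zr <- atanh(r)
    lo <- tanh(zr - z / sqrt(n - 3))
    hi <- tanh(zr + z / sqrt(n - 3))
  }
  tstat <- r * sqrt((n - 2) / (1 - min(r^2, 1 - 1e-15)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, lo = lo, hi = hi, n = n, p = p)
}

# Exact permutation distribution of the rank-sum via dynamic programming
# over doubled midranks (integers even under ties). Counts, for every
# achievable doubled rank-sum s, the number of size-na subsets with that
# sum; equivalent to full enumeration of all C(n, na) assignments.
ranksum_exact_tail <- function(ranks2, na, observed2) {
  n <- length(ranks2)
  maxsum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(na)])
  # f[j+1, s+1] = number of subsets of size j with doubled rank-sum s
  f <- matrix(0, nrow = na + 1L, ncol = maxsum + 1L)
  f[1, 1] <- 1
  for (r in ranks2) {
    jmax <- na
    for (j in jmax:1) {
      shifted <- c(rep(0, r), f[j, seq_len(maxsum + 1L - r)])
      f[j + 1L, ] <- f[j + 1L, ] + shifted
    }
  }
  counts <- f[na + 1L, ]
  tail_count <- sum(counts[seq.int(observed2 + 1L, maxsum + 1L)])
  list(tail = tail_count, total = choose(n, na))
}

#' One-sided Mann-Whitney U test
#'
#' U statistic with midrank tie handling; the one-sided alternative is that
#' group `a` is stochastically larger than group `b` (the direction can be
#' flipped). When `n_a * n_b <= exact_limit` the p-value is exact -- the
#' full permutation distribution of the rank-sum is computed (a
#' dynamic-programming count equivalent to enumerating all group
#' assignments, valid under ties); otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative "greater" (a > b, default) or "less".
#' @param exact_limit Use the exact branch when `length(a) * length(b)` is
#'   at most this (default 400).
#' @return List with U (for group `a`), p, and the method used.
#' @export
mann_whitney_one_sided <- function(a, b, alternative = c("greater", "less"),
                                   exact_limit = 400) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (alternative == "less") return(mann_whitney_one_sided(b, a, "greater",
                                                           exact_limit))
  na <- length(a); nb <- length(b); n <- na + nb
  rk <- rank(c(a, b))  # midranks
  ra <- sum(rk[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  if (na * nb <= exact_limit) {
    ranks2 <- as.integer(round(2 * rk))
    obs2 <- as.integer(round(2 * ra))
    e <- ranksum_exact_tail(ranks2, na, obs2)
    p <- e$tail / e$total
    method <- "exact"
  } else {
    ties <- table(rk)
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    zstat <- (U - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(zstat, lower.tail = FALSE)
    method <- "normal_approx"
  }
  list(U = U, p = p, method = method, n_a = na, n_b = nb)
}

#' ROC curve and c-statistic with bootstrap confidence interval
#'
#' The c-statistic is the probability that a random positive outranks a
#' random negative, with half credit for ties (pairwise concordance,
#' computed from midranks). The confidence interval is a percentile
#' bootstrap over samples; ROC points are produced at every distinct score
#' threshold (positive call: score >= threshold).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 labels; both classes must be present.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `roc_c_statistic`: auc, lo, hi, n_boot and a
#'   data.frame `roc_points` (threshold, tpr, fpr).
#' @export
roc_c_statistic <- function(scores, labels, n_boot = 2000, seed = 1L,
                            conf_level = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a c-statistic")
  }
  auc_of <- function(s, l) {
    n1 <- sum(l); n0 <- sum(!l)
    (sum(rank(s)[l]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(scores, labels)
  n <- length(scores)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        l <- labels[idx]
        if (any(l) && !all(l)) return(auc_of(scores[idx], l))
      }
    }, numeric(1))
  })
  qs <- stats::quantile(boot, c((1 - conf_level) / 2, (1 + conf_level) / 2),
                        names = FALSE, type = 7)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr),
                    fpr = c(0, fpr))
  structure(list(auc = auc, lo = qs[1], hi = qs[2], n_boot = n_boot,
                 roc_points = pts, n_pos = sum(labels), n_neg = sum(!labels)),
            class = "roc_c_statistic")
}

#' @export
print.roc_c_statistic <- function(x, ...) {
  cat(sprintf("c-statistic = %.3f (95%% bootstrap CI %.3f to %.3f; %d+/%d-)\n",
              x$auc, x$lo, x$hi, x$n_pos, x$n_neg))
  invisible(x)
}

#' Continuity-corrected Wilson score interval
#'
#' Newcombe's continuity-corrected version of the Wilson efficient-score
#' interval for a binomial proportion, clamped to [0, 1]; `lo = 0` when
#' `k = 0` and `hi = 1` when `k = n`.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param alpha Two-sided error rate (default 0.05).
#' @return Numeric vector c(lo, hi).
#' @export
wilson_cc_interval <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - alpha / 2)
  p <- k / n
  q <- 1 - p
  lo <- if (k == 0) 0 else {
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) / (2 * (n + z^2))
  }
  hi <- if (k == n) 1 else {
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) / (2 * (n + z^2))
  }
  c(lo = max(0, lo), hi = min(1, hi))
}

#' Sensitivity, specificity, PPV and NPV at a score threshold
#'
#' Positive call iff score >= threshold (closed bound). Each fraction gets a
#' continuity-corrected Wilson 95\% interval; PPV/NPV are NA (with a note)
#' when the corresponding margin of the 2x2 table is empty.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 true condition labels.
#' @param threshold Decision threshold (default 0.023 ABS units).
#' @param alpha Two-sided error rate for the intervals.
#' @return Object of class `diagnostic_metrics`: the 2x2 counts and, for
#'   each of sensitivity/specificity/ppv/npv, the point estimate with
#'   (lo, hi).
#' @export
binary_metrics_at_threshold <- function(scores, labels, threshold = 0.023,
                                        alpha = 0.05) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present")
  }
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels); fn <- sum(!call_pos & labels)
  fp <- sum(call_pos & !labels); tn <- sum(!call_pos & !labels)
  met <- function(k, n) {
    if (n == 0) {
      list(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
           note = "empty margin")
    } else {
      ci <- wilson_cc_interval(k, n, alpha)
      list(estimate = k / n, lo = unname(ci[1]), hi = unname(ci[2]),
           note = NULL)
    }
  }
  structure(list(threshold = threshold,
                 table = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 sensitivity = met(tp, tp + fn),
                 specificity = met(tn, tn + fp),
                 ppv = met(tp, tp + fp),
                 npv = met(tn, tn + fn)),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("Threshold %.4g: TP=%d FP=%d FN=%d TN=%d\n", x$threshold,
              x$table["tp"], x$table["fp"], x$table["fn"], x$table["tn"]))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    if (is.na(v$estimate)) {
      cat(sprintf("  %-11s NA (%s)\n", m, v$note))
    } else {
      cat(sprintf("  %-11s %.1f%% (95%% CI %.1f%% to %.1f%%)\n", m,
                  100 * v$estimate, 100 * v$lo, 100 * v$hi))
    }
  }
  invisible(x)
}

#' Fit an exponential trend y = a * exp(b * t)
#'
#' Nonlinear least squares initialised from a log-linear regression.
#'
#' @param times Numeric times in days (>= 3 points).
#' @param values Strictly positive values (ABS levels).
#' @return Object of class `exp_fit`: a, b, rss, fitted values and n.
#' @export
fit_exponential_trend <- function(times, values) {
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (length(times) < 3) stop("need at least 3 points")
  if (any(values <= 0)) stop("values must be strictly positive")
  init <- stats::lm(log(values) ~ times)
  start <- list(a = exp(unname(stats::coef(init)[1])),
                b = unname(stats::coef(init)[2]))
  df <- data.frame(t = times, y = values)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * t), data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    converged <- fit$convInfo$isConv %||% TRUE
  } else {
    # degenerate cases (e.g. an exact fit at the start values leaves the
    # NLS machinery with zero residuals); polish the start by direct RSS
    # minimisation instead
    rss_fn <- function(p) sum((values - p[1] * exp(p[2] * times))^2)
    op <- stats::optim(c(start$a, start$b), rss_fn, method = "BFGS",
                       control = list(reltol = 1e-14))
    co <- c(a = op$par[1], b = op$par[2])
    converged <- op$convergence == 0
  }
  fitted <- co[["a"]] * exp(co[["b"]] * times)
  structure(list(a = co[["a"]], b = co[["b"]],
                 rss = sum((values - fitted)^2), fitted = fitted,
                 n = length(times), converged = converged),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit y = a*exp(b*t): a = %.4g, b = %.4g (RSS %.3g, n = %d)\n",
              x$a, x$b, x$rss, x$n))
  invisible(x)
}
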