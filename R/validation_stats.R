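# Technical-validation statistics: trapezoidal AUC, fractional AUC
# variability across replicate series, Kolmogorov-Smirnov replicate
# concordance, and confusion-matrix classification metrics.

#' Trapezoidal area under a concentration-time curve
#'
#' Composite trapezoid rule on the given (possibly non-uniform) time grid.
#'
#' @param times time points in hours, strictly increasing, length >= 2.
#' @param concs non-negative concentrations, ug/mL.
#' @return AUC in ug.h/mL.
#' @export
trapezoid_auc <- function(times, concs) {
  if (length(times) < 2 || length(times) != length(concs))
    cvt_error("cvt_input_error",
              "need >= 2 points with matching times and concentrations")
  if (any(diff(times) <= 0))
    cvt_error("cvt_input_error", "times must be strictly increasing")
  if (any(concs < 0))
    cvt_error("cvt_input_error", "concentrations must be >= 0")
  pracma::trapz(times, concs)
}

# Population standard deviation (divisor N); replicate counts here are tiny
# (2-3), so the divisor choice is material and is fixed deliberately.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Fractional variability of replicate series AUCs
#'
#' AUCFracVar = sd(AUCs) / A_plot: the population standard deviation of the
#' per-series trapezoid AUCs, expressed as a fraction of the plot-space area.
#' The plot space is the axis-anchored rectangle covering the compared series:
#' (max time - min(0, min time)) x (max concentration).
#'
#' @param series_list list (length >= 2) of data frames with columns `time`
#'   and `conc`, each with >= 2 points.
#' @return List with `aucs`, `sd_auc`, `a_plot` and `auc_frac_var`.
#' @export
auc_frac_var <- function(series_list) {
  if (!is.list(series_list) || length(series_list) < 2)
    cvt_error("cvt_input_error", "need >= 2 replicate series")
  aucs <- vapply(series_list,
                 function(s) trapezoid_auc(s$time, s$conc), numeric(1))
  all_t <- unlist(lapply(series_list, `[[`, "time"))
  all_c <- unlist(lapply(series_list, `[[`, "conc"))
  a_plot <- (max(all_t) - min(0, min(all_t))) * max(all_c)
  if (a_plot <= 0)
    cvt_error("cvt_degenerate_input_error",
              "plot space has zero area (all concentrations zero)")
  s <- sd_pop(aucs)
  list(aucs = aucs, sd_auc = s, a_plot = a_plot, auc_frac_var = s / a_plot)
}

#' Kolmogorov-Smirnov concordance of two replicate series
#'
#' Two-sample two-sided K-S test of the null hypothesis that the two
#' concentration samples are drawn from the same continuous distribution;
#' replicates are declared concordant when p >= alpha.
#'
#' @param conc_a,conc_b concentration samples (length >= 2).
#' @param alpha significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `same_distribution`.
#' @export
ks_replicate_concordance <- function(conc_a, conc_b, alpha = 0.05) {
  if (length(conc_a) < 2 || length(conc_b) < 2)
    cvt_error("cvt_input_error", "both samples need >= 2 values")
  kt <- suppressWarnings(ks.test(conc_a, conc_b, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       same_distribution = unname(kt$p.value) >= alpha)
}

#' Confusion counts
#'
#' @param TP,FP,FN non-negative true-positive, false-positive and
#'   false-negative counts.
#' @param TN optional true-negative count (unused by the triage metrics).
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, FN, TN = NA_integer_) {
  if (any(c(TP, FP, FN) < 0))
    cvt_error("cvt_input_error", "counts must be non-negative")
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' Confusion counts from labelled predictions
#'
#' @param truth,predicted vectors of class labels of equal length.
#' @param positive the label treated as positive.
#' @return A [confusion_counts()].
#' @export
confusion_from_labels <- function(truth, predicted, positive = "positive") {
  stopifnot(length(truth) == length(predicted))
  confusion_counts(TP = sum(truth == positive & predicted == positive),
                   FP = sum(truth != positive & predicted == positive),
                   FN = sum(truth == positive & predicted != positive),
                   TN = sum(truth != positive & predicted != positive))
}

round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Recall, precision and F1 from confusion counts
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP), F1 = 2PR/(P+R) computed on
#' the unrounded precision and recall. A zero denominator yields 0 for that
#' metric with `degenerate = TRUE`. Rounded renderings (half away from zero)
#' are returned alongside for table display.
#'
#' @param counts a [confusion_counts()].
#' @param decimals digits for the rounded renderings (default 2).
#' @return List with `recall`, `precision`, `f1`, their `rounded_*`
#'   counterparts and `degenerate`.
#' @export
classification_metrics <- function(counts, decimals = 2) {
  stopifnot(inherits(counts, "confusion_counts"))
  degenerate <- FALSE
  rec <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
  else { degenerate <- TRUE; 0 }
  prec <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
  else { degenerate <- TRUE; 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec)
  else { degenerate <- TRUE; 0 }
  list(recall = rec, precision = prec, f1 = f1,
       rounded_recall = round_half_away(rec, decimals),
       rounded_precision = round_half_away(prec, decimals),
       rounded_f1 = round_half_away(f1, decimals),
       degenerate = degenerate)
}
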