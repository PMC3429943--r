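# Threshold classification of sibling vs unrelated populations and
# distribution summaries of log10 LR values.

#' Round half away from zero
#'
#' Display rounding for percentages (so e.g. 99.245 rounds to 99.25); base
#' `round()` rounds half to even.  Computations always keep full precision;
#' this is applied only for reporting.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  # snap values a few ulp below .5 (binary representation artefacts) upward
  r <- round(x * 10^digits, 8)
  sign(x) * floor(abs(r) + 0.5) / 10^digits
}

#' Confusion-matrix summary from counts
#'
#' @param tp,fn true/false outcomes among the sibling population (tp + fn =
#'   its size).
#' @param fp,tn outcomes among the unrelated population.
#' @param threshold,strict the LR threshold the counts were taken at (for
#'   record only; may be `NA`).
#' @return object of class `confusion_summary`: counts plus `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` as unrounded percentages.
#'   Accuracy is (TP+TN)/(TP+TN+FP+FN).  The print method shows percentages
#'   rounded half-up to 2 decimals.
#' @export
confusion_summary <- function(tp, fn, fp, tn, threshold = NA_real_,
                              strict = NA) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("tp, fn, fp, tn must be non-negative integers")
  structure(list(
    threshold = threshold, strict = strict,
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (fp + tn),
    ppv = 100 * tp / (tp + fp),
    npv = 100 * tn / (tn + fn),
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn)),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> threshold %s (%s)\n",
              format(x$threshold),
              if (isTRUE(x$strict)) "LR > t" else "LR >= t"))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  r <- round_half_up(c(sensitivity = x$sensitivity,
                       specificity = x$specificity,
                       ppv = x$ppv, npv = x$npv, accuracy = x$accuracy))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  PPV %.2f%%  NPV %.2f%%  accuracy %.2f%%\n",
              r[1], r[2], r[3], r[4], r[5]))
  invisible(x)
}

#' Classify two LR populations at a threshold
#'
#' Calls a comparison "sibling" when its combined LR clears the threshold
#' (`lr > threshold` when `strict`, else `lr >= threshold`) and tabulates the
#' confusion matrix against truth: `sib_lrs` are true siblings, `unrel_lrs`
#' true non-siblings.
#'
#' @param sib_lrs combined LRs of the sibling population (e.g. 3S trios).
#' @param unrel_lrs combined LRs of the unrelated population (e.g. 2S1U).
#' @param threshold positive LR threshold (e.g. 1, 100, 1000).
#' @param strict logical: `TRUE` for `LR > t`, `FALSE` (default) for
#'   `LR >= t` ("at least" thresholds).
#' @return a [confusion_summary()].
#' @export
confusion_at_threshold <- function(sib_lrs, unrel_lrs, threshold,
                                   strict = FALSE) {
  if (!length(sib_lrs) || !length(unrel_lrs))
    stop("both LR lists must be non-empty")
  stopifnot(threshold > 0)
  call_sib <- function(lr) if (strict) lr > threshold else lr >= threshold
  tp <- sum(call_sib(sib_lrs)); fn <- length(sib_lrs) - tp
  fp <- sum(call_sib(unrel_lrs)); tn <- length(unrel_lrs) - fp
  confusion_summary(tp, fn, fp, tn, threshold = threshold, strict = strict)
}

#' Summary statistics of a log10 LR distribution
#'
#' @param lrs positive LR values (post-floor, so logs are finite).
#' @return object of class `lr_summary`: list with `mean`, `sd` (sample SD,
#'   n-1 denominator), `min`, `max` of log10(LR), and `n`.
#' @export
lr_distribution_summary <- function(lrs) {
  if (!length(lrs)) stop("empty LR list")
  if (any(lrs <= 0)) stop("all LR values must be positive (apply the floor first)")
  x <- log10(lrs)
  structure(list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
                 min = min(x), max = max(x), n = length(x)),
            class = "lr_summary")
}

#' @export
print.lr_summary <- function(x, ...) {
  cat(sprintf("<lr_summary> n = %d: log10 LR %.4f +/- %.4f, range [%.2f, %.2f]\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Histogram of excluding-locus counts per family
#'
#' For each simulated family, the number of loci showing a genetic
#' inconsistency; bin 0 is the count of families with no exclusion at all
#' (the non-excluded fraction of a 2S1U population).
#'
#' @param pop a [simulate_population()] result.
#' @return named integer vector over 0..(number of loci).
#' @export
inconsistency_locus_counts <- function(pop) {
  stopifnot(inherits(pop, "trio_population"))
  L <- length(pop$loci)
  tab <- tabulate(pop$n_excluded + 1L, nbins = L + 1L)
  stats::setNames(as.integer(tab), 0:L)
}

#' Empirical per-locus exclusion power
#'
#' Fraction of non-sibling (2S1U) trios excluded at each locus: an empirical
#' ranking of how informative each locus is for detecting non-sibship.
#'
#' @param pop a 2S1U [simulate_population()] result.
#' @return named numeric vector (locus -> exclusion fraction), sorted
#'   decreasing.
#' @export
per_locus_exclusion_power <- function(pop) {
  stopifnot(inherits(pop, "trio_population"))
  if (pop$mode != "2S1U")
    stop("per-locus exclusion power is defined for 2S1U populations")
  sort(colMeans(pop$exclusions), decreasing = TRUE)
}
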