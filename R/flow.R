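# Flow-cytometry quadrant quantification: per-channel gates derived from a
# secondary-antibody control at a fixed false-positive rate, rectangular
# quadrant classification and conditional co-occurrence ratios.

check_event_table <- function(x, name) {
    if (!is.data.frame(x) || !all(c("intensity_a", "intensity_b") %in% names(x)))
        stop(sprintf("'%s' must be a data.frame with intensity_a and intensity_b",
                     name))
    if (nrow(x) < 1) stop(sprintf("'%s' has no events", name))
    if (any(!is.finite(x$intensity_a)) || any(!is.finite(x$intensity_b)))
        stop(sprintf("'%s' contains non-finite intensities", name))
    invisible(x)
}

nearest_rank_quantile <- function(x, p) {
    xs <- sort(x)
    xs[max(1L, ceiling(p * length(xs)))]
}

#' Derive per-channel gates from a secondary-antibody control
#'
#' The threshold for each channel is the nearest-rank (1 - `control_fpr`)
#' empirical quantile of the control intensities, so the gate is an observed
#' intensity and classifying the control itself (by strict exceedance) yields
#' at most `control_fpr + 1/n` positives per channel.  Gates are independent
#' per channel (rectangular quadrants).
#'
#' @param control event table (data.frame with `intensity_a`, `intensity_b`)
#'   of at least 100 events.
#' @param control_fpr target control false-positive rate (default 0.01).
#' @return An object of class `gate_spec` with `threshold_a`, `threshold_b`,
#'   `control_fpr` and the realized control positive fractions.
#' @export
derive_gate <- function(control, control_fpr = 0.01) {
    check_event_table(control, "control")
    stopifnot_scalar_num(control_fpr, "control_fpr", 0, 1)
    n <- nrow(control)
    if (n < 100) stop("control must have at least 100 events")
    ta <- nearest_rank_quantile(control$intensity_a, 1 - control_fpr)
    tb <- nearest_rank_quantile(control$intensity_b, 1 - control_fpr)
    realized_a <- mean(control$intensity_a > ta)
    realized_b <- mean(control$intensity_b > tb)
    if (realized_a > control_fpr + 1 / n || realized_b > control_fpr + 1 / n)
        stop("gate calibration failed on the control table")
    structure(list(threshold_a = ta, threshold_b = tb,
                   control_fpr = control_fpr,
                   realized_fpr_a = realized_a, realized_fpr_b = realized_b,
                   n_control = n),
              class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
    cat(sprintf(
        "<gate_spec> thresholds A %.4g / B %.4g (control FPR %.3g; realized %.4g / %.4g)\n",
        x$threshold_a, x$threshold_b, x$control_fpr,
        x$realized_fpr_a, x$realized_fpr_b))
    invisible(x)
}

#' Quadrant percentages and conditional co-occurrence ratios
#'
#' Events are classified by strict exceedance of each per-channel threshold
#' into the four rectangular quadrants; percentages are over all events and
#' sum to 100 exactly.  The conditional ratios report what percentage of
#' single-positive events is double-positive, e.g.
#' `conditional_b_given_a = 100 * pct_double / pct_a_pos` (undefined when
#' the denominator is 0).
#'
#' @param sample event table (data.frame with `intensity_a`, `intensity_b`).
#' @param gate a [derive_gate()] result (or any list with `threshold_a`,
#'   `threshold_b`).
#' @return An object of class `quadrant_stats` with `pct_a_pos`,
#'   `pct_b_pos`, `pct_double`, `pct_neg`, `conditional_b_given_a`,
#'   `conditional_a_given_b` (all in percent).
#' @examples
#' # printed quadrant percentages give the headline ratio directly:
#' conditional_ratio(10.49, 10.85)  # ~96.7
#' @export
quadrant_stats <- function(sample, gate) {
    check_event_table(sample, "sample")
    a_pos <- sample$intensity_a > gate$threshold_a
    b_pos <- sample$intensity_b > gate$threshold_b
    n <- nrow(sample)
    pct_double <- 100 * sum(a_pos & b_pos) / n
    pct_a_only <- 100 * sum(a_pos & !b_pos) / n
    pct_b_only <- 100 * sum(!a_pos & b_pos) / n
    pct_neg <- 100 * sum(!a_pos & !b_pos) / n
    pct_a <- pct_double + pct_a_only
    pct_b <- pct_double + pct_b_only
    structure(list(pct_a_pos = pct_a, pct_b_pos = pct_b,
                   pct_double = pct_double, pct_neg = pct_neg,
                   pct_a_only = pct_a_only, pct_b_only = pct_b_only,
                   conditional_b_given_a = conditional_ratio(pct_double, pct_a),
                   conditional_a_given_b = conditional_ratio(pct_double, pct_b),
                   n_events = n),
              class = "quadrant_stats")
}

#' Conditional co-occurrence ratio from quadrant percentages
#'
#' `100 * pct_double / pct_single`: the percentage of single-positive events
#' that is double-positive.  Works directly on printed quadrant percentages.
#'
#' @param pct_double double-positive percentage.
#' @param pct_single single-channel positive percentage.
#' @return Percentage in \[0, 100\], or `NA` when `pct_single` is 0.
#' @examples
#' conditional_ratio(10.49, 42.38)  # ~24.8
#' @export
conditional_ratio <- function(pct_double, pct_single) {
    if (pct_single <= 0) return(NA_real_)
    100 * pct_double / pct_single
}

#' @export
print.quadrant_stats <- function(x, ...) {
    cat(sprintf(
        "<quadrant_stats> A+ %.2f%% | B+ %.2f%% | double %.2f%% | neg %.2f%%\n",
        x$pct_a_pos, x$pct_b_pos, x$pct_double, x$pct_neg))
    cat(sprintf("  B|A = %.1f%%, A|B = %.1f%% (n = %d)\n",
                x$conditional_b_given_a, x$conditional_a_given_b, x$n_events))
    invisible(x)
}
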