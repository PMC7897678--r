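# Sub-synaptic fraction deconvolution: compartment-exclusive markers define
# a 3x3 mixing matrix (per-fraction compartment composition), whose
# inversion converts per-fraction protein signals into per-compartment
# levels (x = synaptic plasma membrane, y = cytoplasm, z = mitochondria).

COMPARTMENTS <- c("SPM", "cytoplasm", "mitochondria")

#' Build a mixing matrix from compartment-marker densitometry
#'
#' Each marker is treated as exclusive to its compartment (Psd95 -> SPM,
#' Ldhb -> cytoplasm, Cox4 -> mitochondria).  Column k of the mixing matrix
#' is marker k's signal per measured fraction divided by that marker's total
#' across the three fractions, i.e. each marker's signal fully distributed
#' across the preparations; the matrix is invariant to rescaling any single
#' marker.  A row-composition alternative (rows normalized instead of
#' columns) is available behind `normalize = "row"`.
#'
#' @param marker_signals 3x3 numeric matrix: rows = measured fractions
#'   (SPM, cytoplasm, mitochondria preparations), columns = markers in
#'   compartment order.  All entries must be >= 0 and no marker may be
#'   all-zero.
#' @param normalize `"column"` (default) or `"row"`.
#' @param max_condition condition number above which an ill-conditioning
#'   warning is raised.
#' @return An object of class `mixing_matrix` (a 3x3 matrix with attributes).
#' @examples
#' sig <- cbind(c(8, 1, 1), c(1.5, 8, 0.5), c(0.5, 1, 8.5))
#' build_mixing_matrix(sig)
#' @export
build_mixing_matrix <- function(marker_signals, normalize = c("column", "row"),
                                max_condition = 1e6) {
    normalize <- match.arg(normalize)
    M <- as.matrix(marker_signals)
    if (!all(dim(M) == c(3, 3))) stop("marker_signals must be 3x3")
    if (any(M < 0) || any(!is.finite(M)))
        stop("marker signals must be finite and >= 0")
    if (normalize == "column") {
        tot <- colSums(M)
        if (any(tot == 0)) stop("degenerate marker: all-zero across fractions")
        M <- sweep(M, 2, tot, "/")
    } else {
        tot <- rowSums(M)
        if (any(tot == 0)) stop("degenerate fraction: all-zero marker signals")
        M <- sweep(M, 1, tot, "/")
    }
    kap <- kappa(M, exact = TRUE)
    if (!is.finite(kap) || kap > max_condition)
        warning(sprintf("mixing matrix is ill-conditioned (condition %.3g)",
                        kap))
    dimnames(M) <- list(fraction = COMPARTMENTS, compartment = COMPARTMENTS)
    structure(M, class = c("mixing_matrix", "matrix"),
              normalize = normalize, condition = kap)
}

#' Solve per-compartment protein levels from per-fraction signals
#'
#' Exact solve of the 3x3 linear system `M %*% levels = observed`.  Negative
#' components are reported as-is with a flag (no constraint by default); an
#' optional non-negative least-squares mode (exact active-set enumeration
#' for the 3x3 case) is available for noisy data.
#'
#' @param M a [build_mixing_matrix()] result (or nonsingular 3x3 matrix).
#' @param observed numeric 3-vector of protein signal per measured fraction.
#' @param nonneg constrain the solution to be non-negative (default `FALSE`).
#' @return An object of class `compartment_levels`: `levels` (named
#'   3-vector: SPM, cytoplasm, mitochondria), `residual_norm`,
#'   `negative_flag`.
#' @examples
#' M <- build_mixing_matrix(diag(3))
#' solve_compartments(M, c(5, 2, 1))$levels
#' @export
solve_compartments <- function(M, observed, nonneg = FALSE) {
    M <- unclass(as.matrix(M))
    if (!all(dim(M) == c(3, 3))) stop("M must be 3x3")
    check_len3(observed, "observed", positive = FALSE)
    if (any(observed < 0)) stop("observed signals must be >= 0")
    if (abs(det(M)) < 1e-12) stop("mixing matrix is singular")
    if (!nonneg) {
        x <- as.numeric(solve(M, observed))
    } else {
        # exact NNLS for the 3x3 case: try every subset of active
        # (zero-clamped) components, keep the feasible least-squares best
        best <- NULL; best_rss <- Inf
        for (free in 0:7) {
            keep <- which(bitwAnd(free, c(1L, 2L, 4L)) > 0)
            x <- numeric(3)
            if (length(keep) > 0) {
                Mk <- M[, keep, drop = FALSE]
                xk <- tryCatch(
                    as.numeric(solve(crossprod(Mk), crossprod(Mk, observed))),
                    error = function(e) NULL)
                if (is.null(xk) || any(xk < 0)) next
                x[keep] <- xk
            }
            rss <- sum((M %*% x - observed)^2)
            if (rss < best_rss - 1e-15) { best <- x; best_rss <- rss }
        }
        x <- best
    }
    res <- sqrt(sum((M %*% x - observed)^2))
    structure(list(levels = setNames(x, COMPARTMENTS),
                   residual_norm = res,
                   negative_flag = any(x < 0),
                   nonneg = nonneg),
              class = "compartment_levels")
}

#' @export
print.compartment_levels <- function(x, ...) {
    cat("<compartment_levels>\n")
    print(round(x$levels, 4))
    cat(sprintf("  residual %.3g%s\n", x$residual_norm,
                if (x$negative_flag) " [negative component flagged]" else ""))
    invisible(x)
}

#' Deconvolve a fractionation densitometry table per replicate
#'
#' For each replicate, builds the mixing matrix from the marker rows and
#' solves the per-compartment levels of every non-marker protein; then
#' summarizes across replicates (mean +/- SEM per compartment), matching a
#' per-mouse analysis structure.
#'
#' @param tables densitometry data.frame in the layout produced by
#'   [make_fraction_tables()]: columns `fraction`, `marker_or_protein`,
#'   `replicate`, `signal`, `is_marker`.
#' @param markers marker names in compartment order (SPM, cytoplasm,
#'   mitochondria).
#' @param nonneg passed to [solve_compartments()].
#' @return A list with `per_replicate` (data.frame: protein, replicate,
#'   compartment, level) and `summary` (data.frame: protein, compartment,
#'   mean, sem, n).
#' @export
deconvolve_replicates <- function(tables,
                                  markers = c("Psd95", "Ldhb", "Cox4"),
                                  nonneg = FALSE) {
    need <- c("fraction", "marker_or_protein", "replicate", "signal")
    if (!all(need %in% names(tables)))
        stop("tables must have columns fraction, marker_or_protein, replicate, signal")
    fracs <- COMPARTMENTS
    proteins <- setdiff(unique(tables$marker_or_protein), markers)
    rows <- list()
    for (rep_i in sort(unique(tables$replicate))) {
        tb <- tables[tables$replicate == rep_i, ]
        sig <- sapply(markers, function(m)
            vapply(fracs, function(f)
                sum(tb$signal[tb$marker_or_protein == m & tb$fraction == f]),
                numeric(1)))
        M <- build_mixing_matrix(sig)
        for (p in proteins) {
            obs <- vapply(fracs, function(f)
                sum(tb$signal[tb$marker_or_protein == p & tb$fraction == f]),
                numeric(1))
            sol <- solve_compartments(M, obs, nonneg = nonneg)
            rows[[length(rows) + 1L]] <- data.frame(
                protein = p, replicate = rep_i, compartment = COMPARTMENTS,
                level = as.numeric(sol$levels))
        }
    }
    per_rep <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(
        per_rep, list(per_rep$protein, per_rep$compartment), drop = TRUE),
        function(g) {
            s <- summarize_fields(g$level)
            data.frame(protein = g$protein[1], compartment = g$compartment[1],
                       mean = s$mean, sem = s$sem, n = s$n)
        }))
    rownames(summ) <- NULL
    list(per_replicate = per_rep, summary = summ)
}
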