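# Monte Carlo shuffle null model for spot proximity: cumulative minimal
# center-to-center distance distributions, a 95% pointwise envelope over
# shuffled iterations, and a signed-rank comparison of per-image medians.

#' Cumulative distribution of minimal center-to-center distances
#'
#' For each reference (A) centroid, the Euclidean nm distance to the nearest
#' B centroid, returned sorted with empirical cumulative frequencies k/n.
#'
#' @param A,B [spot_set()]s; `B` must be non-empty.
#' @return An object of class `distance_cfd` with `distances` (sorted nm),
#'   `cumfreq` and `n_reference`.
#' @export
min_distance_cfd <- function(A, B) {
    stopifnot(inherits(A, "spot_set"), inherits(B, "spot_set"))
    if (n_spots(B) == 0)
        stop("B is empty: minimal distances are undefined")
    d <- sort(nn_min_dist(A$centroids, B$centroids))
    structure(list(distances = d,
                   cumfreq = seq_along(d) / length(d),
                   n_reference = length(d)),
              class = "distance_cfd")
}

#' Uniformly re-place a spot set's centroids within its field
#'
#' The shuffle null: same object count and field extents, new coordinates
#' i.i.d. uniform over the full field cuboid.  When a mask is supplied the
#' shuffle domain is restricted to mask-true voxels (uniform over the
#' masked volume, by rejection), for fields where spots are confined to a
#' sub-volume such as neuropil.
#'
#' @param S a [spot_set()].
#' @param seed integer seed (optional).
#' @param mask optional [segment_mask()] result to restrict the domain.
#' @return A [spot_set()] with shuffled centroids.
#' @export
shuffle_centroids <- function(S, seed = NULL, mask = NULL) {
    stopifnot(inherits(S, "spot_set"))
    with_seed(seed, {
        n <- n_spots(S)
        ext <- S$field_size_nm
        draw <- function(m) cbind(runif(m, 0, ext[1]), runif(m, 0, ext[2]),
                                  runif(m, 0, ext[3]))
        pts <- draw(n)
        if (!is.null(mask)) {
            stopifnot(inherits(mask, "binary_mask"))
            if (!any(mask$mask)) stop("mask is empty: nowhere to shuffle")
            repeat {
                vox <- centroid_voxel(pts, mask$voxel_size_nm,
                                      dim(mask$mask))
                bad <- which(!mask$mask[vox])
                if (length(bad) == 0) break
                pts[bad, ] <- draw(length(bad))
            }
        }
        spot_set(pts, S$peak_intensities, S$labels, S$source_channel, ext)
    })
}

#' Monte Carlo shuffle envelope of the minimal-distance CFD
#'
#' Shuffles the B channel `n_iterations` times (default 100), evaluates each
#' null CFD on a common 64-point distance grid spanning \[0, 95th percentile
#' of the pooled distances\], and returns the mean null CFD with its
#' pointwise 95% envelope (2.5th/97.5th percentiles across iterations), the
#' per-iteration median minimal distances, the observed median, and the
#' median of the mean null distribution (the distance at which the mean null
#' CFD reaches 0.5).
#'
#' @param A,B [spot_set()]s; A is the reference channel, B is shuffled.
#' @param n_iterations number of shuffles (>= 2).
#' @param seed master seed; per-iteration child seeds are derived
#'   deterministically, so results are reproducible.
#' @param grid_points number of grid points for the common distance grid.
#' @return An object of class `shuffle_envelope`.
#' @export
shuffle_envelope <- function(A, B, n_iterations = 100, seed = 1L,
                             grid_points = 64) {
    stopifnot(inherits(A, "spot_set"), inherits(B, "spot_set"))
    if (n_iterations < 2)
        stop("n_iterations must be >= 2 for a defined envelope")
    observed <- min_distance_cfd(A, B)
    seeds <- child_seeds(seed, n_iterations)
    null_d <- lapply(seq_len(n_iterations), function(i)
        sort(nn_min_dist(A$centroids,
                         shuffle_centroids(B, seeds[i])$centroids)))
    pooled <- c(observed$distances, unlist(null_d))
    grid <- seq(0, quantile(pooled, 0.95, names = FALSE),
                length.out = grid_points)
    n_ref <- observed$n_reference
    cfd_mat <- vapply(null_d, function(d) findInterval(grid, d) / n_ref,
                      numeric(grid_points))
    mean_cfd <- rowMeans(cfd_mat)
    ci <- apply(cfd_mat, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
    # distance at which the mean null CFD crosses 0.5
    null_median <- if (all(mean_cfd < 0.5)) NA_real_
        else approx(c(0, mean_cfd), c(0, grid), xout = 0.5, ties = "ordered")$y
    structure(
        list(observed = observed,
             n_iterations = n_iterations,
             grid = grid,
             observed_cfd = findInterval(grid, observed$distances) / n_ref,
             mean_null_cfd = mean_cfd,
             ci_low = ci[1, ], ci_high = ci[2, ],
             per_iteration_medians = vapply(null_d, median, numeric(1)),
             observed_median = median(observed$distances),
             null_median = null_median,
             seed = seed),
        class = "shuffle_envelope")
}

#' @export
print.shuffle_envelope <- function(x, ...) {
    cat(sprintf(
        "<shuffle_envelope> %d iterations; observed median %.0f nm, null median %.0f nm\n",
        x$n_iterations, x$observed_median, x$null_median))
    invisible(x)
}

#' Plot observed vs shuffled cumulative distance distributions
#'
#' Observed CFD against the mean shuffled CFD with its 95% envelope.
#'
#' @param x a [shuffle_envelope()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.shuffle_envelope <- function(x, ...) {
    graphics::plot(x$grid, x$observed_cfd, type = "s", lwd = 2,
                   xlab = "minimal center-to-center distance (nm)",
                   ylab = "cumulative frequency", ylim = c(0, 1), ...)
    graphics::polygon(c(x$grid, rev(x$grid)), c(x$ci_low, rev(x$ci_high)),
                      col = grDevices::adjustcolor("grey60", 0.4), border = NA)
    graphics::lines(x$grid, x$mean_null_cfd, lty = 2)
    graphics::legend("bottomright",
                     legend = c("observed", "mean shuffled", "95% envelope"),
                     lwd = c(2, 1, 8), lty = c(1, 2, 1),
                     col = c("black", "black",
                             grDevices::adjustcolor("grey60", 0.4)),
                     bty = "n")
    invisible(x)
}

#' Signed-rank comparison of observed vs mean-null medians across images
#'
#' Two-sided Wilcoxon signed-rank test on paired per-image medians (observed
#' median minimal distance vs the median of the mean shuffled distribution).
#' When every pair is identical the test is degenerate: p = 1 is reported
#' with a flag and no rejection.
#'
#' @param observed_medians,null_medians paired numeric vectors (one value
#'   per image; at least 6 pairs).
#' @return A list with `statistic`, `p_value`, `n`, `median_difference` and
#'   `degenerate`.
#' @export
compare_observed_vs_null <- function(observed_medians, null_medians) {
    if (length(observed_medians) != length(null_medians))
        stop("paired vectors must have equal length")
    n <- length(observed_medians)
    if (n < 6) stop("at least 6 paired images are required")
    diffs <- observed_medians - null_medians
    if (all(diffs == 0))
        return(list(statistic = NA_real_, p_value = 1, n = n,
                    median_difference = 0, degenerate = TRUE))
    wt <- suppressWarnings(
        wilcox.test(observed_medians, null_medians, paired = TRUE,
                    alternative = "two.sided", exact = NULL))
    list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n,
         median_difference = median(diffs), degenerate = FALSE)
}
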