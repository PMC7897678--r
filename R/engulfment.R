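# Microglial engulfment: reconstruct the cell volume from a marker channel
# by intensity thresholding and count which tagged synaptic centroids fall
# inside it.

#' Reconstruct a binary volume mask by intensity thresholding
#'
#' The mask is true where intensity >= `threshold`.  By default fully
#' enclosed cavities are filled (background components not connected to the
#' image border become mask), so spots inside an unevenly stained soma still
#' count as engulfed.  Optionally only the largest connected component is
#' kept.
#'
#' @param grid a [voxel_grid()] of the microglia marker channel (e.g. Iba1).
#' @param threshold intensity threshold in \[0, 65535\].
#' @param fill_cavities fill fully enclosed background cavities
#'   (default `TRUE`).
#' @param largest_component keep only the largest 6-connected component
#'   (default `FALSE`).
#' @return An object of class `binary_mask` with the logical 3D `mask`,
#'   `voxel_size_nm` and `source_threshold`.
#' @export
segment_mask <- function(grid, threshold, fill_cavities = TRUE,
                         largest_component = FALSE) {
    stopifnot(inherits(grid, "voxel_grid"))
    stopifnot_scalar_num(threshold, "threshold", 0, 65535)
    m <- grid$intensities >= threshold
    dims <- dim(m)
    if (largest_component && any(m)) {
        lab <- cc_label3d(as.logical(m), as.integer(dims))
        sizes <- tabulate(lab[lab > 0])
        m <- array(lab == which.max(sizes), dims)
    }
    if (fill_cavities && any(!m)) {
        bg <- cc_label3d(as.logical(!m), as.integer(dims))
        bga <- array(bg, dims)
        border_labs <- unique(c(bga[c(1, dims[1]), , ], bga[, c(1, dims[2]), ],
                                bga[, , c(1, dims[3])]))
        border_labs <- border_labs[border_labs > 0]
        cavity <- bga > 0 & !(bga %in% border_labs)
        m <- m | array(cavity, dims)
    }
    structure(list(mask = m, voxel_size_nm = grid$voxel_size_nm,
                   source_threshold = threshold),
              class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
    cat(sprintf("<binary_mask> %s voxels, %.2f%% true (threshold %g)\n",
                paste(dim(x$mask), collapse = " x "),
                100 * mean(x$mask), x$source_threshold))
    invisible(x)
}

#' Are centroids inside a binary mask?
#'
#' In the default `"centroid"` mode a spot is inside iff the voxel
#' containing its centroid is mask-true.  The stricter `"ellipsoid"` mode
#' requires every voxel whose centre falls within the PSF ellipsoid around
#' the centroid to be mask-true (the whole spot engulfed, not just its
#' centre).
#'
#' @param S a [spot_set()] (coordinates must lie within the mask's field).
#' @param mask a [segment_mask()] result.
#' @param mode `"centroid"` (default) or `"ellipsoid"`.
#' @param ellipsoid an [ellipsoid_spec()] used by the `"ellipsoid"` mode.
#' @return Logical vector, one element per spot.
#' @export
spots_in_mask <- function(S, mask, mode = c("centroid", "ellipsoid"),
                          ellipsoid = ellipsoid_spec()) {
    stopifnot(inherits(S, "spot_set"), inherits(mask, "binary_mask"))
    mode <- match.arg(mode)
    vox <- centroid_voxel(S$centroids, mask$voxel_size_nm, dim(mask$mask))
    if (nrow(vox) == 0) return(logical(0))
    inside <- mask$mask[vox]
    if (mode == "ellipsoid") {
        dims <- dim(mask$mask)
        vx <- mask$voxel_size_nm
        semi <- c(ellipsoid$a_nm, ellipsoid$a_nm, ellipsoid$c_nm)
        nmax <- ceiling(semi / vx)
        off <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2],
                                     -nmax[3]:nmax[3]))
        for (i in which(inside)) {
            nb <- sweep(off, 2, vox[i, ], "+")
            ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
                  nb[, 2] >= 1 & nb[, 2] <= dims[2] &
                  nb[, 3] >= 1 & nb[, 3] <= dims[3]
            ctr <- sweep(nb - 0.5, 2, vx, "*")
            d <- sweep(sweep(ctr, 2, S$centroids[i, ], "-"), 2, semi, "/")
            within <- rowSums(d^2) <= 1 + 1e-12
            # a spot is engulfed only if its whole ellipsoid stays in the
            # field and every covered voxel is mask-true
            if (any(within & !ok) || !all(mask$mask[nb[within & ok, ,
                                                       drop = FALSE]]))
                inside[i] <- FALSE
        }
    }
    inside
}

#' Count engulfed tagged synaptic spots, with and without a second marker
#'
#' Given the C1q-colocalized synaptophysin centroids of one image and the
#' reconstructed microglial mask, counts how many of them lie inside the
#' mask and what fraction of those also carries the NP flag.
#'
#' @param syp_tagged a [spot_set()] of C1q-colocalized Syp centroids (or all
#'   Syp centroids together with `c1q_positive`).
#' @param mask a [segment_mask()] result.
#' @param np_positive logical vector, one per spot: NP-colocalized?
#' @param c1q_positive optional logical vector; when given, analysis is
#'   restricted to the flagged (C1q-positive) spots.
#' @param mode containment mode, see [spots_in_mask()].
#' @return An object of class `engulfment_result`: `n_tagged_inside`,
#'   `n_tagged_inside_with_NP`, `fraction_NP_positive` (`NA` when nothing is
#'   inside — undefined, distinct from 0).
#' @export
count_engulfed <- function(syp_tagged, mask, np_positive,
                           c1q_positive = NULL, mode = "centroid") {
    stopifnot(inherits(syp_tagged, "spot_set"))
    if (length(np_positive) != n_spots(syp_tagged))
        stop("np_positive must have one flag per spot")
    if (!is.null(c1q_positive)) {
        syp_tagged <- syp_tagged[c1q_positive]
        np_positive <- np_positive[c1q_positive]
    }
    inside <- spots_in_mask(syp_tagged, mask, mode)
    n_in <- sum(inside)
    n_np <- sum(inside & np_positive)
    structure(list(n_tagged_inside = n_in,
                   n_tagged_inside_with_NP = n_np,
                   fraction_NP_positive = if (n_in > 0) n_np / n_in
                                          else NA_real_),
              class = "engulfment_result")
}

#' @export
print.engulfment_result <- function(x, ...) {
    cat(sprintf("<engulfment_result> %d tagged spots inside; %d NP-positive (%s)\n",
                x$n_tagged_inside, x$n_tagged_inside_with_NP,
                if (is.na(x$fraction_NP_positive)) "undefined"
                else sprintf("%.1f%%", 100 * x$fraction_NP_positive)))
    invisible(x)
}

#' Sensitivity of the engulfment fraction to the mask threshold
#'
#' The marker-channel segmentation threshold is a required analysis choice;
#' this utility reports the NP-positive fraction (and counts) across a sweep
#' of thresholds so its influence can be audited.
#'
#' @param grid the microglia marker [voxel_grid()].
#' @param syp_tagged,np_positive,c1q_positive as in [count_engulfed()].
#' @param thresholds numeric vector of mask thresholds.
#' @param ... passed to [segment_mask()].
#' @return data.frame with one row per threshold.
#' @export
engulfment_threshold_sweep <- function(grid, syp_tagged, np_positive,
                                       thresholds, c1q_positive = NULL, ...) {
    rows <- lapply(thresholds, function(thr) {
        res <- count_engulfed(syp_tagged, segment_mask(grid, thr, ...),
                              np_positive, c1q_positive)
        data.frame(threshold = thr, n_tagged_inside = res$n_tagged_inside,
                   n_tagged_inside_with_NP = res$n_tagged_inside_with_NP,
                   fraction_NP_positive = res$fraction_NP_positive)
    })
    do.call(rbind, rows)
}
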