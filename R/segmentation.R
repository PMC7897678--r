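# 3D spot segmentation: local-maxima seeding followed by seeded watershed
# with local-mean thresholding, centroids in physical nm coordinates.

#' Segmentation parameters
#'
#' @param maxima_radius_nm anisotropic search radius (x, y, z, nm) for local
#'   maxima; default one PSF ellipsoid (200 nm lateral, 500 nm axial).
#' @param noise_floor intensity below which maxima are ignored.
#' @param threshold hard intensity floor for spot voxels; the field-standard
#'   working range on the 16-bit scale is 5000--7000 (default 6000).
#' @param local_mean_window_nm box window (x, y, z, nm) for the local-mean
#'   threshold around each seed; default 3x the maxima radius.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(maxima_radius_nm = c(200, 200, 500),
                                noise_floor = 3000,
                                threshold = 6000,
                                local_mean_window_nm = 3 * maxima_radius_nm) {
    check_len3(maxima_radius_nm, "maxima_radius_nm")
    check_len3(local_mean_window_nm, "local_mean_window_nm")
    stopifnot_scalar_num(noise_floor, "noise_floor", 0, 65535)
    stopifnot_scalar_num(threshold, "threshold", 0, 65535)
    structure(list(maxima_radius_nm = as.numeric(maxima_radius_nm),
                   noise_floor = noise_floor, threshold = threshold,
                   local_mean_window_nm = as.numeric(local_mean_window_nm)),
              class = "segmentation_params")
}

# Voxel offsets inside the anisotropic search ellipsoid, excluding (0,0,0).
maxima_offsets <- function(radius_nm, voxel_size_nm) {
    if (any(radius_nm < voxel_size_nm))
        stop("maxima radius must be at least one voxel on every axis")
    nmax <- floor(radius_nm / voxel_size_nm)
    off <- as.matrix(expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2],
                                 dz = -nmax[3]:nmax[3]))
    sc <- sweep(sweep(off, 2, voxel_size_nm, "*"), 2, radius_nm, "/")
    keep <- rowSums(sc^2) <= 1 + 1e-12
    keep[off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0] <- FALSE
    off[keep, , drop = FALSE]
}

#' Find local intensity maxima in a 3D channel
#'
#' Returns every voxel whose intensity is strictly greater than all other
#' voxels within the anisotropic search radius and at least `noise_floor`.
#' Out-of-field neighbours impose no constraint, so maxima at the image
#' border are permitted (flagged via `border_flag`).  Coordinates are
#' reported in nm at voxel centres.
#'
#' @param grid a [voxel_grid()].
#' @param params a [segmentation_params()].
#' @return A [spot_set()] of seed points.
#' @export
find_local_maxima <- function(grid, params) {
    stopifnot(inherits(grid, "voxel_grid"),
              inherits(params, "segmentation_params"))
    img <- grid$intensities
    dims <- dim(img)
    off <- maxima_offsets(params$maxima_radius_nm, grid$voxel_size_nm)
    cand <- which(img >= params$noise_floor)
    if (length(cand) == 0)
        return(spot_set(matrix(numeric(0), ncol = 3),
                        source_channel = grid$channel_name,
                        field_size_nm = field_extent(grid)))
    co <- arrayInd(cand, dims)
    ok <- rep(TRUE, length(cand))
    n12 <- dims[1] * dims[2]
    for (k in seq_len(nrow(off))) {
        act <- which(ok)
        if (length(act) == 0) break
        nx <- co[act, 1] + off[k, 1]
        ny <- co[act, 2] + off[k, 2]
        nz <- co[act, 3] + off[k, 3]
        inside <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
                  nz >= 1 & nz <= dims[3]
        ai <- act[inside]
        if (length(ai) == 0) next
        nb <- nx[inside] + (ny[inside] - 1) * dims[1] + (nz[inside] - 1) * n12
        ok[ai] <- img[cand[ai]] > img[nb]
    }
    keep <- which(ok)
    co <- co[keep, , drop = FALSE]
    centers <- sweep(co - 0.5, 2, grid$voxel_size_nm, "*")
    border <- co[, 1] == 1 | co[, 1] == dims[1] |
              co[, 2] == 1 | co[, 2] == dims[2] |
              co[, 3] == 1 | co[, 3] == dims[3]
    spot_set(centers, peak_intensities = img[cand[keep]],
             source_channel = grid$channel_name,
             field_size_nm = field_extent(grid), border_flag = border)
}

# Per-seed local threshold: mean intensity in the local-mean box window
# around the seed, floored at the global threshold.
local_thresholds <- function(img, seed_vox, window_nm, voxel_size_nm,
                             floor_thr) {
    dims <- dim(img)
    hw <- pmax(0L, floor(window_nm / (2 * voxel_size_nm)))
    vapply(seq_len(nrow(seed_vox)), function(s) {
        lo <- pmax(1L, seed_vox[s, ] - hw)
        hi <- pmin(dims, seed_vox[s, ] + hw)
        max(mean(img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]), floor_thr)
    }, numeric(1))
}

#' Segment spots around seed maxima by watershed with local-mean thresholds
#'
#' Each returned object is a 6-connected voxel region grown from exactly one
#' seed by priority flooding (watershed on the inverted intensity image with
#' the seeds as markers); region voxels must reach a local threshold equal to
#' the mean intensity in the `local_mean_window_nm` box around the seed,
#' floored at `params$threshold`.  Watershed lines split touching spots
#' between competing seeds (deterministic first-come tie-breaking).  The
#' reported centroid is the intensity-weighted centre of the region in nm.
#'
#' @param grid a [voxel_grid()].
#' @param seeds a [spot_set()] of seed points from [find_local_maxima()] on
#'   the same grid.
#' @param params a [segmentation_params()].
#' @return A [spot_set()] of segmented objects (empty when no seed reaches
#'   its threshold).
#' @export
segment_spots <- function(grid, seeds, params) {
    stopifnot(inherits(grid, "voxel_grid"), inherits(seeds, "spot_set"),
              inherits(params, "segmentation_params"))
    img <- grid$intensities
    dims <- dim(img)
    empty <- spot_set(matrix(numeric(0), ncol = 3),
                      source_channel = grid$channel_name,
                      field_size_nm = field_extent(grid))
    if (n_spots(seeds) == 0) return(empty)
    seed_vox <- centroid_voxel(seeds$centroids, grid$voxel_size_nm, dims)
    thr <- local_thresholds(img, seed_vox, params$local_mean_window_nm,
                            grid$voxel_size_nm, params$threshold)
    seed_lin0 <- (seed_vox[, 1] - 1L) +
                 dims[1] * ((seed_vox[, 2] - 1L) +
                            dims[2] * (seed_vox[, 3] - 1L))
    lab <- ws_flood3d(as.numeric(img), as.integer(dims),
                      as.integer(seed_lin0), thr)
    idx <- which(lab > 0)
    if (length(idx) == 0) return(empty)
    li <- lab[idx]
    w <- img[idx]
    co <- arrayInd(idx, dims)
    sw <- tapply(w, li, sum)
    kept <- as.integer(names(sw))
    cx <- tapply(w * (co[, 1] - 0.5), li, sum) / sw
    cy <- tapply(w * (co[, 2] - 0.5), li, sum) / sw
    cz <- tapply(w * (co[, 3] - 0.5), li, sum) / sw
    centers <- cbind(cx * grid$voxel_size_nm[1], cy * grid$voxel_size_nm[2],
                     cz * grid$voxel_size_nm[3])
    border <- tapply(co[, 1] == 1 | co[, 1] == dims[1] |
                     co[, 2] == 1 | co[, 2] == dims[2] |
                     co[, 3] == 1 | co[, 3] == dims[3], li, any)
    peaks <- img[seed_lin0[kept] + 1L]
    spot_set(centers, peak_intensities = as.numeric(peaks),
             labels = seq_along(kept),
             source_channel = grid$channel_name,
             field_size_nm = field_extent(grid),
             border_flag = as.logical(border))
}

#' Segment one channel end to end
#'
#' Convenience wrapper: [find_local_maxima()] then [segment_spots()].
#'
#' @inheritParams segment_spots
#' @return A [spot_set()] of segmented spots.
#' @export
segment_channel <- function(grid, params = segmentation_params()) {
    segment_spots(grid, find_local_maxima(grid, params), params)
}
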