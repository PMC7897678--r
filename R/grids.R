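#' A single-channel 3D image with physical voxel sizes
#'
#' The raw substrate for spot segmentation: a 3D array of intensities on the
#' 16-bit (0--65,535) scale, ordered x (fastest), y, z, together with the
#' physical voxel size in nanometres.  The physical coordinate of voxel
#' `(i, j, k)` (1-based) is `(i - 0.5, j - 0.5, k - 0.5) * voxel_size_nm`
#' (voxel-centre convention); all downstream distances are in nm.
#'
#' @param intensities numeric 3D array, values in \[0, 65535\], at least 8
#'   voxels per axis.
#' @param voxel_size_nm numeric 3-vector of voxel edge lengths (nm).
#' @param channel_name character scalar naming the channel.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(8, 8, 8)), c(50, 50, 150), "syp")
#' dim(g$intensities)
#' @export
voxel_grid <- function(intensities, voxel_size_nm, channel_name = "channel") {
    if (!is.array(intensities) || length(dim(intensities)) != 3L)
        stop("'intensities' must be a 3D array")
    if (any(dim(intensities) < 8L))
        stop("grid must have at least 8 voxels per axis")
    rng <- range(intensities)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 65535)
        stop("intensities must be finite and within [0, 65535]")
    check_len3(voxel_size_nm, "voxel_size_nm")
    structure(
        list(intensities = intensities,
             voxel_size_nm = as.numeric(voxel_size_nm),
             channel_name = as.character(channel_name)[1]),
        class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
    d <- dim(x$intensities)
    cat(sprintf("<voxel_grid> channel '%s': %d x %d x %d voxels @ (%g, %g, %g) nm\n",
                x$channel_name, d[1], d[2], d[3],
                x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]))
    cat(sprintf("  intensity range [%g, %g]\n",
                min(x$intensities), max(x$intensities)))
    invisible(x)
}

# Physical field extent (nm) of a grid.
field_extent <- function(grid) dim(grid$intensities) * grid$voxel_size_nm

#' A set of point objects (spot centroids) for one channel
#'
#' Holds the geometrical centres of segmented (or planted) fluorescent spots
#' in physical nm coordinates, with peak intensities, unique integer labels
#' and a border flag for spots whose segmented region touches the image edge.
#'
#' @param centroids numeric matrix with 3 columns (x, y, z in nm) or a
#'   0-row matrix for an empty set.
#' @param peak_intensities numeric vector, one per spot.
#' @param labels integer vector of unique positive labels; defaults to
#'   `seq_len(nrow(centroids))`.
#' @param source_channel character scalar.
#' @param field_size_nm numeric 3-vector: physical extents of the field.
#' @param border_flag logical vector, one per spot (default all `FALSE`).
#' @return An object of class `spot_set`.
#' @export
spot_set <- function(centroids, peak_intensities = NULL, labels = NULL,
                     source_channel = "channel", field_size_nm,
                     border_flag = NULL) {
    centroids <- matrix(as.numeric(centroids), ncol = 3,
                        dimnames = list(NULL, c("x_nm", "y_nm", "z_nm")))
    n <- nrow(centroids)
    check_len3(field_size_nm, "field_size_nm")
    if (n > 0) {
        for (ax in 1:3)
            if (any(centroids[, ax] < 0 | centroids[, ax] > field_size_nm[ax]))
                stop("centroids must lie within [0, field extent] on every axis")
    }
    if (is.null(peak_intensities)) peak_intensities <- rep(NA_real_, n)
    if (is.null(labels)) labels <- seq_len(n)
    if (is.null(border_flag)) border_flag <- rep(FALSE, n)
    labels <- as.integer(labels)
    if (anyDuplicated(labels)) stop("labels must be unique")
    if (length(peak_intensities) != n || length(labels) != n ||
        length(border_flag) != n)
        stop("centroids, peak_intensities, labels and border_flag lengths differ")
    structure(
        list(centroids = centroids,
             peak_intensities = as.numeric(peak_intensities),
             labels = labels,
             border_flag = as.logical(border_flag),
             source_channel = as.character(source_channel)[1],
             field_size_nm = as.numeric(field_size_nm)),
        class = "spot_set")
}

#' Number of spots in a spot set
#' @param S a `spot_set`.
#' @return Integer count.
#' @export
n_spots <- function(S) nrow(S$centroids)

#' Subset a spot set
#' @param x a `spot_set`.
#' @param i index vector (logical or integer over spots).
#' @param ... ignored.
#' @return A `spot_set` containing the selected spots, labels preserved.
#' @export
`[.spot_set` <- function(x, i, ...) {
    spot_set(x$centroids[i, , drop = FALSE], x$peak_intensities[i],
             x$labels[i], x$source_channel, x$field_size_nm, x$border_flag[i])
}

#' @export
print.spot_set <- function(x, ...) {
    cat(sprintf("<spot_set> channel '%s': %d spots in %g x %g x %g nm field\n",
                x$source_channel, n_spots(x), x$field_size_nm[1],
                x$field_size_nm[2], x$field_size_nm[3]))
    invisible(x)
}

#' @export
as.data.frame.spot_set <- function(x, ...) {
    data.frame(label = x$labels,
               x_nm = x$centroids[, 1], y_nm = x$centroids[, 2],
               z_nm = x$centroids[, 3], peak = x$peak_intensities,
               border_flag = x$border_flag)
}

# Voxel (1-based array) index containing each centroid; errors on
# out-of-field coordinates.
centroid_voxel <- function(centroids, voxel_size_nm, dims) {
    if (nrow(centroids) == 0)
        return(matrix(integer(0), ncol = 3))
    idx <- sapply(1:3, function(ax) {
        i <- floor(centroids[, ax] / voxel_size_nm[ax]) + 1L
        i[centroids[, ax] >= dims[ax] * voxel_size_nm[ax]] <- dims[ax]
        if (any(i < 1L | i > dims[ax]))
            stop("centroid coordinate outside the image field")
        as.integer(i)
    })
    matrix(idx, ncol = 3)
}
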