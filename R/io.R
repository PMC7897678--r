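# Plain-text / TIFF interfaces: one single-channel 16-bit TIFF per channel
# (ZYX plane order) with a YAML sidecar for voxel sizes, spot sets and
# ground truth as CSV, colocalization summaries as JSON.

#' Write a voxel grid as a 16-bit TIFF stack with a YAML sidecar
#'
#' Pages are z-planes; within a page rows are y and columns are x.
#' Intensities are rounded to integers on write.
#'
#' @param grid a [voxel_grid()].
#' @param tiff_path output TIFF path.
#' @param sidecar_path metadata YAML path (default: `tiff_path` +
#'   `".meta.yaml"`).
#' @return Invisibly, `tiff_path`.
#' @export
write_voxel_grid <- function(grid, tiff_path,
                             sidecar_path = paste0(tiff_path, ".meta.yaml")) {
    stopifnot(inherits(grid, "voxel_grid"))
    arr <- round(grid$intensities)
    planes <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]) / 65535)
    tiff::writeTIFF(planes, tiff_path, bits.per.sample = 16L)
    yaml::write_yaml(list(channel_name = grid$channel_name,
                          voxel_size_nm = as.numeric(grid$voxel_size_nm),
                          n_voxels = dim(arr),
                          intensity_scale = "16-bit (0-65535)"),
                     sidecar_path)
    invisible(tiff_path)
}

#' Read a 16-bit single-channel TIFF stack into a voxel grid
#'
#' @param tiff_path input TIFF path.
#' @param voxel_size_nm voxel sizes; taken from the sidecar when omitted.
#' @param sidecar_path metadata YAML path.
#' @param channel_name channel name override.
#' @return A [voxel_grid()].
#' @export
read_voxel_grid <- function(tiff_path, voxel_size_nm = NULL,
                            sidecar_path = paste0(tiff_path, ".meta.yaml"),
                            channel_name = NULL) {
    planes <- tiff::readTIFF(tiff_path, all = TRUE)
    if (!is.list(planes)) planes <- list(planes)
    meta <- if (file.exists(sidecar_path)) yaml::read_yaml(sidecar_path) else NULL
    if (is.null(voxel_size_nm)) {
        if (is.null(meta)) stop("voxel_size_nm required when no sidecar exists")
        voxel_size_nm <- as.numeric(meta$voxel_size_nm)
    }
    if (is.null(channel_name))
        channel_name <- meta$channel_name %||% "channel"
    ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
    arr <- array(0, c(nx, ny, length(planes)))
    for (k in seq_along(planes)) arr[, , k] <- t(planes[[k]]) * 65535
    voxel_grid(round(arr), voxel_size_nm, channel_name)
}

#' Write a spot set as CSV
#'
#' Columns: label, x_nm, y_nm, z_nm, peak, border_flag.
#'
#' @param S a [spot_set()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spot_set <- function(S, path) {
    stopifnot(inherits(S, "spot_set"))
    write.csv(as.data.frame(S), path, row.names = FALSE)
    invisible(path)
}

#' Read a spot set from CSV
#'
#' @param path CSV path written by [write_spot_set()].
#' @param source_channel channel name.
#' @param field_size_nm physical field extents (nm).
#' @return A [spot_set()].
#' @export
read_spot_set <- function(path, source_channel, field_size_nm) {
    df <- read.csv(path)
    spot_set(cbind(df$x_nm, df$y_nm, df$z_nm), df$peak, df$label,
             source_channel, field_size_nm,
             if ("border_flag" %in% names(df)) df$border_flag else NULL)
}

#' Write ground-truth centroids as CSV
#'
#' Columns: channel, x_nm, y_nm, z_nm, link_id, in_mask.
#'
#' @param truth the `truth` element of a [make_spot_scene()] result.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
    stopifnot(inherits(truth, "ground_truth"))
    rows <- lapply(names(truth$centroids), function(ch) {
        m <- truth$centroids[[ch]]
        if (nrow(m) == 0) return(NULL)
        link <- rep(NA_integer_, nrow(m))
        ls <- truth$links
        if (nrow(ls) > 0) {
            link[ls$source_index[ls$source_channel == ch]] <-
                ls$link_id[ls$source_channel == ch]
            link[ls$target_index[ls$target_channel == ch]] <-
                ls$link_id[ls$target_channel == ch]
        }
        data.frame(channel = ch, x_nm = m[, 1], y_nm = m[, 2], z_nm = m[, 3],
                   link_id = link, in_mask = NA)
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' Write a colocalization result as CSV pairs plus a JSON summary
#'
#' @param res a [pairwise_coloc()] / [triple_coloc()] result.
#' @param csv_path output CSV path for the pair list.
#' @param json_path output JSON path for counts, fractions and conventions.
#' @return Invisibly, `json_path`.
#' @export
write_coloc_result <- function(res, csv_path, json_path) {
    stopifnot(inherits(res, "coloc_result"))
    write.csv(res$pair_list, csv_path, row.names = FALSE)
    jsonlite::write_json(
        list(n_A = res$n_A, n_B = res$n_B, n_A_coloc = res$n_A_coloc,
             fraction_A_coloc = res$fraction_A_coloc,
             ellipsoid = list(lateral_size_nm = res$spec$lateral_size_nm,
                              axial_size_nm = res$spec$axial_size_nm,
                              size_convention = res$spec$size_convention,
                              tangency_counts_as_overlap = TRUE)),
        json_path, auto_unbox = TRUE, digits = NA)
    invisible(json_path)
}

#' Write a binary mask as an 8-bit TIFF stack
#'
#' @param mask a [segment_mask()] result.
#' @param tiff_path output path (mask voxels stored as 255).
#' @return Invisibly, `tiff_path`.
#' @export
write_binary_mask <- function(mask, tiff_path) {
    stopifnot(inherits(mask, "binary_mask"))
    planes <- lapply(seq_len(dim(mask$mask)[3]),
                     function(k) t(mask$mask[, , k]) * 1)
    tiff::writeTIFF(planes, tiff_path, bits.per.sample = 8L)
    invisible(tiff_path)
}
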