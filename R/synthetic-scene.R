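# Synthetic 3D spot scenes with planted ground truth.
#
# The generator emulates pseudo-super-resolution confocal fields of synaptic
# puncta: sub-micron Gaussian blobs on a 16-bit intensity scale, an
# anisotropic voxel grid, planted pairwise/triple colocalization with
# controllable jitter, microglia-like mask blobs with a planted engulfed
# fraction, flow-cytometry event tables and fractionation densitometry
# tables.  Every stochastic draw is governed by the spec seed, so equal
# specs give byte-identical scenes.

#' Specification of a synthetic 3D spot scene
#'
#' Defaults describe a desk-scale confocal field: 12.8 x 12.8 x 3 um
#' (256 x 256 x 20 voxels at 50 x 50 x 150 nm), three spot channels of 200
#' spots each, Gaussian blobs with sigma (80, 80, 200) nm (XY diameters well
#' under 1 um), peaks uniform in \[20000, 40000\] over a background of 1000
#' with read-noise SD 300 — intensities that put sensible segmentation
#' thresholds in the 5000--7000 range of the 16-bit scale.
#'
#' @param field_size_nm physical extents (x, y, z) in nm.
#' @param voxel_size_nm voxel edge lengths in nm; the field must divide into
#'   at least 8 voxels per axis.
#' @param channels character vector of channel names.
#' @param n_spots_per_channel integer: one count, or a named vector per
#'   channel.
#' @param spot_sigma_nm Gaussian blob sigmas (x, y, z) in nm.
#' @param peak_intensity_range range of per-spot peak intensities; must lie
#'   within \[0, 65535\] and above `background_level`.
#' @param background_level,noise_sd additive background and Gaussian read
#'   noise SD (intensity units).
#' @param coloc_plan list of entries `list(source=, target=, fraction=,
#'   jitter_sd_nm=)`: `round(fraction * n_source)` source spots get a partner
#'   spot in the target channel displaced by isotropic jitter truncated at
#'   3 x `jitter_sd_nm`.
#' @param triple_plan optional `list(syp=, a=, b=, frac_a_synaptic=,
#'   frac_triple=, jitter_sd_nm=)`: plants synaptic a-spots on syp positions
#'   and places b-partners on a `frac_triple` subset of those same synapses.
#' @param mask_plan optional `list(n_blobs=, blob_radius_nm=,
#'   engulfed_fraction=, channel=, np_fraction_inside=, np_fraction_outside=,
#'   intensity=)` describing microglia-like mask blobs and which fraction of
#'   the designated channel's centroids is placed inside them.
#' @param min_separation_sigma minimal same-channel spot separation, in
#'   blob-sigma units (anisotropically scaled); 0 disables the constraint.
#' @param seed integer master seed.
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(channels = c("a", "b"), n_spots_per_channel = 50, seed = 1)
#' sp$field_size_nm
#' @export
scene_spec <- function(field_size_nm = c(12800, 12800, 3000),
                       voxel_size_nm = c(50, 50, 150),
                       channels = c("c1q", "np1", "syp"),
                       n_spots_per_channel = 200,
                       spot_sigma_nm = c(80, 80, 200),
                       peak_intensity_range = c(20000, 40000),
                       background_level = 1000,
                       noise_sd = 300,
                       coloc_plan = list(),
                       triple_plan = NULL,
                       mask_plan = NULL,
                       min_separation_sigma = 0,
                       seed = 1L) {
    check_len3(field_size_nm, "field_size_nm")
    check_len3(voxel_size_nm, "voxel_size_nm")
    check_len3(spot_sigma_nm, "spot_sigma_nm")
    nvox <- round(field_size_nm / voxel_size_nm)
    if (any(abs(nvox * voxel_size_nm - field_size_nm) > 1e-6))
        stop("voxel sizes must divide the field extents exactly")
    if (any(nvox < 8)) stop("field must span at least 8 voxels per axis")
    channels <- as.character(channels)
    if (length(channels) < 1 || anyDuplicated(channels))
        stop("channels must be distinct names")
    if (is.null(names(n_spots_per_channel)))
        n_spots_per_channel <- setNames(rep(as.integer(n_spots_per_channel),
                                            length.out = length(channels)),
                                        channels)
    if (!all(channels %in% names(n_spots_per_channel)))
        stop("n_spots_per_channel must cover every channel")
    n_spots_per_channel <- n_spots_per_channel[channels]
    if (any(n_spots_per_channel < 0)) stop("spot counts must be >= 0")
    if (length(peak_intensity_range) != 2 ||
        any(peak_intensity_range < 0) || any(peak_intensity_range > 65535) ||
        peak_intensity_range[1] > peak_intensity_range[2])
        stop("peak_intensity_range must be an increasing pair within [0, 65535]")
    stopifnot_scalar_num(background_level, "background_level", 0, 65535)
    if (peak_intensity_range[2] <= background_level && peak_intensity_range[2] > 0)
        stop("peak intensities must exceed the background level")
    stopifnot_scalar_num(noise_sd, "noise_sd", 0)
    for (e in coloc_plan) {
        if (!all(c("source", "target", "fraction") %in% names(e)))
            stop("coloc_plan entries need source, target and fraction")
        if (!all(c(e$source, e$target) %in% channels))
            stop("coloc_plan refers to unknown channels")
        stopifnot_scalar_num(e$fraction, "coloc fraction", 0, 1)
        stopifnot_scalar_num(e$jitter_sd_nm %||% 0, "jitter_sd_nm", 0)
    }
    if (!is.null(triple_plan)) {
        tp <- triple_plan
        if (!all(c(tp$syp, tp$a, tp$b) %in% channels))
            stop("triple_plan refers to unknown channels")
        stopifnot_scalar_num(tp$frac_a_synaptic, "frac_a_synaptic", 0, 1)
        stopifnot_scalar_num(tp$frac_triple, "frac_triple", 0, 1)
        stopifnot_scalar_num(tp$jitter_sd_nm %||% 0, "jitter_sd_nm", 0)
    }
    if (!is.null(mask_plan)) {
        mp <- mask_plan
        stopifnot_scalar_num(mp$n_blobs, "n_blobs", 1)
        stopifnot_scalar_num(mp$blob_radius_nm, "blob_radius_nm", 1)
        if (is.null(mp$engulfed_fraction) || mp$engulfed_fraction < 0 ||
            mp$engulfed_fraction > 1)
            stop("engulfed_fraction must be in [0, 1]")
    }
    structure(
        list(field_size_nm = as.numeric(nvox * voxel_size_nm),
             voxel_size_nm = as.numeric(voxel_size_nm),
             n_voxels = as.integer(nvox),
             channels = channels,
             n_spots_per_channel = n_spots_per_channel,
             spot_sigma_nm = as.numeric(spot_sigma_nm),
             peak_intensity_range = as.numeric(peak_intensity_range),
             background_level = background_level,
             noise_sd = noise_sd,
             coloc_plan = coloc_plan,
             triple_plan = triple_plan,
             mask_plan = mask_plan,
             min_separation_sigma = min_separation_sigma,
             seed = as.integer(seed)),
        class = "scene_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Refuse specs whose expected blob density would merge most same-channel
# spots: under uniform placement the expected fraction of spots with a
# same-channel neighbour within one blob sigma is 1 - exp(-(n-1) v/V).
check_density <- function(spec) {
    V <- prod(spec$field_size_nm)
    v <- 4 / 3 * pi * prod(spec$spot_sigma_nm)
    for (ch in spec$channels) {
        n <- spec$n_spots_per_channel[[ch]]
        if (n > 1 && 1 - exp(-(n - 1) * v / V) > 0.5)
            stop(sprintf(
                "density error: channel '%s' (%d spots) would merge >50%% of spots",
                ch, n))
    }
    invisible(TRUE)
}

# Uniform points in the field with an optional minimal same-channel
# separation expressed in blob-sigma units (anisotropically scaled).
place_uniform <- function(n, spec, existing = NULL) {
    ext <- spec$field_size_nm
    if (n == 0) return(matrix(numeric(0), ncol = 3))
    if (spec$min_separation_sigma <= 0) {
        return(cbind(runif(n, 0, ext[1]), runif(n, 0, ext[2]),
                     runif(n, 0, ext[3])))
    }
    sig <- spec$spot_sigma_nm
    minsep2 <- spec$min_separation_sigma^2
    acc <- if (is.null(existing)) matrix(numeric(0), ncol = 3)
           else sweep(existing, 2, sig, "/")
    out <- matrix(NA_real_, n, 3)
    got <- 0L
    tries <- 0L
    while (got < n) {
        tries <- tries + 1L
        if (tries > 200L * n)
            stop("could not satisfy min_separation_sigma; field too dense")
        p <- c(runif(1, 0, ext[1]), runif(1, 0, ext[2]), runif(1, 0, ext[3]))
        ps <- p / sig
        if (nrow(acc) > 0) {
            d2 <- (acc[, 1] - ps[1])^2 + (acc[, 2] - ps[2])^2 +
                  (acc[, 3] - ps[3])^2
            if (min(d2) < minsep2) next
        }
        got <- got + 1L
        out[got, ] <- p
        acc <- rbind(acc, matrix(ps, 1))
    }
    out
}

# Isotropic physical-space jitter truncated at 3*sd so that every planted
# pair satisfies |pair distance| <= 3 * jitter_sd_nm.
draw_jitter <- function(n, sd) {
    if (n == 0 || sd == 0) return(matrix(0, n, 3))
    out <- matrix(rnorm(3 * n, 0, sd), n, 3)
    repeat {
        bad <- which(sqrt(rowSums(out^2)) > 3 * sd)
        if (length(bad) == 0) break
        out[bad, ] <- matrix(rnorm(3 * length(bad), 0, sd), length(bad), 3)
    }
    out
}

clamp_to_field <- function(p, ext) {
    for (ax in 1:3) p[, ax] <- pmin(pmax(p[, ax], 0), ext[ax])
    p
}

# Render one channel: truncated (3 sigma) Gaussian blobs + background +
# read noise, clipped to the 16-bit range.
render_channel <- function(points, peaks, spec, noiseless = FALSE) {
    nv <- spec$n_voxels
    vx <- spec$voxel_size_nm
    sig <- spec$spot_sigma_nm
    arr <- array(0, nv)
    if (nrow(points) > 0) {
        for (s in seq_len(nrow(points))) {
            ctr <- points[s, ]
            lo <- pmax(1L, floor((ctr - 3 * sig) / vx) + 1L)
            hi <- pmin(nv, ceiling((ctr + 3 * sig) / vx))
            if (any(lo > hi)) next
            ax <- lapply(1:3, function(k) {
                cc <- (seq(lo[k], hi[k]) - 0.5) * vx[k]
                (cc - ctr[k]) / sig[k]
            })
            d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
            blob <- peaks[s] * exp(-0.5 * d2)
            blob[d2 > 9] <- 0
            arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
                arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
        }
    }
    arr <- arr + spec$background_level
    if (!noiseless && spec$noise_sd > 0)
        arr <- arr + rnorm(length(arr), 0, spec$noise_sd)
    arr[arr < 0] <- 0
    arr[arr > 65535] <- 65535
    arr
}

#' Generate a multichannel 3D spot scene with known ground truth
#'
#' Places spots per channel (uniform, pairwise-colocalized per `coloc_plan`,
#' and/or triple-colocalized per `triple_plan`), records the planted
#' centroids and links, and renders each channel as Gaussian blobs plus
#' background and read noise.  Identical specs (including the seed) give
#' byte-identical output.
#'
#' @param spec a [scene_spec()].
#' @param render if `FALSE`, skip image rendering and return ground truth
#'   (and truth-derived spot sets) only — useful for centroid-level studies.
#' @return A list of class `spot_scene` with elements `grids` (named list of
#'   [voxel_grid()] or `NULL`), `truth` (ground truth: per-channel centroid
#'   matrices, link tables, per-spot peaks) and `spots` (named list of
#'   [spot_set()] built from the planted centroids).
#' @examples
#' sp <- scene_spec(channels = c("a", "b"), n_spots_per_channel = 20,
#'                  coloc_plan = list(list(source = "a", target = "b",
#'                                         fraction = 0.5, jitter_sd_nm = 0)),
#'                  seed = 7)
#' sc <- make_spot_scene(sp, render = FALSE)
#' nrow(sc$truth$links)
#' @export
make_spot_scene <- function(spec, render = TRUE) {
    stopifnot(inherits(spec, "scene_spec"))
    check_density(spec)
    with_seed(spec$seed, {
        ext <- spec$field_size_nm
        pts <- list()
        links <- data.frame(link_id = integer(), source_channel = character(),
                            source_index = integer(),
                            target_channel = character(),
                            target_index = integer())
        triple_links <- NULL
        next_link <- 1L

        tp <- spec$triple_plan
        if (!is.null(tp)) {
            n_syp <- spec$n_spots_per_channel[[tp$syp]]
            n_a <- spec$n_spots_per_channel[[tp$a]]
            n_b <- spec$n_spots_per_channel[[tp$b]]
            jit <- tp$jitter_sd_nm %||% 0
            syp_pos <- place_uniform(n_syp, spec)
            pts[[tp$syp]] <- syp_pos
            n_a_syn <- round(tp$frac_a_synaptic * n_a)
            if (n_a_syn > n_syp)
                stop("triple_plan: more synaptic a-spots than syp spots")
            sa <- sample(n_syp, n_a_syn)
            a_syn <- clamp_to_field(syp_pos[sa, , drop = FALSE] +
                                    draw_jitter(n_a_syn, jit), ext)
            a_rest <- place_uniform(n_a - n_a_syn, spec, existing = a_syn)
            pts[[tp$a]] <- rbind(a_syn, a_rest)
            n_triple <- round(tp$frac_triple * n_a_syn)
            tb <- if (n_triple > 0) sample(n_a_syn, n_triple) else integer(0)
            b_tri <- clamp_to_field(syp_pos[sa[tb], , drop = FALSE] +
                                    draw_jitter(n_triple, jit), ext)
            if (n_b < n_triple)
                stop("triple_plan: b channel too small for planted triples")
            b_rest <- place_uniform(n_b - n_triple, spec, existing = b_tri)
            pts[[tp$b]] <- rbind(b_tri, b_rest)
            triple_links <- data.frame(
                link_id = seq_len(n_a_syn),
                syp_index = sa,
                a_index = seq_len(n_a_syn),
                b_index = NA_integer_)
            if (n_triple > 0)
                triple_links$b_index[tb] <- seq_len(n_triple)
            next_link <- n_a_syn + 1L
        }

        targets <- vapply(spec$coloc_plan, function(e) e$target, "")
        if (anyDuplicated(targets) ||
            any(targets %in% names(pts)))
            stop("each channel may be the target of at most one plan")
        for (e in spec$coloc_plan) {
            if (is.null(pts[[e$source]]))
                pts[[e$source]] <- place_uniform(
                    spec$n_spots_per_channel[[e$source]], spec)
        }
        for (ch in spec$channels)
            if (is.null(pts[[ch]]) && !(ch %in% targets))
                pts[[ch]] <- place_uniform(spec$n_spots_per_channel[[ch]], spec)
        for (e in spec$coloc_plan) {
            n_src <- nrow(pts[[e$source]])
            n_tgt <- spec$n_spots_per_channel[[e$target]]
            jit <- e$jitter_sd_nm %||% 0
            n_links <- round(e$fraction * n_src)
            if (n_links > n_tgt)
                stop("coloc_plan: target channel smaller than planted links")
            src_idx <- if (n_links > 0) sample(n_src, n_links) else integer(0)
            partners <- clamp_to_field(
                pts[[e$source]][src_idx, , drop = FALSE] +
                draw_jitter(n_links, jit), ext)
            rest <- place_uniform(n_tgt - n_links, spec, existing = partners)
            pts[[e$target]] <- rbind(partners, rest)
            if (n_links > 0) {
                links <- rbind(links, data.frame(
                    link_id = seq(next_link, length.out = n_links),
                    source_channel = e$source, source_index = src_idx,
                    target_channel = e$target,
                    target_index = seq_len(n_links)))
                next_link <- next_link + n_links
            }
        }

        peaks <- lapply(spec$channels, function(ch)
            runif(nrow(pts[[ch]]), spec$peak_intensity_range[1],
                  spec$peak_intensity_range[2]))
        names(peaks) <- spec$channels

        grids <- NULL
        if (render) {
            grids <- lapply(spec$channels, function(ch)
                voxel_grid(render_channel(pts[[ch]], peaks[[ch]], spec),
                           spec$voxel_size_nm, ch))
            names(grids) <- spec$channels
        }
        spots <- lapply(spec$channels, function(ch)
            spot_set(pts[[ch]], peaks[[ch]], source_channel = ch,
                     field_size_nm = ext))
        names(spots) <- spec$channels
        truth <- structure(
            list(centroids = pts[spec$channels], peaks = peaks,
                 links = links, triple_links = triple_links,
                 in_mask = NULL, spec = spec),
            class = "ground_truth")
        structure(list(grids = grids, truth = truth, spots = spots,
                       spec = spec),
                  class = "spot_scene")
    })
}

#' Generate a microglia-like mask scene with planted engulfment
#'
#' Renders solid high-intensity blobs (the mask channel) and places a known
#' fraction of a designated channel's centroids inside them, at least one
#' voxel away from blob boundaries so membership is unambiguous.  Optional
#' `np_fraction_inside` / `np_fraction_outside` plant a per-spot marker flag
#' (e.g. NP colocalization) at given rates inside and outside the mask.
#'
#' @param spec a [scene_spec()] whose `mask_plan` is set.
#' @param render if `FALSE`, skip rendering the mask grid.
#' @return A list of class `mask_scene`: `grid` (the mask channel),
#'   `spots` (a [spot_set()] of the designated channel), `in_mask` (logical,
#'   planted membership), `np_flag` (logical or `NULL`), `blob_centers_nm`,
#'   `blob_radius_nm`.
#' @examples
#' sp <- scene_spec(channels = "syp", n_spots_per_channel = 40,
#'                  mask_plan = list(n_blobs = 4, blob_radius_nm = 1200,
#'                                   engulfed_fraction = 0.5), seed = 2)
#' ms <- make_mask_scene(sp, render = FALSE)
#' mean(ms$in_mask)
#' @export
make_mask_scene <- function(spec, render = TRUE) {
    stopifnot(inherits(spec, "scene_spec"))
    mp <- spec$mask_plan
    if (is.null(mp)) stop("spec$mask_plan is required")
    ch <- mp$channel %||% spec$channels[1]
    n <- spec$n_spots_per_channel[[ch]]
    r <- mp$blob_radius_nm
    ext <- spec$field_size_nm
    if (any(2 * r > ext)) stop("blob radius too large for the field")
    margin <- sqrt(sum(spec$voxel_size_nm^2))  # one voxel diagonal
    with_seed(spec$seed, {
        nb <- as.integer(mp$n_blobs)
        centers <- cbind(runif(nb, r, ext[1] - r), runif(nb, r, ext[2] - r),
                         runif(nb, r, ext[3] - r))
        n_in <- round(mp$engulfed_fraction * n)
        inside <- matrix(numeric(0), ncol = 3)
        if (n_in > 0) {
            b <- sample(nb, n_in, replace = TRUE)
            # uniform in a sphere of radius (r - margin) around each blob center
            u <- matrix(rnorm(3 * n_in), n_in, 3)
            u <- u / sqrt(rowSums(u^2))
            rad <- (r - margin) * runif(n_in)^(1 / 3)
            inside <- centers[b, , drop = FALSE] + u * rad
        }
        n_out <- n - n_in
        outside <- matrix(NA_real_, n_out, 3)
        got <- 0L; tries <- 0L
        while (got < n_out) {
            tries <- tries + 1L
            if (tries > 500L * max(n_out, 1L))
                stop("mask blobs fill too much of the field to place outside spots")
            p <- c(runif(1, 0, ext[1]), runif(1, 0, ext[2]), runif(1, 0, ext[3]))
            d <- sqrt(colSums((t(centers) - p)^2))
            if (min(d) <= r + margin) next
            got <- got + 1L
            outside[got, ] <- p
        }
        pts <- rbind(inside, outside)
        in_mask <- c(rep(TRUE, n_in), rep(FALSE, n_out))
        np_flag <- NULL
        if (!is.null(mp$np_fraction_inside) || !is.null(mp$np_fraction_outside)) {
            np_flag <- rep(FALSE, n)
            fi <- mp$np_fraction_inside %||% 0
            fo <- mp$np_fraction_outside %||% 0
            if (n_in > 0)
                np_flag[sample(which(in_mask), round(fi * n_in))] <- TRUE
            if (n_out > 0)
                np_flag[sample(which(!in_mask), round(fo * n_out))] <- TRUE
        }
        grid <- NULL
        if (render) {
            nv <- spec$n_voxels; vx <- spec$voxel_size_nm
            arr <- array(0, nv)
            intensity <- mp$intensity %||% 30000
            for (b in seq_len(nb)) {
                ctr <- centers[b, ]
                lo <- pmax(1L, floor((ctr - r) / vx) + 1L)
                hi <- pmin(nv, ceiling((ctr + r) / vx))
                ax <- lapply(1:3, function(k)
                    ((seq(lo[k], hi[k]) - 0.5) * vx[k] - ctr[k])^2)
                d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
                sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
                sub[d2 <= r^2] <- intensity
                arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
            }
            arr <- arr + spec$background_level
            if (spec$noise_sd > 0)
                arr <- arr + rnorm(length(arr), 0, spec$noise_sd)
            arr[arr < 0] <- 0; arr[arr > 65535] <- 65535
            grid <- voxel_grid(arr, vx, "mask")
        }
        structure(
            list(grid = grid,
                 spots = spot_set(pts, source_channel = ch,
                                  field_size_nm = ext),
                 in_mask = in_mask, np_flag = np_flag,
                 blob_centers_nm = centers, blob_radius_nm = r, spec = spec),
            class = "mask_scene")
    })
}

#' Generate a synthetic flow-cytometry event table
#'
#' Each event carries two fluorescence intensities.  Positive populations
#' are drawn from a high-mean log-normal, negatives from a low-mean
#' log-normal; planted population counts follow the requested fractions
#' after round-half-to-even rounding.
#'
#' @param n_events number of events.
#' @param frac_a_pos,frac_b_pos,frac_double planted positive fractions;
#'   `frac_double` must not exceed either single-positive fraction.
#' @param channel_noise list with `meanlog_neg`, `meanlog_pos`, `sdlog`.
#' @param seed integer seed.
#' @return A data.frame with columns `event_id`, `intensity_a`,
#'   `intensity_b`, `true_label` (one of `"neg"`, `"a_only"`, `"b_only"`,
#'   `"double"`), in randomized event order.
#' @examples
#' ev <- make_flow_events(1000, 0.1, 0.4, 0.1, seed = 3)
#' table(ev$true_label)
#' @export
make_flow_events <- function(n_events, frac_a_pos, frac_b_pos, frac_double,
                             channel_noise = list(meanlog_neg = log(100),
                                                  meanlog_pos = log(5000),
                                                  sdlog = 0.4),
                             seed = 1L) {
    stopifnot_scalar_num(n_events, "n_events", 1)
    for (f in c(frac_a_pos, frac_b_pos, frac_double))
        stopifnot_scalar_num(f, "fraction", 0, 1)
    if (frac_double > min(frac_a_pos, frac_b_pos) + 1e-12)
        stop("frac_double cannot exceed either single-positive fraction")
    n <- as.integer(n_events)
    n_ab <- round(frac_double * n)
    n_a <- round(frac_a_pos * n)
    n_b <- round(frac_b_pos * n)
    if (n_ab > min(n_a, n_b)) stop("inconsistent planted fractions after rounding")
    n_a_only <- n_a - n_ab
    n_b_only <- n_b - n_ab
    n_neg <- n - n_ab - n_a_only - n_b_only
    if (n_neg < 0) stop("planted fractions exceed the event count")
    lab <- c(rep("double", n_ab), rep("a_only", n_a_only),
             rep("b_only", n_b_only), rep("neg", n_neg))
    cn <- channel_noise
    with_seed(seed, {
        lab <- lab[sample.int(n)]
        a_pos <- lab %in% c("double", "a_only")
        b_pos <- lab %in% c("double", "b_only")
        ia <- rlnorm(n, ifelse(a_pos, cn$meanlog_pos, cn$meanlog_neg), cn$sdlog)
        ib <- rlnorm(n, ifelse(b_pos, cn$meanlog_pos, cn$meanlog_neg), cn$sdlog)
        data.frame(event_id = seq_len(n), intensity_a = ia, intensity_b = ib,
                   true_label = lab)
    })
}

#' Generate synthetic fractionation densitometry tables
#'
#' Emulates western-blot densitometry of three sub-synaptic preparations
#' (SPM, cytoplasm, mitochondria).  The observed signal of a protein in
#' fraction i is `sum_k mixing[i, k] * true_levels[k]`, multiplied by
#' log-normal noise of the stated coefficient of variation; marker rows are
#' generated the same way from compartment-pure levels (Psd95 -> SPM,
#' Ldhb -> cytoplasm, Cox4 -> mitochondria).
#'
#' @param true_levels named list of numeric 3-vectors (per-compartment levels
#'   for each protein of interest), or a single 3-vector.
#' @param mixing 3x3 non-negative matrix; rows = measured fractions,
#'   columns = compartments (SPM, cytoplasm, mitochondria).
#' @param noise_cv multiplicative log-normal noise CV (0 = noiseless).
#' @param n_replicates number of replicates (e.g. mice).
#' @param marker_levels pure marker levels, one per marker.
#' @param seed integer seed.
#' @return A data.frame with columns `fraction`, `marker_or_protein`,
#'   `replicate`, `signal`, `is_marker`.
#' @examples
#' M <- diag(3)
#' tb <- make_fraction_tables(list(np1 = c(10, 2, 1)), M, 0, 1, seed = 1)
#' subset(tb, marker_or_protein == "np1")$signal
#' @export
make_fraction_tables <- function(true_levels, mixing, noise_cv = 0.1,
                                 n_replicates = 4,
                                 marker_levels = c(Psd95 = 10, Ldhb = 10,
                                                   Cox4 = 10),
                                 seed = 1L) {
    if (is.numeric(true_levels)) true_levels <- list(protein = true_levels)
    for (tl in true_levels) {
        check_len3(tl, "true_levels", positive = FALSE)
        if (any(tl < 0)) stop("protein levels must be non-negative")
    }
    mixing <- as.matrix(mixing)
    if (!all(dim(mixing) == c(3, 3)) || any(mixing < 0))
        stop("mixing must be a non-negative 3x3 matrix")
    stopifnot_scalar_num(noise_cv, "noise_cv", 0)
    fracs <- c("SPM", "cytoplasm", "mitochondria")
    markers <- names(marker_levels)
    sdlog <- sqrt(log(1 + noise_cv^2))
    meanlog <- -sdlog^2 / 2  # unit-mean noise
    with_seed(seed, {
        rows <- list()
        for (rep_i in seq_len(n_replicates)) {
            for (m in seq_along(markers)) {
                pure <- numeric(3); pure[m] <- marker_levels[[m]]
                obs <- as.numeric(mixing %*% pure)
                if (noise_cv > 0) obs <- obs * rlnorm(3, meanlog, sdlog)
                rows[[length(rows) + 1L]] <- data.frame(
                    fraction = fracs, marker_or_protein = markers[m],
                    replicate = rep_i, signal = obs, is_marker = TRUE)
            }
            for (p in names(true_levels)) {
                obs <- as.numeric(mixing %*% true_levels[[p]])
                if (noise_cv > 0) obs <- obs * rlnorm(3, meanlog, sdlog)
                rows[[length(rows) + 1L]] <- data.frame(
                    fraction = fracs, marker_or_protein = p,
                    replicate = rep_i, signal = obs, is_marker = FALSE)
            }
        }
        do.call(rbind, rows)
    })
}
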