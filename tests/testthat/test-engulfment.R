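# Mask reconstruction and engulfed-spot counting.

test_that("threshold extremes give all-true / all-false masks", {
    sp <- scene_spec(channels = "syp", n_spots_per_channel = 20,
                     field_size_nm = c(1600, 1600, 1800),
                     voxel_size_nm = c(100, 100, 150),
                     mask_plan = list(n_blobs = 2, blob_radius_nm = 400,
                                      engulfed_fraction = 0.5),
                     seed = 61)
    ms <- make_mask_scene(sp)
    expect_true(all(segment_mask(ms$grid, 0)$mask))
    expect_false(any(segment_mask(ms$grid,
                                  max(ms$grid$intensities) + 1)$mask))
})

test_that("cavity filling closes fully enclosed holes only", {
    arr <- array(100, c(12, 12, 12))
    arr[3:10, 3:10, 3:10] <- 30000
    arr[6:7, 6:7, 6:7] <- 100      # enclosed cavity
    arr[1:2, 6, 6] <- 100          # border-connected background stays
    g <- voxel_grid(arr, c(50, 50, 150), "iba1")
    filled <- segment_mask(g, 15000, fill_cavities = TRUE)
    expect_true(all(filled$mask[6:7, 6:7, 6:7]))
    unfilled <- segment_mask(g, 15000, fill_cavities = FALSE)
    expect_false(any(unfilled$mask[6:7, 6:7, 6:7]))
    expect_false(any(filled$mask[1, , ]))
})

test_that("mask segmentation recovers generator blobs (Jaccard >= 0.95)", {
    sp <- scene_spec(channels = "syp", n_spots_per_channel = 50,
                     mask_plan = list(n_blobs = 5, blob_radius_nm = 1200,
                                      engulfed_fraction = 0.5),
                     seed = 62)
    ms <- make_mask_scene(sp)
    mask <- segment_mask(ms$grid, 15000)
    nv <- sp$n_voxels; vx <- sp$voxel_size_nm
    xs <- (1:nv[1] - 0.5) * vx[1]; ys <- (1:nv[2] - 0.5) * vx[2]
    zs <- (1:nv[3] - 0.5) * vx[3]
    truthvox <- array(FALSE, nv)
    for (b in seq_len(nrow(ms$blob_centers_nm))) {
        d2 <- outer(outer((xs - ms$blob_centers_nm[b, 1])^2,
                          (ys - ms$blob_centers_nm[b, 2])^2, "+"),
                    (zs - ms$blob_centers_nm[b, 3])^2, "+")
        truthvox <- truthvox | (d2 <= ms$blob_radius_nm^2)
    }
    jac <- sum(mask$mask & truthvox) / sum(mask$mask | truthvox)
    expect_gte(jac, 0.95)
})

test_that("planted membership is reproduced exactly away from boundaries", {
    sp <- scene_spec(channels = "syp", n_spots_per_channel = 200,
                     mask_plan = list(n_blobs = 5, blob_radius_nm = 1200,
                                      engulfed_fraction = 0.4),
                     seed = 63)
    ms <- make_mask_scene(sp)
    mask <- segment_mask(ms$grid, 15000)
    expect_identical(unname(spots_in_mask(ms$spots, mask)), ms$in_mask)
})

test_that("engulfment counting and its degenerate cases are correct", {
    sp <- scene_spec(channels = "syp", n_spots_per_channel = 100,
                     mask_plan = list(n_blobs = 4, blob_radius_nm = 1200,
                                      engulfed_fraction = 0.65,
                                      np_fraction_inside = 0.65,
                                      np_fraction_outside = 0.3),
                     seed = 64)
    ms <- make_mask_scene(sp)
    mask <- segment_mask(ms$grid, 15000)
    res <- count_engulfed(ms$spots, mask, ms$np_flag)
    expect_identical(res$n_tagged_inside, as.integer(round(0.65 * 100)))
    expect_identical(res$n_tagged_inside_with_NP,
                     as.integer(round(0.65 * round(0.65 * 100))))
    # empty mask -> undefined fraction
    none <- segment_mask(ms$grid, max(ms$grid$intensities) + 1)
    res0 <- count_engulfed(ms$spots, none, ms$np_flag)
    expect_identical(res0$n_tagged_inside, 0L)
    expect_true(is.na(res0$fraction_NP_positive))
    # all inside and all NP-positive -> fraction 1
    all_in <- ms$spots[ms$in_mask]
    res1 <- count_engulfed(all_in, mask, rep(TRUE, n_spots(all_in)))
    expect_equal(res1$fraction_NP_positive, 1)
})

test_that("raising the mask threshold never increases the inside count", {
    sp <- scene_spec(channels = "syp", n_spots_per_channel = 150,
                     mask_plan = list(n_blobs = 4, blob_radius_nm = 1200,
                                      engulfed_fraction = 0.5,
                                      np_fraction_inside = 0.5),
                     seed = 65)
    ms <- make_mask_scene(sp)
    sweep_df <- engulfment_threshold_sweep(
        ms$grid, ms$spots, ms$np_flag,
        thresholds = c(500, 5000, 15000, 29000, 40000))
    expect_true(all(diff(sweep_df$n_tagged_inside) <= 0))
})

test_that("the whole-ellipsoid containment mode is stricter than centroid mode", {
    arr <- array(100, c(20, 20, 10))
    arr[6:15, 6:15, 4:7] <- 30000
    g <- voxel_grid(arr, c(100, 100, 200), "iba1")
    mask <- segment_mask(g, 15000)
    # deep inside the block, at the block's edge voxel, and outside
    S <- spot_set(rbind(c(1050, 1050, 1100),
                        c(550, 1050, 1100),
                        c(250, 250, 300)),
                  source_channel = "syp", field_size_nm = c(2000, 2000, 2000))
    cen <- spots_in_mask(S, mask, "centroid")
    ell <- spots_in_mask(S, mask, "ellipsoid")
    expect_identical(cen, c(TRUE, TRUE, FALSE))
    expect_identical(ell, c(TRUE, FALSE, FALSE))
    expect_true(all(which(ell) %in% which(cen)))
})
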