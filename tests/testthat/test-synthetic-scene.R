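# The scene generator: determinism, conservation, planted structure.

test_that("spec validation rejects impossible scenes", {
    expect_error(scene_spec(field_size_nm = c(300, 12800, 3000)),
                 "8 voxels")
    expect_error(scene_spec(voxel_size_nm = c(47, 50, 150)), "divide")
    expect_error(scene_spec(peak_intensity_range = c(500, 900),
                            background_level = 1000), "background")
    expect_error(scene_spec(coloc_plan = list(list(source = "c1q",
                                                   target = "np1",
                                                   fraction = 1.5))),
                 "fraction")
    # blob density so high that most same-channel spots would merge
    dense <- scene_spec(channels = "a", n_spots_per_channel = 60000,
                        field_size_nm = c(3200, 3200, 1200),
                        voxel_size_nm = c(50, 50, 150))
    expect_error(make_spot_scene(dense, render = FALSE), "density")
})

test_that("equal specs give byte-identical scenes and unequal seeds differ", {
    sp <- scene_spec(channels = c("a", "b"), n_spots_per_channel = 40,
                     coloc_plan = list(list(source = "a", target = "b",
                                            fraction = 0.5,
                                            jitter_sd_nm = 30)),
                     seed = 11)
    s1 <- make_spot_scene(sp)
    s2 <- make_spot_scene(sp)
    expect_identical(s1$grids$a$intensities, s2$grids$a$intensities)
    expect_identical(s1$truth$centroids, s2$truth$centroids)
    sp2 <- sp; sp2$seed <- 12L
    s3 <- make_spot_scene(sp2, render = FALSE)
    expect_false(isTRUE(all.equal(s1$truth$centroids$a,
                                  s3$truth$centroids$a)))
})

test_that("planted counts and links are conserved", {
    sp <- scene_spec(channels = c("a", "b"), n_spots_per_channel = 200,
                     coloc_plan = list(list(source = "a", target = "b",
                                            fraction = 0.5,
                                            jitter_sd_nm = 0)),
                     seed = 7)
    sc <- make_spot_scene(sp, render = FALSE)
    expect_identical(vapply(sc$truth$centroids, nrow, integer(1)),
                     c(a = 200L, b = 200L))
    expect_identical(nrow(sc$truth$links), 100L)
    # recomputed planted fraction equals request to within 1/n
    expect_lt(abs(nrow(sc$truth$links) / 200 - 0.5), 1 / 200 + 1e-12)
    # jitter 0: linked pairs coincide exactly
    d <- sqrt(rowSums((sc$truth$centroids$a[sc$truth$links$source_index, ] -
                       sc$truth$centroids$b[sc$truth$links$target_index, ])^2))
    expect_equal(max(d), 0)
})

test_that("jittered links respect the 3-sigma distance bound", {
    sp <- scene_spec(channels = c("a", "b"), n_spots_per_channel = 150,
                     coloc_plan = list(list(source = "a", target = "b",
                                            fraction = 0.8,
                                            jitter_sd_nm = 60)),
                     seed = 3)
    sc <- make_spot_scene(sp, render = FALSE)
    d <- sqrt(rowSums((sc$truth$centroids$a[sc$truth$links$source_index, ] -
                       sc$truth$centroids$b[sc$truth$links$target_index, ])^2))
    expect_lte(max(d), 3 * 60 + 1e-9)
    expect_gt(max(d), 0)
})

test_that("a rendered noiseless blob peaks at its planted centroid", {
    sp <- scene_spec(channels = "a", n_spots_per_channel = 1,
                     background_level = 0, noise_sd = 0, seed = 4)
    sc <- make_spot_scene(sp)
    img <- sc$grids$a$intensities
    peak_vox <- arrayInd(which.max(img), dim(img))
    truth_vox <- floor(sc$truth$centroids$a[1, ] / sp$voxel_size_nm) + 1
    expect_identical(as.integer(peak_vox), as.integer(truth_vox))
    # centroid of mass within half a voxel of the planted coordinate
    idx <- which(img > 0)
    co <- arrayInd(idx, dim(img))
    w <- img[idx]
    com <- colSums(sweep(co - 0.5, 2, sp$voxel_size_nm, "*") * w) / sum(w)
    expect_true(all(abs(com - sc$truth$centroids$a[1, ]) <
                    sp$voxel_size_nm / 2))
})

test_that("flow event generator plants exact label counts, deterministically", {
    ev <- make_flow_events(10000, 0.1085, 0.4238, 0.1049, seed = 21)
    tab <- table(ev$true_label)
    expect_identical(unname(tab[["double"]]), 1049L)
    expect_identical(unname(tab[["double"]]) + unname(tab[["a_only"]]), 1085L)
    expect_identical(unname(tab[["double"]]) + unname(tab[["b_only"]]), 4238L)
    expect_identical(make_flow_events(500, 0.1, 0.2, 0.05, seed = 8),
                     make_flow_events(500, 0.1, 0.2, 0.05, seed = 8))
    ev0 <- make_flow_events(200, 0, 0, 0, seed = 1)
    expect_true(all(ev0$true_label == "neg"))
    expect_error(make_flow_events(100, 0.1, 0.2, 0.3, seed = 1),
                 "frac_double")
})

test_that("fraction tables reproduce the forward mixing model", {
    M <- rbind(c(.8, .15, .05), c(.1, .8, .1), c(.1, .05, .85))
    tb <- make_fraction_tables(list(p = c(10, 2, 1)), M, noise_cv = 0,
                               n_replicates = 1, seed = 1)
    obs <- tb$signal[tb$marker_or_protein == "p"]
    expect_equal(obs, c(8.35, 2.7, 1.95))
    tb0 <- make_fraction_tables(list(p = c(0, 0, 0)), M, noise_cv = 0,
                                n_replicates = 1, seed = 1)
    expect_true(all(tb0$signal[tb0$marker_or_protein == "p"] == 0))
    tbI <- make_fraction_tables(list(p = c(4, 5, 6)), diag(3), noise_cv = 0,
                                n_replicates = 1, seed = 1)
    expect_equal(tbI$signal[tbI$marker_or_protein == "p"], c(4, 5, 6))
    expect_error(make_fraction_tables(list(p = c(-1, 0, 0)), M, 0, 1),
                 "non-negative")
})

test_that("mask scenes plant the requested engulfed fraction", {
    for (ef in c(0, 1, 0.6489)) {
        sp <- scene_spec(channels = "syp", n_spots_per_channel = 50,
                         mask_plan = list(n_blobs = 4, blob_radius_nm = 1000,
                                          engulfed_fraction = ef),
                         seed = 6)
        ms <- make_mask_scene(sp, render = FALSE)
        expect_identical(sum(ms$in_mask), as.integer(round(ef * 50)))
        # membership agrees with a direct point-in-blob check
        d <- apply(ms$spots$centroids, 1, function(p)
            min(sqrt(colSums((t(ms$blob_centers_nm) - p)^2))))
        expect_identical(unname(d <= ms$blob_radius_nm), ms$in_mask)
    }
    expect_error(scene_spec(channels = "syp",
                            mask_plan = list(n_blobs = 2,
                                             blob_radius_nm = 1000,
                                             engulfed_fraction = 1.2)),
                 "engulfed_fraction")
})
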