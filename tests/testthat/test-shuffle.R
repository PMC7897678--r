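# Shuffle null model: CFDs, conservation, envelope behaviour, signed-rank
# comparison.

test_that("minimal-distance CFDs match the brute-force double loop", {
    A <- random_spot_set(50, channel = "a", seed = 41)
    B <- random_spot_set(50, channel = "b", seed = 42)
    cfd <- min_distance_cfd(A, B)
    oracle <- sort(brute_nn_dist(A$centroids, B$centroids))
    expect_equal(cfd$distances, oracle)
    expect_equal(cfd$cumfreq, seq_len(50) / 50)
    expect_identical(cfd$n_reference, 50L)
    # A = B -> all distances zero
    expect_true(all(min_distance_cfd(A, A)$distances == 0))
    # single pair
    one <- spot_set(matrix(c(0, 0, 0), 1), source_channel = "a",
                    field_size_nm = c(1000, 1000, 1000))
    other <- spot_set(matrix(c(300, 0, 0), 1), source_channel = "b",
                      field_size_nm = c(1000, 1000, 1000))
    expect_equal(min_distance_cfd(one, other)$distances, 300)
    expect_error(min_distance_cfd(A, A[integer(0)]), "empty")
})

test_that("shuffling preserves counts and field extents, differs by seed", {
    S <- random_spot_set(80, channel = "a", seed = 43)
    sh1 <- shuffle_centroids(S, seed = 1)
    sh2 <- shuffle_centroids(S, seed = 2)
    expect_identical(n_spots(sh1), 80L)
    expect_identical(sh1$field_size_nm, S$field_size_nm)
    expect_false(isTRUE(all.equal(sh1$centroids, sh2$centroids)))
    expect_identical(shuffle_centroids(S, seed = 1)$centroids, sh1$centroids)
    for (ax in 1:3) {
        expect_gte(min(sh1$centroids[, ax]), 0)
        expect_lte(max(sh1$centroids[, ax]), S$field_size_nm[ax])
    }
})

test_that("mean nearest-neighbour distance of shuffles approaches the Poisson form", {
    # E[NN] = 0.55396 (V/n)^(1/3) for a spatial Poisson process; a cubic
    # field and moderate density keep edge-effect bias within a few percent
    field <- c(10000, 10000, 10000)
    n <- 1000
    S <- random_spot_set(n, field, "b", seed = 44)
    A <- random_spot_set(400, field, "a", seed = 45)
    set.seed(46)
    d <- unlist(lapply(1:30, function(i)
        min_distance_cfd(A, shuffle_centroids(S))$distances))
    expected <- 0.55396 * (prod(field) / n)^(1 / 3)
    expect_lt(abs(mean(d) - expected) / expected, 0.10)
})

test_that("the envelope is deterministic under a fixed seed and well-formed", {
    A <- random_spot_set(60, channel = "a", seed = 47)
    B <- random_spot_set(60, channel = "b", seed = 48)
    e1 <- shuffle_envelope(A, B, n_iterations = 25, seed = 5)
    e2 <- shuffle_envelope(A, B, n_iterations = 25, seed = 5)
    expect_identical(e1$mean_null_cfd, e2$mean_null_cfd)
    expect_identical(e1$ci_low, e2$ci_low)
    expect_identical(e1$per_iteration_medians, e2$per_iteration_medians)
    expect_true(all(e1$ci_low <= e1$mean_null_cfd + 1e-12))
    expect_true(all(e1$mean_null_cfd <= e1$ci_high + 1e-12))
    expect_length(e1$grid, 64)
    expect_error(shuffle_envelope(A, B, n_iterations = 1), "n_iterations")
})

test_that("a uniform channel stays inside the envelope; attraction escapes it", {
    # uniform B: observed CFD within the envelope at >= 90% of grid points
    A <- random_spot_set(100, channel = "a", seed = 49)
    B <- random_spot_set(100, channel = "b", seed = 50)
    env <- shuffle_envelope(A, B, n_iterations = 100, seed = 6)
    inside <- mean(env$observed_cfd >= env$ci_low - 1e-12 &
                   env$observed_cfd <= env$ci_high + 1e-12)
    expect_gte(inside, 0.90)
    # planted attraction at fraction 0.5, jitter 50 nm: observed CFD above
    # the upper envelope at every grid distance below 200 nm
    sp <- scene_spec(channels = c("a", "b"), n_spots_per_channel = 200,
                     coloc_plan = list(list(source = "a", target = "b",
                                            fraction = 0.5,
                                            jitter_sd_nm = 50)),
                     seed = 51)
    sc <- make_spot_scene(sp, render = FALSE)
    env2 <- shuffle_envelope(sc$spots$a, sc$spots$b, n_iterations = 100,
                             seed = 7)
    low <- env2$grid > 0 & env2$grid < 200
    expect_true(all(env2$observed_cfd[low] > env2$ci_high[low]))
})

test_that("the signed-rank comparison behaves at its contract edges", {
    expect_error(compare_observed_vs_null(1:3, 1:3), "6")
    res <- compare_observed_vs_null(rep(1, 8), rep(1, 8))
    expect_true(res$degenerate)
    expect_equal(res$p_value, 1)
    obs <- c(100, 120, 90, 110, 95, 105, 115, 85)
    null <- obs + 200  # strong separation
    res2 <- compare_observed_vs_null(obs, null)
    expect_false(res2$degenerate)
    expect_lt(res2$p_value, 0.05)
    expect_equal(res2$median_difference, -200)
})

test_that("masked shuffling confines points to the mask volume", {
    arr <- array(100, c(16, 16, 10))
    arr[4:12, 4:12, 3:8] <- 30000
    g <- voxel_grid(arr, c(100, 100, 200), "iba1")
    mask <- segment_mask(g, 15000)
    S <- random_spot_set(60, field = c(1600, 1600, 2000), seed = 52)
    sh <- shuffle_centroids(S, seed = 3, mask = mask)
    expect_identical(n_spots(sh), 60L)
    expect_true(all(spots_in_mask(sh, mask)))
    empty <- segment_mask(g, 65535)
    expect_error(shuffle_centroids(S, seed = 3, mask = empty), "empty")
})
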