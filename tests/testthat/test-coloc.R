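# Ellipsoid-overlap colocalization: predicate geometry, accelerated vs
# brute-force equivalence, planted-fraction recovery, synaptic filtering.

test_that("the overlap predicate handles identity, tangency and separation", {
    spec <- ellipsoid_spec()  # 200/500 nm full-axis -> semi-axes 100/250
    expect_true(ellipsoids_overlap(c(0, 0, 0), c(0, 0, 0), spec))
    expect_true(ellipsoids_overlap(c(0, 0, 0), c(200, 0, 0), spec))   # tangent
    expect_true(ellipsoids_overlap(c(0, 0, 0), c(0, 0, 500), spec))   # tangent
    eps <- 1e-6
    expect_false(ellipsoids_overlap(c(0, 0, 0), c(200 + eps, 0, 0), spec))
    expect_false(ellipsoids_overlap(c(0, 0, 0), c(0, 0, 500 + eps), spec))
    expect_false(ellipsoids_overlap(c(0, 0, 0), c(0, 0, 600), spec))
    # symmetry
    set.seed(1)
    for (i in 1:20) {
        p <- runif(3, 0, 400); q <- runif(3, 0, 400)
        expect_identical(ellipsoids_overlap(p, q, spec),
                         ellipsoids_overlap(q, p, spec))
    }
    # semi-axis convention doubles the reach
    semi <- ellipsoid_spec(200, 500, "semi-axis")
    expect_true(ellipsoids_overlap(c(0, 0, 0), c(400, 0, 0), semi))
})

test_that("enlarging the ellipsoid never breaks an existing overlap", {
    set.seed(2)
    base <- ellipsoid_spec(200, 500)
    big <- ellipsoid_spec(300, 700)
    for (i in 1:50) {
        p <- runif(3, 0, 600); q <- runif(3, 0, 600)
        if (ellipsoids_overlap(p, q, base))
            expect_true(ellipsoids_overlap(p, q, big))
    }
})

test_that("accelerated pairwise_coloc equals brute-force all-pairs", {
    spec <- ellipsoid_spec()
    field <- c(3000, 3000, 1500)  # dense enough that pairs always occur
    for (seed in 1:8) {
        A <- random_spot_set(40, field, channel = "a", seed = seed)
        B <- random_spot_set(40, field, channel = "b", seed = seed + 500)
        res <- pairwise_coloc(A, B, spec)
        oracle <- brute_coloc_pairs(A, B, spec)
        expect_gt(nrow(oracle), 0)
        got <- matrix(as.integer(as.matrix(res$pair_list)), ncol = 2)
        expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                     unname(oracle[order(oracle[, 1], oracle[, 2]), ,
                                   drop = FALSE]))
        expect_identical(res$n_A_coloc, length(unique(oracle[, 1])))
    }
})

test_that("identical sets colocalize fully; empty reference is undefined", {
    A <- random_spot_set(30, channel = "a", seed = 4)
    expect_equal(pairwise_coloc(A, A)$fraction_A_coloc, 1)
    empty <- A[integer(0)]
    res <- pairwise_coloc(empty, A)
    expect_identical(res$n_A_coloc, 0L)
    expect_true(is.na(res$fraction_A_coloc))
})

test_that("planted pairwise fractions are recovered from ground truth", {
    errs <- vapply(1:10, function(seed) {
        sp <- scene_spec(channels = c("a", "b"), n_spots_per_channel = 200,
                         coloc_plan = list(list(source = "a", target = "b",
                                                fraction = 0.5,
                                                jitter_sd_nm = 0)),
                         seed = seed)
        sc <- make_spot_scene(sp, render = FALSE)
        abs(pairwise_coloc(sc$spots$a, sc$spots$b)$fraction_A_coloc - 0.5)
    }, numeric(1))
    expect_lt(mean(errs), 0.02)
})

test_that("chance colocalization of uniform spots matches the Poisson rate", {
    # fraction ~ 1 - (1 - v_e/V)^nB with v_e the relative-position overlap
    # ellipsoid (semi-axes 2a, 2a, 2c)
    spec <- ellipsoid_spec()
    field <- c(12800, 12800, 3000)
    v_e <- 4 / 3 * pi * (2 * spec$a_nm)^2 * (2 * spec$c_nm)
    nB <- 200
    expected <- 1 - (1 - v_e / prod(field))^nB
    fr <- vapply(1:40, function(seed) {
        A <- random_spot_set(200, field, "a", seed)
        B <- random_spot_set(nB, field, "b", seed + 1000)
        pairwise_coloc(A, B, spec)$fraction_A_coloc
    }, numeric(1))
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - expected), 4 * se + 0.002)
})

test_that("synaptic filtering returns exactly the Syp-overlapping pool", {
    A <- random_spot_set(50, channel = "a", seed = 6)
    # Syp on top of the first 20 A spots
    syp <- spot_set(A$centroids[1:20, ], source_channel = "syp",
                    field_size_nm = A$field_size_nm)
    filt <- synaptic_filter(A, syp)
    expect_setequal(filt$labels, 1:20)
    expect_identical(n_spots(synaptic_filter(A, syp[integer(0)])), 0L)
    # A entirely on Syp positions -> full A returned
    expect_identical(n_spots(synaptic_filter(syp, A)), 20L)
})

test_that("triple colocalization equals pairwise on the synaptic pools", {
    sp <- scene_spec(triple_plan = list(syp = "syp", a = "c1q", b = "np1",
                                        frac_a_synaptic = 0.5,
                                        frac_triple = 0.67,
                                        jitter_sd_nm = 0),
                     seed = 31)
    sc <- make_spot_scene(sp, render = FALSE)
    spec <- ellipsoid_spec()
    trip <- triple_coloc(sc$spots$c1q, sc$spots$np1, sc$spots$syp, spec)
    ref <- pairwise_coloc(synaptic_filter(sc$spots$c1q, sc$spots$syp, spec),
                          synaptic_filter(sc$spots$np1, sc$spots$syp, spec),
                          spec)
    expect_identical(trip$n_A_coloc, ref$n_A_coloc)
    expect_identical(trip$n_A, ref$n_A)
    # all three channels identical -> fraction 1
    S <- random_spot_set(25, channel = "s", seed = 7)
    expect_equal(triple_coloc(S, S, S)$fraction_A_coloc, 1)
})
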