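# Independent brute-force oracles used across tests.  These deliberately
# avoid the package's accelerated code paths.

# All-pairs ellipsoid-overlap oracle: double loop over scaled distances.
brute_coloc_pairs <- function(A, B, spec = ellipsoid_spec()) {
    sc <- c(spec$a_nm, spec$a_nm, spec$c_nm)
    sa <- sweep(A$centroids, 2, sc, "/")
    sb <- sweep(B$centroids, 2, sc, "/")
    out <- NULL
    for (i in seq_len(nrow(sa))) {
        for (j in seq_len(nrow(sb))) {
            d <- sqrt(sum((sa[i, ] - sb[j, ])^2))
            if (d <= 2 + 1e-12) out <- rbind(out, c(i, j))
        }
    }
    if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Brute-force local-maxima scan: for every voxel above the floor, compare
# against every voxel in the anisotropic ellipsoid neighbourhood.
brute_local_maxima <- function(img, voxel_size_nm, radius_nm, noise_floor) {
    dims <- dim(img)
    nmax <- floor(radius_nm / voxel_size_nm)
    hits <- NULL
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
        for (k in seq_len(dims[3])) {
            if (img[i, j, k] < noise_floor) next
            is_max <- TRUE
            for (di in -nmax[1]:nmax[1]) for (dj in -nmax[2]:nmax[2])
                for (dk in -nmax[3]:nmax[3]) {
                    if (di == 0 && dj == 0 && dk == 0) next
                    sc <- (di * voxel_size_nm[1] / radius_nm[1])^2 +
                          (dj * voxel_size_nm[2] / radius_nm[2])^2 +
                          (dk * voxel_size_nm[3] / radius_nm[3])^2
                    if (sc > 1 + 1e-12) next
                    ii <- i + di; jj <- j + dj; kk <- k + dk
                    if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
                        kk < 1 || kk > dims[3]) next
                    if (img[ii, jj, kk] >= img[i, j, k]) { is_max <- FALSE; break }
                }
            if (is_max) hits <- rbind(hits, c(i, j, k))
        }
    if (is.null(hits)) matrix(integer(0), ncol = 3) else hits
}

# Nearest-neighbour distance oracle: plain double loop.
brute_nn_dist <- function(A, B) {
    apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2))))
}

# Random spot set in a box field.
random_spot_set <- function(n, field = c(12800, 12800, 3000), channel = "x",
                            seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    spot_set(cbind(runif(n, 0, field[1]), runif(n, 0, field[2]),
                   runif(n, 0, field[3])),
             source_channel = channel, field_size_nm = field)
}
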