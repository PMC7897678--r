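# Object-based colocalization: two spots colocalize when the anisotropic
# PSF-approximating ellipsoids drawn around their centroids overlap in 3D.

#' Ellipsoid specification for object-based colocalization
#'
#' The ellipsoid approximates the microscope point spread function.  With
#' the default full-axis convention the stated sizes are total axis lengths
#' (diameters), i.e. semi-axes of 100 nm laterally and 250 nm axially.
#'
#' @param lateral_size_nm lateral size (default 200 nm).
#' @param axial_size_nm axial size (default 500 nm).
#' @param size_convention `"full-axis"` (sizes are diameters, the default)
#'   or `"semi-axis"` (sizes are semi-axes).
#' @return An object of class `ellipsoid_spec` with derived semi-axes
#'   `a_nm` (lateral) and `c_nm` (axial).
#' @examples
#' ellipsoid_spec()$a_nm  # 100
#' @export
ellipsoid_spec <- function(lateral_size_nm = 200, axial_size_nm = 500,
                           size_convention = c("full-axis", "semi-axis")) {
    stopifnot_scalar_num(lateral_size_nm, "lateral_size_nm", 1e-9)
    stopifnot_scalar_num(axial_size_nm, "axial_size_nm", 1e-9)
    size_convention <- match.arg(size_convention)
    half <- if (size_convention == "full-axis") 2 else 1
    structure(list(lateral_size_nm = lateral_size_nm,
                   axial_size_nm = axial_size_nm,
                   size_convention = size_convention,
                   a_nm = lateral_size_nm / half,
                   c_nm = axial_size_nm / half),
              class = "ellipsoid_spec")
}

#' Do the ellipsoids around two centroids overlap?
#'
#' Two identical axis-aligned ellipsoids with semi-axes `(a, a, c)` overlap
#' exactly when the centre separation, measured in ellipsoid-scaled space
#' `sqrt((dx/a)^2 + (dy/a)^2 + (dz/c)^2)`, is at most 2.  Tangency counts
#' as overlap.
#'
#' @param c1,c2 numeric nm coordinates: 3-vectors or n x 3 matrices
#'   (recycled row-wise).
#' @param spec an [ellipsoid_spec()].
#' @return Logical vector.
#' @examples
#' ellipsoids_overlap(c(0, 0, 0), c(200, 0, 0))  # TRUE (tangent)
#' ellipsoids_overlap(c(0, 0, 0), c(0, 0, 600))  # FALSE
#' @export
ellipsoids_overlap <- function(c1, c2, spec = ellipsoid_spec()) {
    c1 <- matrix(as.numeric(c1), ncol = 3)
    c2 <- matrix(as.numeric(c2), ncol = 3)
    if (any(!is.finite(c1)) || any(!is.finite(c2)))
        stop("coordinates must be finite")
    d <- sqrt(((c1[, 1] - c2[, 1]) / spec$a_nm)^2 +
              ((c1[, 2] - c2[, 2]) / spec$a_nm)^2 +
              ((c1[, 3] - c2[, 3]) / spec$c_nm)^2)
    d <= 2
}

# Scale centroids into ellipsoid space (unit semi-axes); overlap is then
# scaled distance <= 2.
scale_coords <- function(S, spec) {
    sweep(S$centroids, 2, c(spec$a_nm, spec$a_nm, spec$c_nm), "/")
}

# All (a, b) index pairs with scaled distance <= 2, found by a sweep over
# B sorted on the scaled x coordinate.  Exact: returns precisely the
# brute-force all-pairs result.
overlap_pairs <- function(A, B, spec) {
    sa <- scale_coords(A, spec)
    sb <- scale_coords(B, spec)
    ordb <- order(sb[, 1])
    sbx <- sb[ordb, 1]
    out_a <- integer(0); out_b <- integer(0)
    for (i in seq_len(nrow(sa))) {
        lo <- findInterval(sa[i, 1] - 2, sbx) + 1L
        hi <- findInterval(sa[i, 1] + 2, sbx)
        if (hi < lo) next
        j <- ordb[lo:hi]
        d2 <- (sb[j, 1] - sa[i, 1])^2 + (sb[j, 2] - sa[i, 2])^2 +
              (sb[j, 3] - sa[i, 3])^2
        hit <- j[d2 <= 4 + 1e-12]
        if (length(hit)) {
            out_a <- c(out_a, rep.int(i, length(hit)))
            out_b <- c(out_b, hit)
        }
    }
    cbind(a = out_a, b = out_b)
}

#' Pairwise object-based colocalization between two spot sets
#'
#' Lists every (A, B) spot pair whose PSF ellipsoids overlap and reports the
#' fraction of A objects (the reference population) with at least one
#' overlapping B object.  An A object overlapping several B objects counts
#' once in the fraction; all pairs are still listed.  Counts for the other
#' direction are obtained by swapping the arguments.
#'
#' @param A,B [spot_set()]s from the same field.
#' @param spec an [ellipsoid_spec()].
#' @return An object of class `coloc_result`: `n_A`, `n_B`, `n_A_coloc`,
#'   `fraction_A_coloc` (`NA` when A is empty — undefined, distinct from 0),
#'   and `pair_list` (data.frame of A and B labels).
#' @export
pairwise_coloc <- function(A, B, spec = ellipsoid_spec()) {
    stopifnot(inherits(A, "spot_set"), inherits(B, "spot_set"))
    if (!isTRUE(all.equal(A$field_size_nm, B$field_size_nm)))
        stop("A and B must come from the same field")
    if (n_spots(A) == 0 || n_spots(B) == 0) {
        pr <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
    } else {
        pr <- overlap_pairs(A, B, spec)
    }
    n_a_coloc <- length(unique(pr[, 1]))
    structure(
        list(n_A = n_spots(A), n_B = n_spots(B), n_A_coloc = n_a_coloc,
             fraction_A_coloc = if (n_spots(A) > 0) n_a_coloc / n_spots(A)
                                else NA_real_,
             pair_list = data.frame(label_A = A$labels[pr[, 1]],
                                    label_B = B$labels[pr[, 2]]),
             spec = spec),
        class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
    cat(sprintf("<coloc_result> %d/%d reference objects colocalized (%s); %d pairs\n",
                x$n_A_coloc, x$n_A,
                if (is.na(x$fraction_A_coloc)) "undefined"
                else sprintf("%.1f%%", 100 * x$fraction_A_coloc),
                nrow(x$pair_list)))
    invisible(x)
}

#' Restrict a spot set to its synaptic (Syp-colocalized) pool
#'
#' Returns the subset of `A` whose ellipsoid overlaps at least one
#' synaptophysin (or other synapse-marker) object; labels are preserved.
#'
#' @param A,syp [spot_set()]s from the same field.
#' @param spec an [ellipsoid_spec()].
#' @return A [spot_set()].
#' @export
synaptic_filter <- function(A, syp, spec = ellipsoid_spec()) {
    stopifnot(inherits(A, "spot_set"), inherits(syp, "spot_set"))
    if (n_spots(A) == 0 || n_spots(syp) == 0) return(A[integer(0)])
    pr <- overlap_pairs(A, syp, spec)
    A[sort(unique(pr[, 1]))]
}

#' Triple ("synaptic") colocalization
#'
#' Pairwise colocalization restricted to the synaptic pools: equals
#' `pairwise_coloc(synaptic_filter(A, syp), synaptic_filter(B, syp))`.
#' The reference population is synaptic A.
#'
#' @param A,B,syp [spot_set()]s from the same field.
#' @param spec an [ellipsoid_spec()].
#' @return A `coloc_result` (see [pairwise_coloc()]).
#' @export
triple_coloc <- function(A, B, syp, spec = ellipsoid_spec()) {
    pairwise_coloc(synaptic_filter(A, syp, spec),
                   synaptic_filter(B, syp, spec), spec)
}
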