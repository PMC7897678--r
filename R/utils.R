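# Shared internal helpers.

# Run `expr` under a local RNG state seeded with `seed` (when non-NULL),
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic child seeds below 2^31 derived from one master seed.
child_seeds <- function(seed, n) {
    with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
        stop(sprintf("'%s' must be a finite number in [%g, %g]", name, lo, hi),
             call. = FALSE)
    invisible(x)
}

check_len3 <- function(x, name, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
        stop(sprintf("'%s' must be a numeric 3-vector", name), call. = FALSE)
    if (positive && any(x <= 0))
        stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
    invisible(x)
}

#' Mean and standard error across per-image rows
#'
#' The aggregate reported throughout: mean and SEM (sample SD / sqrt(n)).
#' With a single value the SEM is undefined and reported as `NA`.
#'
#' @param x numeric vector of per-image values.
#' @return A list with elements `mean`, `sem` and `n`.
#' @examples
#' summarize_fields(c(1, 2, 3))
#' @export
summarize_fields <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n == 0L) stop("no finite values to summarize")
    list(mean = mean(x), sem = if (n > 1L) sd(x) / sqrt(n) else NA_real_, n = n)
}
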