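# End-to-end orchestration: simulate (or load) fields, segment, colocalize,
# run the shuffle null and engulfment counting, and aggregate per-image
# rows into means +/- SEM, all under one master seed.

#' Build a run configuration
#'
#' A declarative description of a multi-field analysis run.  All defaults
#' are resolved at construction time so the stored configuration fully
#' documents the run.
#'
#' @param n_fields number of 3D fields (images) to analyse.
#' @param scene a [scene_spec()] template; its seed is re-derived per field
#'   from the master `seed`.
#' @param seg_params a [segmentation_params()].
#' @param ellipsoid an [ellipsoid_spec()].
#' @param reference,partner,synapse channel names used as reference (A),
#'   partner (B) and synapse marker for the triple analysis; defaults are
#'   taken from `scene$triple_plan` when present, else the first channels.
#' @param use_ground_truth analyse planted centroids directly instead of
#'   segmenting rendered images (faster; default `FALSE`).
#' @param shuffle list: `enabled`, `n_iterations` for the shuffle-null
#'   stage.
#' @param mask_threshold intensity threshold for the engulfment mask stage;
#'   the stage runs only when the scene has a `mask_plan`.
#' @param output_dir optional directory for per-image CSV outputs.
#' @param seed master seed governing every stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_fields = 3,
                       scene = scene_spec(),
                       seg_params = segmentation_params(),
                       ellipsoid = ellipsoid_spec(),
                       reference = NULL, partner = NULL, synapse = NULL,
                       use_ground_truth = FALSE,
                       shuffle = list(enabled = TRUE, n_iterations = 100),
                       mask_threshold = 15000,
                       output_dir = NULL,
                       seed = 1L) {
    stopifnot(inherits(scene, "scene_spec"),
              inherits(seg_params, "segmentation_params"),
              inherits(ellipsoid, "ellipsoid_spec"))
    stopifnot_scalar_num(n_fields, "n_fields", 1)
    tp <- scene$triple_plan
    reference <- reference %||% (if (!is.null(tp)) tp$a else scene$channels[1])
    partner <- partner %||%
        (if (!is.null(tp)) tp$b else scene$channels[min(2, length(scene$channels))])
    synapse <- synapse %||% (if (!is.null(tp)) tp$syp else NULL)
    for (ch in c(reference, partner, synapse))
        if (!ch %in% scene$channels)
            stop(sprintf("channel '%s' is not in the scene", ch))
    shuffle$enabled <- isTRUE(shuffle$enabled %||% TRUE)
    shuffle$n_iterations <- shuffle$n_iterations %||% 100
    structure(list(n_fields = as.integer(n_fields), scene = scene,
                   seg_params = seg_params, ellipsoid = ellipsoid,
                   reference = reference, partner = partner,
                   synapse = synapse,
                   use_ground_truth = isTRUE(use_ground_truth),
                   shuffle = shuffle, mask_threshold = mask_threshold,
                   output_dir = output_dir, seed = as.integer(seed)),
              class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Understands the keys of [run_config()]; nested `scene`, `seg_params` and
#' `ellipsoid` maps are passed to their constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    scene <- do.call(scene_spec, y$scene %||% list())
    seg <- do.call(segmentation_params, y$seg_params %||% list())
    ell <- do.call(ellipsoid_spec, y$ellipsoid %||% list())
    run_config(n_fields = y$n_fields %||% 3, scene = scene, seg_params = seg,
               ellipsoid = ell, reference = y$reference,
               partner = y$partner, synapse = y$synapse,
               use_ground_truth = y$use_ground_truth %||% FALSE,
               shuffle = y$shuffle %||% list(enabled = TRUE, n_iterations = 100),
               mask_threshold = y$mask_threshold %||% 15000,
               output_dir = y$output_dir, seed = y$seed %||% 1L)
}

analyse_field <- function(config, field_seed) {
    sc <- config$scene
    sc$seed <- field_seed
    scene <- make_spot_scene(sc, render = !config$use_ground_truth)
    get_spots <- function(ch) {
        if (config$use_ground_truth) scene$spots[[ch]]
        else segment_channel(scene$grids[[ch]], config$seg_params)
    }
    A <- get_spots(config$reference)
    B <- get_spots(config$partner)
    syp <- if (!is.null(config$synapse)) get_spots(config$synapse) else NULL
    pair <- pairwise_coloc(A, B, config$ellipsoid)
    trip <- if (!is.null(syp)) triple_coloc(A, B, syp, config$ellipsoid)
            else NULL
    env <- NULL
    if (isTRUE(config$shuffle$enabled) && n_spots(A) > 0 && n_spots(B) > 0)
        env <- shuffle_envelope(A, B, config$shuffle$n_iterations,
                                seed = field_seed)
    eng <- NULL
    if (!is.null(sc$mask_plan)) {
        ms <- make_mask_scene(sc, render = TRUE)
        mask <- segment_mask(ms$grid, config$mask_threshold)
        eng <- count_engulfed(ms$spots, mask,
                              ms$np_flag %||% rep(FALSE, n_spots(ms$spots)))
    }
    list(spots = list(A = A, B = B, syp = syp), pairwise = pair,
         triple = trip, envelope = env, engulfment = eng,
         n_planted = vapply(scene$truth$centroids, nrow, integer(1)))
}

#' Run the full analysis pipeline over synthetic fields
#'
#' For each field: simulate the scene, obtain spot sets (segmentation of the
#' rendered channels, or the planted centroids), run pairwise and triple
#' colocalization, the shuffle-null envelope and — when the scene has a mask
#' plan — engulfment counting.  Per-image rows are aggregated as mean
#' +/- SEM, and the signed-rank observed-vs-null test is reported when at
#' least 6 fields carry an envelope.  Identical configurations (including
#' the master seed) give identical reports.
#'
#' @param config a [run_config()].
#' @return An object of class `run_report`: `per_image` (data.frame),
#'   `aggregates` (list of [summarize_fields()] results), `null_test`,
#'   `config`, `version`.
#' @export
run_pipeline <- function(config) {
    stopifnot(inherits(config, "run_config"))
    field_seeds <- child_seeds(config$seed, config$n_fields)
    rows <- list()
    results <- vector("list", config$n_fields)
    for (f in seq_len(config$n_fields)) {
        res <- analyse_field(config, field_seeds[f])
        results[[f]] <- res
        rows[[f]] <- data.frame(
            field = f,
            n_A = res$pairwise$n_A, n_B = res$pairwise$n_B,
            fraction_A_coloc = res$pairwise$fraction_A_coloc,
            fraction_triple = if (!is.null(res$triple))
                res$triple$fraction_A_coloc else NA_real_,
            observed_median_nm = if (!is.null(res$envelope))
                res$envelope$observed_median else NA_real_,
            null_median_nm = if (!is.null(res$envelope))
                res$envelope$null_median else NA_real_,
            engulfed_fraction_NP = if (!is.null(res$engulfment))
                res$engulfment$fraction_NP_positive else NA_real_)
    }
    per_image <- do.call(rbind, rows)
    agg_of <- function(col) {
        v <- per_image[[col]]
        if (all(!is.finite(v))) NULL else summarize_fields(v)
    }
    aggregates <- Filter(Negate(is.null), list(
        fraction_A_coloc = agg_of("fraction_A_coloc"),
        fraction_triple = agg_of("fraction_triple"),
        observed_median_nm = agg_of("observed_median_nm"),
        null_median_nm = agg_of("null_median_nm"),
        engulfed_fraction_NP = agg_of("engulfed_fraction_NP")))
    null_test <- NULL
    ok <- is.finite(per_image$observed_median_nm) &
          is.finite(per_image$null_median_nm)
    if (sum(ok) >= 6)
        null_test <- compare_observed_vs_null(
            per_image$observed_median_nm[ok], per_image$null_median_nm[ok])
    if (!is.null(config$output_dir)) {
        dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
        write.csv(per_image,
                  file.path(config$output_dir, "per_image.csv"),
                  row.names = FALSE)
        jsonlite::write_json(
            list(aggregates = aggregates, null_test = null_test,
                 seed = config$seed,
                 version = as.character(utils::packageVersion("puncta3d"))),
            file.path(config$output_dir, "report.json"),
            auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    structure(list(per_image = per_image, aggregates = aggregates,
                   null_test = null_test, fields = results,
                   config = config,
                   version = as.character(utils::packageVersion("puncta3d"))),
              class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
    cat(sprintf("<run_report> %d fields (seed %d)\n",
                x$config$n_fields, x$config$seed))
    for (nm in names(x$aggregates)) {
        a <- x$aggregates[[nm]]
        cat(sprintf("  %-22s mean %.4g +/- %.4g SEM (n = %d)\n",
                    nm, a$mean, if (is.na(a$sem)) NA else a$sem, a$n))
    }
    if (!is.null(x$null_test))
        cat(sprintf("  shuffle null: signed-rank p = %.3g (n = %d)\n",
                    x$null_test$p_value, x$null_test$n))
    invisible(x)
}
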