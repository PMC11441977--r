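#' Run configuration
#'
#' Bundles every setting of a coarse-graining run so that outputs are fully
#' reproducible: scale grid, grid-origin policy and seed, surface-extraction
#' mode and smoothing, rescaling reference and output paths. The logarithm
#' base of the K/I/S coordinates is fixed at 10 and recorded. A run's config
#' is serialised into a JSON sidecar next to every output table.
#'
#' @param scales numeric scale grid (mm) or `NULL` for [default_scales()].
#' @param origin_policy `"bbox"` or `"jitter"`.
#' @param seed integer seed (mandatory with jitter).
#' @param mode `"marching"` or `"faces"`.
#' @param smooth_iters Taubin iterations for marching-mode surfaces.
#' @param lambda_ref rescaling reference (mm) or `NULL` for the smallest scale.
#' @param min_voxels degeneracy threshold.
#' @param out_dir output directory.
#' @return a `cs_config` list.
#' @export
cs_config <- function(scales = NULL, origin_policy = "bbox", seed = NULL,
                      mode = "marching", smooth_iters = 0L, lambda_ref = NULL,
                      min_voxels = 8L, out_dir = ".") {
  structure(list(scales = scales, origin_policy = origin_policy, seed = seed,
                 mode = mode, smooth_iters = smooth_iters,
                 lambda_ref = lambda_ref, min_voxels = min_voxels,
                 log_base = 10L, out_dir = out_dir),
            class = "cs_config")
}

#' End-to-end pipeline over one or more surface pairs
#'
#' For each input object: melt sweep, morphometric measurement, K/I/S
#' trajectory, scaling-law fit and trajectory classification. Writes (when
#' `write = TRUE`) a per-scale morphometrics TSV, a fits TSV and a JSON config
#' sidecar into `config$out_dir`. Deterministic given the config (including
#' seeds).
#'
#' @param inputs named list of `cs_pair`/`cs_mesh` objects, or a character
#'   vector of surface file paths (single-surface mode) read with
#'   [read_surface()].
#' @param config a [cs_config()].
#' @param native measure and include native-scale points (pairs only).
#' @param write write TSV outputs.
#' @return list with `trajectories`, `fits`, `classifications`, `morpho`
#'   (combined data frame), `fits_table`.
#' @export
run_pipeline <- function(inputs, config = cs_config(), native = FALSE,
                         write = TRUE) {
  if (is.character(inputs)) {
    paths <- inputs
    inputs <- lapply(paths, read_surface)
    names(inputs) <- basename(paths)
  }
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- sprintf("object%02d", seq_along(inputs))
  trajectories <- fits <- classes <- list()
  for (nm in names(inputs)) {
    pair <- as_pair(inputs[[nm]])
    scales <- config$scales %||% default_scales(pair)
    melt <- melt_sweep(pair, scales, origin_policy = config$origin_policy,
                       seed = config$seed, mode = config$mode,
                       smooth_iters = config$smooth_iters,
                       min_voxels = config$min_voxels)
    traj <- measure_sweep(melt, lambda_ref = config$lambda_ref,
                          native = native && !is.null(pair$white),
                          pair = pair, id = nm)
    trajectories[[nm]] <- traj
    fits[[nm]] <- fit_scaling_law(traj)
    classes[[nm]] <- classify_trajectory(traj)
  }
  morpho <- do.call(rbind, trajectories)
  fits_table <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(object = nm, alpha = f$alpha, alpha_ci_lo = f$alpha_ci[1],
               alpha_ci_hi = f$alpha_ci[2], log10_k = f$log_k, df = f$df,
               r2 = f$r2, n = f$n, a0_ref = f$A0,
               label = classes[[nm]]$label, stringsAsFactors = FALSE)
  }))
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(morpho, file.path(config$out_dir, "morpho.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fits_table, file.path(config$out_dir, "fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cfg <- config
    cfg$scales <- as.numeric(cfg$scales)
    jsonlite::write_json(unclass(cfg),
                         file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(trajectories = trajectories, fits = fits, classifications = classes,
       morpho = morpho, fits_table = fits_table)
}

#' Diagnostic plots
#'
#' `plot_scaling`: log-log scaling plot (`log10(At sqrt(T))` vs `log10 Ae`)
#' with slope-1 reference lines. `plot_kis`: K x S trajectories with the
#' convex reference line `K = -S/9`. `plot_effect`: effect size against scale.
#'
#' @param trajectories list of `cs_trajectory` objects.
#' @return a ggplot object.
#' @export
plot_scaling <- function(trajectories) {
  d <- do.call(rbind, lapply(trajectories, as.data.frame))
  if (is.null(d) || nrow(d) == 0L) stop("no trajectories to plot")
  d$x <- log10(d$Ae); d$y <- log10(d$At * sqrt(d$T))
  ref <- data.frame(intercept = pretty(d$y - d$x, 5))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$id)) +
    ggplot2::geom_abline(data = ref,
                         ggplot2::aes(intercept = .data$intercept, slope = 1),
                         colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d[d$native, , drop = FALSE], size = 2) +
    ggplot2::labs(x = expression(log[10] ~ A[e]),
                  y = expression(log[10] ~ (A[t] * sqrt(T))),
                  colour = "object") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scaling
#' @export
plot_kis <- function(trajectories) {
  d <- do.call(rbind, lapply(trajectories, as.data.frame))
  if (is.null(d) || nrow(d) == 0L) stop("no trajectories to plot")
  sr <- range(d$S)
  conv <- data.frame(S = sr, K = -sr / 9)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$S, y = .data$K, colour = .data$id)) +
    ggplot2::geom_line(data = conv, ggplot2::aes(x = .data$S, y = .data$K),
                       inherit.aes = FALSE, colour = "black",
                       linetype = "dashed") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "S (morphological complexity)", y = "K (offset)",
                  colour = "object") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scaling
#' @param curve a `cs_effect` from [compare_groups()].
#' @param effect column to draw.
#' @export
plot_effect <- function(curve, effect = "ranksum_z") {
  d <- as.data.frame(curve)
  d <- d[d$flag == "", , drop = FALSE]
  if (nrow(d) == 0L) stop("empty effect table")
  d <- d[!d$native, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data[[effect]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda ~ (mm)), y = effect) +
    ggplot2::theme_minimal()
}
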