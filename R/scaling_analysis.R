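#' Fit the universal scaling law to a trajectory
#'
#' Ordinary least squares of `y = log10(At * sqrt(T))` on `x = log10(Ae)`
#' across the realisations of one trajectory. The slope is the scaling
#' exponent alpha; the fractal dimension is `df = 2 * alpha` (the factor 2
#' being the topological dimension of areas); the intercept is `log10 k`. The
#' fundamental area element `A0 = T^2 / k^4` is reported at the reference
#' thickness (the native thickness when present, otherwise the thickness at
#' the smallest scale).
#'
#' @param traj a `cs_trajectory` (or data frame with `At`, `Ae`, `T` columns).
#' @param fit_range optional `c(min, max)` interval of lambda (mm) restricting
#'   the fitted points; the native point is kept unless `include_native` is
#'   `FALSE`.
#' @param include_native include the native-scale point in the fit.
#' @param conf confidence level for the t-based slope interval.
#' @return a `cs_scalingfit`: list with `alpha`, `alpha_ci`, `log_k`, `k`,
#'   `df`, `r2`, `n`, `A0`, `T_ref`, `fit` (the `lm` object).
#' @export
fit_scaling_law <- function(traj, fit_range = NULL, include_native = TRUE,
                            conf = 0.95) {
  d <- as.data.frame(traj)
  if (!is.null(d$native) && !include_native) d <- d[!d$native, , drop = FALSE]
  if (!is.null(fit_range) && !is.null(d$lambda)) {
    keep <- (!is.null(d$native) & d$native) |
      (d$lambda >= fit_range[1] & d$lambda <= fit_range[2])
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) < 3L) stop("need at least 3 points to fit the scaling law")
  x <- log10(d$Ae)
  y <- log10(d$At * sqrt(d$T))
  if (stats::var(x) <= 0) stop("zero variance in log10(Ae); cannot fit")
  fit <- stats::lm(y ~ x)
  alpha <- unname(stats::coef(fit)[2])
  log_k <- unname(stats::coef(fit)[1])
  ci <- unname(stats::confint(fit, "x", level = conf))
  r2 <- summary(fit)$r.squared
  T_ref <- if (!is.null(d$native) && any(d$native)) d$T[d$native][1]
           else d$T[which.min(d$lambda)]
  structure(list(alpha = alpha, alpha_ci = as.numeric(ci), log_k = log_k,
                 k = 10^log_k, df = 2 * alpha, r2 = r2, n = nrow(d),
                 A0 = compute_A0(T_ref, 10^log_k), T_ref = T_ref,
                 conf = conf, fit = fit),
            class = "cs_scalingfit")
}

#' @export
print.cs_scalingfit <- function(x, ...) {
  cat(sprintf(
    "<scaling-law fit: alpha = %.4f [%.4f, %.4f], log10 k = %.4f (k = %.4f),\n  df = %.3f, R^2 = %.6f, n = %d, A0 = %.4g mm^2>\n",
    x$alpha, x$alpha_ci[1], x$alpha_ci[2], x$log_k, x$k, x$df, x$r2, x$n, x$A0))
  invisible(x)
}

#' Group-level scaling-law fit
#'
#' `method = "two-stage"` (default): per-object OLS slopes and intercepts,
#' then the mean slope with a t-based confidence interval over objects and the
#' standard deviation of intercepts across objects. `method = "lmm"`: a
#' random-intercept, common-slope linear mixed model (requires lme4); the
#' intercept spread is the random-intercept standard deviation. Both report
#' the same fields.
#'
#' @param trajs list of `cs_trajectory` objects.
#' @param method `"two-stage"` or `"lmm"`.
#' @param conf confidence level.
#' @param ... passed to [fit_scaling_law()] for the per-object fits.
#' @return list with `slope`, `slope_ci`, `intercept_mean`, `intercept_sd`,
#'   `method`, `n_objects`, and `per_object` (two-stage) or `model` (lmm).
#' @export
fit_group_slope <- function(trajs, method = c("two-stage", "lmm"),
                            conf = 0.95, ...) {
  method <- match.arg(method)
  if (length(trajs) < 2L) stop("need at least 2 trajectories")
  if (method == "two-stage") {
    fits <- lapply(seq_along(trajs), function(i) {
      f <- tryCatch(fit_scaling_law(trajs[[i]], ...), error = function(e)
        stop(sprintf("trajectory %d unfittable: %s", i, conditionMessage(e)),
             call. = FALSE))
      f
    })
    slopes <- vapply(fits, `[[`, 0, "alpha")
    inters <- vapply(fits, `[[`, 0, "log_k")
    n <- length(slopes)
    se <- stats::sd(slopes) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    ci <- if (se > 0) mean(slopes) + c(-1, 1) * tq * se
          else rep(mean(slopes), 2)
    list(slope = mean(slopes), slope_ci = ci,
         intercept_mean = mean(inters), intercept_sd = stats::sd(inters),
         method = method, n_objects = n,
         per_object = data.frame(object = seq_len(n), alpha = slopes,
                                 log_k = inters))
  } else {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method = 'lmm' requires the lme4 package")
    dd <- do.call(rbind, lapply(seq_along(trajs), function(i) {
      d <- as.data.frame(trajs[[i]])
      data.frame(x = log10(d$Ae), y = log10(d$At * sqrt(d$T)),
                 object = factor(i))
    }))
    m <- lme4::lmer(y ~ x + (1 | object), data = dd)
    fe <- lme4::fixef(m)
    se <- sqrt(diag(as.matrix(stats::vcov(m))))["x"]
    z <- stats::qnorm(1 - (1 - conf) / 2)
    vc <- as.data.frame(lme4::VarCorr(m))
    list(slope = unname(fe["x"]),
         slope_ci = unname(fe["x"] + c(-1, 1) * z * se),
         intercept_mean = unname(fe["(Intercept)"]),
         intercept_sd = vc$sdcor[vc$grp == "object"][1],
         method = method, n_objects = length(trajs), model = m)
  }
}

#' Box-counting fractal dimension
#'
#' Voxelises the object at each scale (bounding-box-aligned grids) and fits
#' the OLS slope of `log10 N` against `log10(1 / lambda)`, the classic
#' box-count estimate of fractal dimension.
#'
#' @param pair a `cs_pair` or single `cs_mesh`.
#' @param scales box sides (mm), at least 3 valid values.
#' @param counts optional precomputed data frame (`lambda`, `N`) to fit
#'   without re-voxelising.
#' @return list with `df` (slope), `r2`, `counts` (per-scale lambda/N), `fit`.
#' @export
box_count_dimension <- function(pair, scales = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(scales) || length(scales) < 3L)
      stop("need at least 3 scales for a box-count fit")
    N <- vapply(scales, function(lam)
      voxelise_ribbon(pair, lam)$n_occupied, 0L)
    counts <- data.frame(lambda = scales, N = N)
  }
  counts <- counts[counts$N > 0, , drop = FALSE]
  if (nrow(counts) < 3L) stop("fewer than 3 non-degenerate scales")
  fit <- stats::lm(log10(N) ~ log10(1 / lambda), data = counts)
  list(df = unname(stats::coef(fit)[2]), r2 = summary(fit)$r.squared,
       counts = counts, fit = fit)
}

#' Fundamental area element
#'
#' `A0 = T^2 / k^4`, the algebraic solution of the scaling law at
#' `At = Ae = A0`: the threshold area between gyrencephaly and lissencephaly,
#' and the size of the smallest possible gyri and sulci for a cortex of
#' thickness T.
#'
#' @param T average cortical thickness (mm).
#' @param k dimensionless scaling-law offset.
#' @return A0 in mm^2.
#' @export
compute_A0 <- function(T, k) {
  if (any(T <= 0) || any(k <= 0)) stop("T and k must be positive")
  T^2 / k^4
}

#' @rdname compute_A0
#' @param At total area (mm^2).
#' @param A0 fundamental area element (mm^2).
#' @return estimated number of structural features, `At / A0`.
#' @export
feature_count <- function(At, A0) At / A0

#' Classify a K x S trajectory
#'
#' OLS slope of K on S across the trajectory. Labels: `convex-line` when the
#' slope is within `tol_convex` of -1/9 and the residuals are small (the
#' identity `K = -S/9` holds exactly whenever `Ae = At`, i.e. for convex
#' objects at every scale); `flat-fractal` when the slope is within
#' `tol_flat` of 0 and the K range is below `k_range_thresh` (a constant-K
#' trajectory is the signature of a fractal of dimension 2.5); otherwise
#' `other`. Non-flat slopes are reported as slopes, not converted to a
#' dimension.
#'
#' @param traj a `cs_trajectory` (needs `K` and `S` columns, >= 3 rows).
#' @param tol_convex,tol_flat slope tolerances.
#' @param k_range_thresh maximum K range for the flat-fractal label.
#' @param max_rmse residual tolerance for the convex-line label.
#' @return list with `label`, `slope`, `rmse`, `K_range`, `S_range`, and the
#'   thresholds used.
#' @export
classify_trajectory <- function(traj, tol_convex = 0.02, tol_flat = 0.02,
                                k_range_thresh = 0.05, max_rmse = 0.02) {
  d <- as.data.frame(traj)
  if (nrow(d) < 3L) stop("need at least 3 points to classify a trajectory")
  if (is.null(d$K) || is.null(d$S)) stop("trajectory lacks K/S columns")
  K_range <- diff(range(d$K))
  S_range <- diff(range(d$S))
  if (S_range < 1e-9) {
    # a point-like trajectory (e.g. a cube: every realisation is an isometric
    # copy): classify by position relative to the convex line
    on_line <- max(abs(d$K + d$S / 9)) < tol_convex
    return(list(label = if (on_line) "convex-line" else "other",
                slope = NA_real_, rmse = 0,
                K_range = K_range, S_range = S_range,
                tol_convex = tol_convex, tol_flat = tol_flat,
                k_range_thresh = k_range_thresh))
  }
  fit <- stats::lm(K ~ S, data = d)
  slope <- unname(stats::coef(fit)[2])
  rmse <- sqrt(mean(stats::resid(fit)^2))
  label <- if (!is.finite(slope)) "other"
    else if (abs(slope) < tol_flat && K_range < k_range_thresh) "flat-fractal"
    else if (abs(slope + 1 / 9) < tol_convex && rmse < max_rmse) "convex-line"
    else "other"
  list(label = label, slope = slope, rmse = rmse,
       K_range = K_range, S_range = S_range,
       tol_convex = tol_convex, tol_flat = tol_flat,
       k_range_thresh = k_range_thresh)
}

#' Generate realisations exactly on the scaling law
#'
#' Utility for parameter-recovery studies: points satisfying
#' `At * sqrt(T) = k * Ae^alpha` exactly, with optional multiplicative
#' log-normal noise on At.
#'
#' @param n number of points.
#' @param k,alpha law parameters.
#' @param Ae_range range of exposed areas (mm^2), log-spaced.
#' @param T_fun thickness as a function of Ae (default constant 2.5 mm).
#' @param sigma standard deviation of Gaussian noise added to log10(At).
#' @param seed optional seed for the noise.
#' @return a data frame usable by [fit_scaling_law()].
#' @export
law_points <- function(n = 10, k = 0.2277, alpha = 1.25,
                       Ae_range = c(1e3, 1e5), T_fun = function(Ae) 2.5,
                       sigma = 0, seed = NULL) {
  Ae <- 10^seq(log10(Ae_range[1]), log10(Ae_range[2]), length.out = n)
  T <- vapply(Ae, T_fun, 0)
  At <- k * Ae^alpha / sqrt(T)
  if (sigma > 0) {
    eps <- if (is.null(seed)) stats::rnorm(n, 0, sigma)
           else with_seed(seed, stats::rnorm(n, 0, sigma))
    At <- At * 10^eps
  }
  data.frame(lambda = seq_len(n), At = At, Ae = Ae, T = T,
             native = FALSE)
}
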