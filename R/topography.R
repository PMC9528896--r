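# Principal-gradient topography of the coherence effect: voxelwise
# correlations with the gradient, decile binning, per-participant bin means,
# and linear mixed models with a quadratic trend in gradient bin.

#' Correlate a voxel map with the principal gradient
#'
#' Pearson correlation, over voxels, between map values (typically group-mean
#' coherence betas) and gradient position, optionally restricted to a mask.
#' The p-value comes from the usual t transform but is descriptive only:
#' voxels are spatially autocorrelated, not independent.
#'
#' @param map Tibble with columns `voxel`, `value`.
#' @param gradient Tibble with columns `voxel`, `gradient`.
#' @param mask Optional character vector of voxel ids to restrict to.
#' @return A one-row tibble: `r`, `p` (descriptive), `n_voxels`.
#' @export
gradient_correlation <- function(map, gradient, mask = NULL) {
  require_columns(map, c("voxel", "value"), "voxel map")
  require_columns(gradient, c("voxel", "gradient"), "gradient map")
  joined <- dplyr::inner_join(map, gradient, by = "voxel")
  if (nrow(joined) < nrow(map) || nrow(joined) < nrow(gradient)) {
    if (nrow(joined) == 0) {
      abort_glocoh("map and gradient share no voxel ids.", "glocoh_input_error")
    }
  }
  if (!setequal(map$voxel, gradient$voxel)) {
    abort_glocoh("map and gradient are defined on different voxel sets.",
                 "glocoh_input_error")
  }
  if (!is.null(mask)) {
    joined <- joined[joined$voxel %in% mask, ]
  }
  n <- nrow(joined)
  if (n < 3) {
    abort_glocoh("need at least 3 voxels after masking.", "glocoh_input_error")
  }
  if (stats::sd(joined$value) == 0 || stats::sd(joined$gradient) == 0) {
    abort_glocoh("correlation with a constant map is undefined.",
                 "glocoh_input_error")
  }
  r <- stats::cor(joined$value, joined$gradient)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(r = r, p = p, n_voxels = n)
}

#' Assign voxels to equal-sized gradient bins
#'
#' Voxels are ranked by ascending gradient value (bin 1 = unimodal end, bin
#' `n_bins` = multimodal end) and split into `n_bins` contiguous rank groups
#' whose sizes differ by at most one (lower bins take the extra voxel when
#' the count does not divide evenly). Ties in gradient value are broken by
#' stable voxel-id order, so the assignment is deterministic. Because only
#' ranks are used, the binning is invariant to strictly monotone transforms
#' of the gradient.
#'
#' @param gradient Tibble with columns `voxel`, `gradient`.
#' @param n_bins Number of bins (default 10).
#' @return The gradient tibble with an integer `bin` column added.
#' @export
decile_bins <- function(gradient, n_bins = 10) {
  require_columns(gradient, c("voxel", "gradient"), "gradient map")
  n <- nrow(gradient)
  if (n < n_bins) {
    abort_glocoh(sprintf("need at least %d voxels for %d bins.", n_bins, n_bins),
                 "glocoh_input_error")
  }
  ord <- order_by_value_then_voxel(gradient$gradient, gradient$voxel)
  sizes <- rep(floor(n / n_bins), n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bin_sorted <- rep.int(seq_len(n_bins), sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  dplyr::mutate(gradient, bin = bin)
}

#' Per-participant mean coherence effect in each gradient bin
#'
#' @param betas Tibble of per-participant voxel maps: columns `participant`,
#'   `voxel`, `value`, and optionally `task` (carried through).
#' @param bins Output of [decile_bins()].
#' @return A bin table: one row per (participant\[, task\], bin) with
#'   `mean_beta` and `n_voxels`. An empty bin is an error.
#' @export
gradient_bin_means <- function(betas, bins) {
  require_columns(betas, c("participant", "voxel", "value"), "beta maps")
  require_columns(bins, c("voxel", "bin"), "bin assignment")
  joined <- dplyr::inner_join(betas,
                              dplyr::select(bins, "voxel", "bin"),
                              by = "voxel")
  group_cols <- intersect(c("participant", "task", "bin"), names(joined))
  out <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(mean_beta = mean(.data$value), n_voxels = dplyr::n(),
                     .groups = "drop")
  n_bins <- length(unique(bins$bin))
  cells <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(group_cols, "bin")))) |>
    dplyr::summarise(n_bins_present = dplyr::n(), .groups = "drop")
  if (any(cells$n_bins_present < n_bins)) {
    abort_glocoh("at least one gradient bin is empty for some participant.",
                 "glocoh_input_error")
  }
  out
}

#' Mixed model for the coherence effect along the gradient
#'
#' Fits `mean_beta ~ bin + bin^2` (bin index centered before fitting; the
#' quadratic term is computed from the centered index) with by-participant
#' random effects, by restricted maximum likelihood via \pkg{lme4}. The
#' linear-versus-quadratic comparison refits both fixed structures by maximum
#' likelihood and reports the likelihood-ratio test. p-values for the fixed
#' effects use the normal approximation to the t statistic; the package does
#' not compute Satterthwaite degrees of freedom (see the methods vignette).
#'
#' @param bin_table Output of [gradient_bin_means()] (one task at a time).
#' @param quadratic Include the quadratic fixed term (default `TRUE`).
#' @param random Random-effects structure: `"intercept_slope"` (default:
#'   random intercept and random linear slope per participant),
#'   `"intercept"`, `"intercept_slope_quad"` (random quadratic slope too), or
#'   `"none"` (plain pooled OLS via `lm`).
#' @param center Centering constant for the bin index; defaults to the mean
#'   of the observed bin indices (5.5 for 10 bins).
#' @param lrt Perform the maximum-likelihood refits for the linear-versus-
#'   quadratic likelihood-ratio comparison (default `TRUE`; skip when only
#'   the REML fixed effects are needed).
#' @return A `gradient_trend` object; see [tidy.gradient_trend()] and
#'   [glance.gradient_trend()].
#' @export
fit_gradient_trend <- function(bin_table, quadratic = TRUE,
                               random = c("intercept_slope", "intercept",
                                          "intercept_slope_quad", "none"),
                               center = NULL, lrt = TRUE) {
  random <- match.arg(random)
  require_columns(bin_table, c("participant", "bin", "mean_beta"), "bin table")
  n_participants <- length(unique(bin_table$participant))
  if (random != "none" && n_participants < 5) {
    abort_glocoh("need at least 5 participants for the mixed model.",
                 "glocoh_input_error")
  }
  if (is.null(center)) {
    center <- mean(unique(bin_table$bin))
  }
  dat <- bin_table |>
    dplyr::mutate(bin_c = .data$bin - center,
                  bin_c2 = (.data$bin - center)^2)
  fixed_lin <- "mean_beta ~ bin_c"
  fixed_quad <- "mean_beta ~ bin_c + bin_c2"
  fixed <- if (quadratic) fixed_quad else fixed_lin
  re_term <- switch(random,
                    intercept = "(1 | participant)",
                    intercept_slope = "(1 + bin_c | participant)",
                    intercept_slope_quad = "(1 + bin_c + bin_c2 | participant)",
                    none = NULL)
  singular <- FALSE
  if (random == "none") {
    fit <- stats::lm(stats::as.formula(fixed), data = dat)
    co <- summary(fit)$coefficients[, 1:3, drop = FALSE]
    if (lrt) {
      fit_lin_ml <- stats::lm(stats::as.formula(fixed_lin), data = dat)
      fit_quad_ml <- stats::lm(stats::as.formula(fixed_quad), data = dat)
      lrt_stat <- as.numeric(2 * (stats::logLik(fit_quad_ml) - stats::logLik(fit_lin_ml)))
      loglik_lin <- as.numeric(stats::logLik(fit_lin_ml))
      loglik_quad <- as.numeric(stats::logLik(fit_quad_ml))
    }
  } else {
    form <- stats::as.formula(paste(fixed, "+", re_term))
    fit <- quiet_lmer(form, dat, REML = TRUE)
    if (lme4::isSingular(fit)) {
      singular <- TRUE
      vc <- lme4::VarCorr(fit)
      rlang::warn(paste0(
        "random-effects fit is singular; variance estimates are at the boundary:\n",
        paste(utils::capture.output(print(vc)), collapse = "\n")
      ), class = "glocoh_singular_warning")
    }
    co <- summary(fit)$coefficients
    if (lrt) {
      fit_lin_ml <- quiet_lmer(stats::as.formula(paste(fixed_lin, "+", re_term)),
                               dat, REML = FALSE)
      fit_quad_ml <- quiet_lmer(stats::as.formula(paste(fixed_quad, "+", re_term)),
                                dat, REML = FALSE)
      lrt_stat <- as.numeric(2 * (stats::logLik(fit_quad_ml) - stats::logLik(fit_lin_ml)))
      loglik_lin <- as.numeric(stats::logLik(fit_lin_ml))
      loglik_quad <- as.numeric(stats::logLik(fit_quad_ml))
    }
  }
  if (!lrt) {
    lrt_stat <- NA_real_
    loglik_lin <- NA_real_
    loglik_quad <- NA_real_
  }
  lrt_stat <- max(lrt_stat, 0)
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, 1]),
    std.error = unname(co[, 2]),
    statistic = unname(co[, 1] / co[, 2]),
    p.value = unname(2 * stats::pnorm(-abs(co[, 1] / co[, 2])))
  )
  structure(
    list(
      coefficients = coefs,
      fit = fit,
      lrt = tibble::tibble(
        statistic = lrt_stat, df = 1,
        p.value = if (is.na(lrt_stat)) NA_real_ else
          stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE),
        loglik_linear = loglik_lin, loglik_quadratic = loglik_quad
      ),
      quadratic = quadratic,
      random = random,
      center = center,
      singular = singular,
      n_participants = n_participants,
      data = dat
    ),
    class = "gradient_trend"
  )
}

quiet_lmer <- function(formula, data, REML) {
  withCallingHandlers(
    lme4::lmer(formula, data = data, REML = REML,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage")
  )
}

#' @export
print.gradient_trend <- function(x, ...) {
  cat(sprintf("<gradient_trend> %s trend, random = %s, %d participants%s\n",
              if (x$quadratic) "linear + quadratic" else "linear",
              x$random, x$n_participants,
              if (x$singular) " (singular random effects)" else ""))
  print(x$coefficients)
  cat(sprintf("LRT quadratic vs linear: chisq = %.3f, p = %.4g\n",
              x$lrt$statistic, x$lrt$p.value))
  invisible(x)
}

#' Tidy and summarize a gradient trend fit
#'
#' `tidy()` returns the fixed effects with normal-approximation p-values;
#' `glance()` returns model-level quantities including the likelihood-ratio
#' comparison of the linear-only and quadratic fixed structures.
#'
#' @param x A `gradient_trend`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gradient_trend <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.gradient_trend
#' @export
glance.gradient_trend <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    quadratic = x$quadratic,
    random = x$random,
    singular = x$singular,
    lrt_statistic = x$lrt$statistic,
    lrt_p.value = x$lrt$p.value,
    loglik_linear = x$lrt$loglik_linear,
    loglik_quadratic = x$lrt$loglik_quadratic
  )
}

#' Plot a gradient trend fit
#'
#' Participant bin means as light lines plus the population-level fitted
#' trend.
#'
#' @param object A `gradient_trend`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradient_trend <- function(object, ...) {
  dat <- object$data
  co <- object$coefficients
  grid <- tibble::tibble(bin = seq(min(dat$bin), max(dat$bin), length.out = 100))
  grid$bin_c <- grid$bin - object$center
  pred <- co$estimate[co$term == "(Intercept)"] +
    co$estimate[co$term == "bin_c"] * grid$bin_c
  if ("bin_c2" %in% co$term) {
    pred <- pred + co$estimate[co$term == "bin_c2"] * grid$bin_c^2
  }
  grid$mean_beta <- pred
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$mean_beta)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       alpha = 0.25, colour = "grey50") +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::scale_x_continuous(breaks = sort(unique(dat$bin))) +
    ggplot2::labs(x = "gradient bin (1 = unimodal, 10 = multimodal)",
                  y = "mean coherence effect (beta)") +
    ggplot2::theme_minimal()
}
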