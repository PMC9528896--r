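# First-level design construction: condition boxcars and block-wise parametric
# modulators convolved with a canonical double-gamma HRF at microtime
# resolution, discrete-cosine drift per run, runs concatenated with run
# intercepts.

#' Canonical double-gamma haemodynamic response function
#'
#' The SPM-style canonical HRF: a gamma density with shape (delay) parameter 6
#' minus an undershoot gamma with shape 16 scaled by 1/6, normalized to unit
#' peak.
#'
#' @param t Time in seconds (vector).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

# Build a (possibly weighted) boxcar on the microtime grid of one run and
# convolve it with the HRF; returns the regressor sampled at volume onsets.
convolve_events <- function(onsets, durations, weights, n_volumes, TR,
                            microtime = 0.1) {
  run_dur <- n_volumes * TR
  grid_n <- ceiling(run_dur / microtime) + 1L
  x <- numeric(grid_n)
  for (e in seq_along(onsets)) {
    j1 <- floor(onsets[e] / microtime + 1e-9) + 1L
    j2 <- floor((onsets[e] + durations[e]) / microtime + 1e-9)
    j2 <- min(j2, grid_n)
    if (j2 >= j1) {
      x[j1:j2] <- x[j1:j2] + weights[e]
    }
  }
  kernel <- hrf_double_gamma(seq(0, 32, by = microtime))
  kernel <- kernel / max(kernel)
  conv <- stats::convolve(x, rev(kernel), type = "open")[seq_len(grid_n)]
  sample_idx <- floor((seq_len(n_volumes) - 1) * TR / microtime + 1e-9) + 1L
  conv[sample_idx] * microtime
}

# Discrete-cosine drift basis for one run (SPM convention): K columns with
# K = floor(2 * N * TR / cutoff).
dct_basis <- function(n_volumes, TR, cutoff) {
  K <- floor(2 * n_volumes * TR / cutoff)
  if (K < 1) {
    return(matrix(numeric(0), nrow = n_volumes, ncol = 0))
  }
  n <- seq_len(n_volumes)
  sapply(seq_len(K), function(k) {
    sqrt(2 / n_volumes) * cos(pi * k * (2 * n - 1) / (2 * n_volumes))
  })
}

validate_events <- function(events, n_volumes, TR) {
  require_columns(events, c("run", "condition", "onset", "duration"), "events table")
  runs <- sort(unique(events$run))
  for (r in runs) {
    dur <- n_volumes[[match(r, runs)]] * TR
    ev_r <- events[events$run == r, ]
    if (any(ev_r$onset < 0) || any(ev_r$onset + ev_r$duration > dur + 1e-6)) {
      abort_glocoh(sprintf("events in run %s extend beyond the run duration (%g s).", r, dur),
                   "glocoh_input_error")
    }
    for (cond in unique(ev_r$condition)) {
      ev <- ev_r[ev_r$condition == cond, ]
      ev <- ev[order(ev$onset), ]
      if (nrow(ev) > 1 &&
          any(ev$onset[-1] < ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)] - 1e-9)) {
        abort_glocoh(sprintf("overlapping '%s' events in run %s.", cond, r),
                     "glocoh_overlap_error")
      }
    }
  }
  invisible(events)
}

#' Build a first-level design matrix
#'
#' Condition regressors are boxcars convolved with the canonical HRF at
#' microtime resolution and sampled at the TR. Discourse periods are modelled
#' as concatenated 5-s blocks carrying two parametric modulators: the block's
#' mean coherence and its time index within the period (1 to period/block
#' length). Modulator values are mean-centered within each run before
#' convolution; a missing (NA) coherence value is imputed to the run mean,
#' i.e. exactly 0 after centering, so it cannot drive the modulator effect.
#' Modulated regressors are *not* serially orthogonalized against each other:
#' correlated coherence and time modulators are estimated jointly by the GLM.
#' Each run contributes an intercept column and a discrete-cosine drift basis
#' with the requested high-pass cutoff; runs are concatenated row-wise.
#'
#' @param events Tibble with columns `run`, `condition`, `onset` (s),
#'   `duration` (s): one row per event (speech periods, baselines,
#'   preparation events).
#' @param modulators Optional tibble describing the 5-s blocks of the
#'   modulated (discourse) conditions: columns `run`, `condition`, `period`
#'   (period identifier), `block` (1-based index within the period, the time
#'   modulator), `onset`, `duration`, `coherence` (may be `NA`). Every
#'   discourse event must decompose into `duration / block duration`
#'   contiguous blocks.
#' @param n_volumes Integer vector of volumes per run (recycled if scalar).
#' @param TR Repetition time in seconds.
#' @param hp_cutoff High-pass filter cutoff in seconds for the drift basis.
#' @param microtime Microtime resolution in seconds for HRF convolution.
#' @return An `fmri_design` object: list with `X` (total volumes x
#'   regressors, named columns), `run` (run label per row), `TR`,
#'   `n_volumes`, `condition_cols`, `modulator_cols`, `drift_cols`, and
#'   `modulator_weights` (the centered pre-convolution block weights, for
#'   inspection).
#' @export
build_design <- function(events, modulators = NULL, n_volumes, TR = 1.7,
                         hp_cutoff = 128, microtime = 0.1) {
  runs <- sort(unique(events$run))
  if (length(n_volumes) == 1) {
    n_volumes <- rep(n_volumes, length(runs))
  }
  if (length(n_volumes) != length(runs)) {
    abort_glocoh("`n_volumes` must have one entry per run.", "glocoh_input_error")
  }
  validate_events(events, n_volumes, TR)
  conditions <- unique(events$condition)
  mod_conditions <- character(0)
  mod_weights <- NULL
  if (!is.null(modulators) && nrow(modulators) > 0) {
    require_columns(modulators,
                    c("run", "condition", "period", "block", "onset",
                      "duration", "coherence"),
                    "modulators table")
    check_modulator_blocks(events, modulators)
    mod_conditions <- unique(modulators$condition)
    mod_weights <- modulators |>
      dplyr::group_by(.data$run, .data$condition) |>
      dplyr::mutate(
        coherence_imputed = ifelse(is.na(.data$coherence),
                                   mean(.data$coherence, na.rm = TRUE),
                                   .data$coherence),
        coherence_centered = .data$coherence_imputed -
          mean(.data$coherence_imputed),
        time_centered = .data$block - mean(.data$block)
      ) |>
      dplyr::ungroup()
    if (any(!is.finite(mod_weights$coherence_centered))) {
      abort_glocoh("a run has no defined coherence modulator values at all.",
                   "glocoh_input_error")
    }
  }

  col_names <- c(
    conditions,
    unlist(lapply(mod_conditions, function(cc) paste0(cc, c("_coherence", "_time"))))
  )
  blocks <- list()
  drift_cols <- character(0)
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    nv <- n_volumes[ri]
    Xr <- matrix(0, nrow = nv, ncol = length(col_names),
                 dimnames = list(NULL, col_names))
    ev_r <- events[events$run == r, ]
    for (cond in conditions) {
      ev <- ev_r[ev_r$condition == cond, ]
      if (nrow(ev) > 0) {
        Xr[, cond] <- convolve_events(ev$onset, ev$duration,
                                      rep(1, nrow(ev)), nv, TR, microtime)
      }
    }
    if (!is.null(mod_weights)) {
      mw_r <- mod_weights[mod_weights$run == r, ]
      for (cond in mod_conditions) {
        mw <- mw_r[mw_r$condition == cond, ]
        if (nrow(mw) > 0) {
          Xr[, paste0(cond, "_coherence")] <-
            convolve_events(mw$onset, mw$duration, mw$coherence_centered,
                            nv, TR, microtime)
          Xr[, paste0(cond, "_time")] <-
            convolve_events(mw$onset, mw$duration, mw$time_centered,
                            nv, TR, microtime)
        }
      }
    }
    drift <- dct_basis(nv, TR, hp_cutoff)
    run_cols <- matrix(0, nrow = nv, ncol = 1 + ncol(drift))
    run_cols[, 1] <- 1
    if (ncol(drift) > 0) {
      run_cols[, -1] <- drift
    }
    colnames(run_cols) <- c(sprintf("run%s_intercept", r),
                            if (ncol(drift) > 0)
                              sprintf("run%s_dct%d", r, seq_len(ncol(drift))))
    drift_cols <- c(drift_cols, colnames(run_cols))
    blocks[[ri]] <- cbind(Xr, run_cols)
  }
  # Pad so every run block has the same columns, then stack.
  all_cols <- unique(unlist(lapply(blocks, colnames)))
  X <- do.call(rbind, lapply(blocks, function(b) {
    out <- matrix(0, nrow = nrow(b), ncol = length(all_cols),
                  dimnames = list(NULL, all_cols))
    out[, colnames(b)] <- b
    out
  }))
  zero_cols <- colnames(X)[colSums(abs(X)) == 0]
  if (length(zero_cols) > 0) {
    abort_glocoh(sprintf("all-zero design column(s): %s",
                         paste(zero_cols, collapse = ", ")),
                 "glocoh_design_error")
  }
  structure(
    list(
      X = X,
      run = rep(runs, n_volumes),
      TR = TR,
      n_volumes = stats::setNames(n_volumes, runs),
      hp_cutoff = hp_cutoff,
      microtime = microtime,
      condition_cols = conditions,
      modulator_cols = setdiff(col_names, conditions),
      drift_cols = drift_cols,
      modulator_weights = mod_weights
    ),
    class = "fmri_design"
  )
}

# Every modulated event must decompose into duration / block-duration blocks
# lying inside it.
check_modulator_blocks <- function(events, modulators) {
  for (cond in unique(modulators$condition)) {
    ev <- events[events$condition == cond, ]
    if (nrow(ev) == 0) {
      abort_glocoh(sprintf("modulators reference condition '%s' with no events.", cond),
                   "glocoh_input_error")
    }
    for (i in seq_len(nrow(ev))) {
      mw <- modulators[modulators$condition == cond &
                         modulators$run == ev$run[i] &
                         modulators$onset >= ev$onset[i] - 1e-9 &
                         modulators$onset < ev$onset[i] + ev$duration[i] - 1e-9, ]
      expected <- round(ev$duration[i] / mw$duration[1])
      if (nrow(mw) == 0 || nrow(mw) != expected) {
        abort_glocoh(
          sprintf("condition '%s' event at %g s (run %s) has %d modulator block(s); expected %s.",
                  cond, ev$onset[i], ev$run[i], nrow(mw),
                  if (nrow(mw) == 0) "duration / block-duration" else expected),
          "glocoh_modulator_error"
        )
      }
    }
  }
  invisible(modulators)
}

#' @export
print.fmri_design <- function(x, ...) {
  cat(sprintf("<fmri_design> %d volumes x %d regressors, %d run(s), TR = %g s, high-pass %g s\n",
              nrow(x$X), ncol(x$X), length(x$n_volumes), x$TR, x$hp_cutoff))
  invisible(x)
}

#' Plot a design matrix as a heat map
#'
#' @param object An `fmri_design`.
#' @param ... Unused.
#' @return A ggplot object (volumes on the vertical axis, regressors on the
#'   horizontal, columns scaled to unit maximum absolute value).
#' @export
autoplot.fmri_design <- function(object, ...) {
  X <- object$X
  scaled <- sweep(X, 2, pmax(apply(abs(X), 2, max), .Machine$double.eps), "/")
  df <- tibble::as_tibble(scaled, .name_repair = "minimal")
  names(df) <- colnames(X)
  df$volume <- seq_len(nrow(X))
  long <- tidyr::pivot_longer(df, -"volume", names_to = "regressor",
                              values_to = "value")
  long$regressor <- factor(long$regressor, levels = colnames(X))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$regressor, y = .data$volume,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = "volume", fill = "scaled\nvalue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
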