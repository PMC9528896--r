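# Massively univariate ordinary least squares over voxels, and contrasts of
# the fitted betas. No prewhitening: estimation is per participant and
# inference happens across participants downstream.

#' Fit the GLM at every voxel
#'
#' Ordinary least squares of each voxel's time series on the design matrix.
#' The design must be full column rank; a rank-deficient design is an error
#' that names the collinear columns.
#'
#' @param Y Numeric matrix, voxels x volumes. Row names (if present) are used
#'   as voxel ids, otherwise `v1..vN`.
#' @param design An [build_design()] `fmri_design`.
#' @return A `voxel_glm` object: list with `betas` (voxels x regressors),
#'   `sigma2` (residual variance per voxel), `df_residual`, `voxel` ids, and
#'   the `design`.
#' @export
fit_glm <- function(Y, design) {
  stopifnot(inherits(design, "fmri_design"))
  Y <- as.matrix(Y)
  X <- design$X
  if (ncol(Y) != nrow(X)) {
    abort_glocoh(sprintf("Y has %d volumes but the design has %d.", ncol(Y), nrow(X)),
                 "glocoh_input_error")
  }
  qrX <- qr(X, LAPACK = FALSE)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_glocoh(sprintf("design matrix is rank deficient; collinear column(s): %s",
                         paste(bad, collapse = ", ")),
                 "glocoh_rank_error")
  }
  voxel <- rownames(Y)
  if (is.null(voxel)) {
    voxel <- paste0("v", seq_len(nrow(Y)))
  }
  tY <- t(Y)
  betas <- t(qr.coef(qrX, tY))
  resid <- tY - X %*% t(betas)
  df_residual <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df_residual
  colnames(betas) <- colnames(X)
  rownames(betas) <- voxel
  structure(
    list(
      betas = betas,
      sigma2 = stats::setNames(sigma2, voxel),
      df_residual = df_residual,
      voxel = voxel,
      design = design
    ),
    class = "voxel_glm"
  )
}

#' @export
print.voxel_glm <- function(x, ...) {
  cat(sprintf("<voxel_glm> %d voxels x %d regressors (df = %d)\n",
              nrow(x$betas), ncol(x$betas), x$df_residual))
  invisible(x)
}

#' Turn a voxelwise GLM fit into a tidy tibble
#'
#' @param x A `voxel_glm`.
#' @param ... Unused.
#' @return One row per voxel x regressor: `voxel`, `term`, `estimate`.
#' @export
tidy.voxel_glm <- function(x, ...) {
  tibble::as_tibble(x$betas, rownames = "voxel") |>
    tidyr::pivot_longer(-"voxel", names_to = "term", values_to = "estimate")
}

#' @rdname tidy.voxel_glm
#' @export
glance.voxel_glm <- function(x, ...) {
  tibble::tibble(
    n_voxels = nrow(x$betas),
    n_regressors = ncol(x$betas),
    df_residual = x$df_residual,
    median_sigma2 = stats::median(x$sigma2)
  )
}

#' Weighted contrast of fitted betas
#'
#' @param fit A `voxel_glm`.
#' @param weights Named numeric vector of contrast weights over regressor
#'   names (e.g. `c(discourse_production = 1, baseline_production = -1)`).
#'   Unknown names are an error.
#' @return A tibble with columns `voxel` and `value` (the weighted sum of
#'   betas at each voxel).
#' @export
contrast_map <- function(fit, weights) {
  stopifnot(inherits(fit, "voxel_glm"))
  unknown <- setdiff(names(weights), colnames(fit$betas))
  if (length(unknown) > 0) {
    abort_glocoh(sprintf("unknown regressor(s) in contrast: %s",
                         paste(unknown, collapse = ", ")),
                 "glocoh_input_error")
  }
  value <- drop(fit$betas[, names(weights), drop = FALSE] %*% weights)
  tibble::tibble(voxel = fit$voxel, value = unname(value))
}

#' Extract one regressor's beta map as a tibble
#'
#' @param fit A `voxel_glm`.
#' @param term Regressor name.
#' @return Tibble with `voxel`, `value`.
#' @export
beta_map <- function(fit, term) {
  contrast_map(fit, stats::setNames(1, term))
}
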