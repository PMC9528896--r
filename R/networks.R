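# Network-of-interest analysis: overlap resolution between DMN / SCN / MDN
# masks, per-participant top-voxel selection on the discourse-minus-baseline
# contrast, a 2 x 3 repeated-measures ANOVA on the mean coherence effects,
# and the individual-differences covariate analysis.

#' Resolve overlapping network masks into disjoint sets
#'
#' Voxels in the semantic control network (SCN) are removed from the
#' default-mode (DMN) and multiple-demand (MDN) masks, and voxels shared
#' between DMN and MDN are removed from the DMN, so the three resolved masks
#' are pairwise disjoint. The SCN mask is left untouched. The operation is
#' idempotent.
#'
#' @param masks Tibble with columns `network` (values `"DMN"`, `"SCN"`,
#'   `"MDN"`) and `voxel`.
#' @return A list with `masks` (resolved, same format) and `audit` (tibble of
#'   removal counts per rule).
#' @export
resolve_networks <- function(masks) {
  require_columns(masks, c("network", "voxel"), "network masks")
  need <- c("DMN", "SCN", "MDN")
  missing <- setdiff(need, unique(masks$network))
  if (length(missing) > 0) {
    abort_glocoh(sprintf("missing network mask(s): %s", paste(missing, collapse = ", ")),
                 "glocoh_input_error")
  }
  sets <- lapply(need, function(nw) unique(masks$voxel[masks$network == nw]))
  names(sets) <- need
  dmn_minus_scn <- setdiff(sets$DMN, sets$SCN)
  resolved <- list(
    DMN = setdiff(dmn_minus_scn, sets$MDN),
    SCN = sets$SCN,
    MDN = setdiff(sets$MDN, sets$SCN)
  )
  audit <- tibble::tibble(
    network = c("DMN", "DMN", "MDN"),
    rule = c("removed_scn_overlap", "removed_mdn_overlap", "removed_scn_overlap"),
    n_removed = c(
      length(sets$DMN) - length(dmn_minus_scn),
      length(dmn_minus_scn) - length(resolved$DMN),
      length(sets$MDN) - length(resolved$MDN)
    )
  )
  empty <- names(resolved)[vapply(resolved, length, integer(1)) == 0]
  if (length(empty) > 0) {
    abort_glocoh(sprintf("resolved mask is empty for network(s): %s",
                         paste(empty, collapse = ", ")),
                 "glocoh_empty_mask_error")
  }
  out_masks <- dplyr::bind_rows(lapply(need, function(nw) {
    tibble::tibble(network = nw, voxel = resolved[[nw]])
  }))
  list(masks = out_masks, audit = audit)
}

#' Select the top fraction of voxels by contrast value
#'
#' Returns the `ceiling(fraction * |mask|)` voxels in the mask with the
#' largest contrast values. Ties at the cutoff are broken by stable voxel-id
#' order, so the selection is deterministic.
#'
#' @param contrast Tibble with columns `voxel`, `value` (one participant's
#'   discourse-minus-baseline contrast for the relevant task).
#' @param mask Character vector of voxel ids.
#' @param fraction Fraction to keep, in (0, 1\] (default 0.2).
#' @return Character vector of selected voxel ids.
#' @export
select_top_voxels <- function(contrast, mask, fraction = 0.2) {
  require_columns(contrast, c("voxel", "value"), "contrast map")
  if (length(mask) == 0) {
    abort_glocoh("mask is empty.", "glocoh_input_error")
  }
  if (fraction <= 0 || fraction > 1) {
    abort_glocoh("`fraction` must be in (0, 1].", "glocoh_input_error")
  }
  inside <- contrast[contrast$voxel %in% mask, ]
  if (nrow(inside) < length(mask)) {
    abort_glocoh("contrast map does not cover every mask voxel.",
                 "glocoh_input_error")
  }
  n_keep <- ceiling(fraction * length(mask))
  ord <- order_by_value_then_voxel(inside$value, inside$voxel, decreasing = TRUE)
  inside$voxel[ord][seq_len(n_keep)]
}

#' Mean coherence effect per participant, task, and network
#'
#' For each cell, selects the top-responding voxels of the resolved network
#' mask on that participant's and task's discourse-minus-baseline contrast,
#' then averages the coherence betas over the selected voxels.
#'
#' @param betas Tibble of coherence-beta maps: columns `participant`, `task`,
#'   `voxel`, `value`.
#' @param contrasts Tibble of discourse-minus-baseline contrast maps with the
#'   same columns (used only for voxel selection).
#' @param masks Resolved masks tibble (`network`, `voxel`) from
#'   [resolve_networks()].
#' @param fraction Top fraction of voxels to keep per cell.
#' @return A tibble with one row per (participant, task, network):
#'   `mean_beta`, `n_selected_voxels`.
#' @export
network_effect_table <- function(betas, contrasts, masks, fraction = 0.2) {
  require_columns(betas, c("participant", "task", "voxel", "value"), "beta maps")
  require_columns(contrasts, c("participant", "task", "voxel", "value"),
                  "contrast maps")
  require_columns(masks, c("network", "voxel"), "resolved masks")
  cells <- dplyr::distinct(betas, .data$participant, .data$task)
  networks <- unique(masks$network)
  out <- purrr::pmap_dfr(cells, function(participant, task) {
    con <- contrasts[contrasts$participant == participant &
                       contrasts$task == task, c("voxel", "value")]
    bet <- betas[betas$participant == participant & betas$task == task, ]
    purrr::map_dfr(networks, function(nw) {
      mask <- masks$voxel[masks$network == nw]
      sel <- select_top_voxels(con, mask, fraction)
      tibble::tibble(
        participant = participant, task = task, network = nw,
        mean_beta = mean(bet$value[bet$voxel %in% sel]),
        n_selected_voxels = length(sel)
      )
    })
  })
  dplyr::arrange(out, .data$participant, .data$task, .data$network)
}

#' Repeated-measures ANOVA on the network effect table
#'
#' Two-way (task x network) repeated-measures ANOVA with participant as the
#' random blocking factor and within-participant error strata per effect
#' (plain degrees of freedom, no sphericity correction). Post hoc pairwise
#' network comparisons are paired t tests within each task, Holm-adjusted
#' within each task's family of three comparisons.
#'
#' @param table Balanced [network_effect_table()] output: every
#'   participant x task x network cell exactly once.
#' @param posthoc_by `"task"` (default: Holm family = the three network
#'   comparisons within each task) or `"all"` (one family of six).
#' @return A `network_anova` object with `$anova` (effect, df1, df2,
#'   statistic, p.value) and `$posthoc` tibbles.
#' @export
network_anova <- function(table, posthoc_by = c("task", "all")) {
  posthoc_by <- match.arg(posthoc_by)
  require_columns(table, c("participant", "task", "network", "mean_beta"),
                  "network effect table")
  counts <- dplyr::count(table, .data$participant, .data$task, .data$network)
  n_tasks <- length(unique(table$task))
  n_networks <- length(unique(table$network))
  n_participants <- length(unique(table$participant))
  if (any(counts$n != 1) ||
      nrow(counts) != n_tasks * n_networks * n_participants) {
    abort_glocoh("the effect table must be balanced and complete: one value per participant x task x network cell.",
                 "glocoh_input_error")
  }
  dat <- table |>
    dplyr::mutate(participant = factor(.data$participant),
                  task = factor(.data$task),
                  network = factor(.data$network))
  fit <- stats::aov(mean_beta ~ task * network +
                      Error(participant / (task * network)), data = dat)
  smry <- summary(fit)
  # Sums of squares this far below the data scale are floating-point residue
  # of an exactly-null effect; report F = 0, p = 1 rather than a 0/0 ratio.
  ss_floor <- 1e-12 * (sum(dat$mean_beta^2) + .Machine$double.xmin)
  extract_stratum <- function(effect) {
    for (stratum in smry) {
      tab <- stratum[[1]]
      rows <- trimws(rownames(tab))
      hit <- match(effect, rows)
      if (!is.na(hit) && "F value" %in% colnames(tab)) {
        fval <- tab[hit, "F value"]
        pval <- tab[hit, "Pr(>F)"]
        if (tab[hit, "Sum Sq"] < ss_floor) {
          fval <- 0
          pval <- 1
        }
        if (is.na(fval) || is.nan(fval)) {
          next
        }
        return(tibble::tibble(
          effect = effect,
          df1 = tab[hit, "Df"],
          df2 = tab[nrow(tab), "Df"],
          statistic = fval,
          p.value = pval
        ))
      }
    }
    abort_glocoh(sprintf("effect '%s' not found in the ANOVA table.", effect),
                 "glocoh_internal_error")
  }
  anova_tbl <- dplyr::bind_rows(
    extract_stratum("task"),
    extract_stratum("network"),
    extract_stratum("task:network")
  )
  posthoc <- posthoc_network_tests(dat, posthoc_by)
  structure(
    list(anova = anova_tbl, posthoc = posthoc, data = dat,
         n_participants = n_participants),
    class = "network_anova"
  )
}

posthoc_network_tests <- function(dat, posthoc_by) {
  networks <- levels(dat$network)
  pairs <- utils::combn(networks, 2, simplify = FALSE)
  raw <- purrr::map_dfr(levels(dat$task), function(tk) {
    purrr::map_dfr(pairs, function(pr) {
      a <- dat[dat$task == tk & dat$network == pr[1], ]
      b <- dat[dat$task == tk & dat$network == pr[2], ]
      a <- a[order(a$participant), ]
      b <- b[order(b$participant), ]
      d <- a$mean_beta - b$mean_beta
      if (stats::sd(d) < 1e-14 * max(1, mean(abs(d)))) {
        # constant differences: degenerate paired t
        tt <- list(estimate = mean(d),
                   statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                   parameter = length(d) - 1,
                   p.value = if (mean(d) == 0) 1 else 0)
      } else {
        tt <- stats::t.test(a$mean_beta, b$mean_beta, paired = TRUE)
      }
      tibble::tibble(
        task = tk,
        comparison = paste(pr, collapse = " - "),
        estimate = unname(tt$estimate),
        statistic = unname(tt$statistic),
        df = unname(tt$parameter),
        p.value = tt$p.value
      )
    })
  })
  if (posthoc_by == "task") {
    raw |>
      dplyr::group_by(.data$task) |>
      dplyr::mutate(p.adjusted = stats::p.adjust(.data$p.value, method = "holm")) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(raw, p.adjusted = stats::p.adjust(.data$p.value, method = "holm"))
  }
}

#' @export
print.network_anova <- function(x, ...) {
  cat(sprintf("<network_anova> 2 x 3 repeated-measures ANOVA, n = %d participants\n",
              x$n_participants))
  print(x$anova)
  cat("post hoc (Holm-adjusted):\n")
  print(x$posthoc)
  invisible(x)
}

#' @export
tidy.network_anova <- function(x, ...) {
  x$anova
}

#' @export
glance.network_anova <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    network_F = x$anova$statistic[x$anova$effect == "network"],
    network_p = x$anova$p.value[x$anova$effect == "network"],
    interaction_F = x$anova$statistic[x$anova$effect == "task:network"],
    interaction_p = x$anova$p.value[x$anova$effect == "task:network"]
  )
}

#' Plot the network effect table
#'
#' @param table A [network_effect_table()] tibble.
#' @return A ggplot object: per-participant points and cell means by network
#'   and task.
#' @export
plot_network_effects <- function(table) {
  require_columns(table, c("participant", "task", "network", "mean_beta"),
                  "network effect table")
  means <- table |>
    dplyr::group_by(.data$task, .data$network) |>
    dplyr::summarise(mean_beta = mean(.data$mean_beta), .groups = "drop")
  ggplot2::ggplot(table, ggplot2::aes(x = .data$network, y = .data$mean_beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = means, colour = "firebrick", size = 3) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = NULL, y = "mean coherence effect (beta)") +
    ggplot2::theme_minimal()
}

#' Individual-differences covariate analysis
#'
#' Regresses each voxel's activation (across participants) on the
#' mean-centered participant-level mean coherence, returning the slope, t
#' statistic, and uncorrected p per voxel, plus counts of suprathreshold
#' voxels in each direction at an uncorrected threshold.
#'
#' @param activation Tibble of per-participant voxel maps: `participant`,
#'   `voxel`, `value`.
#' @param covariate Tibble with `participant`, `mean_coherence` (nonconstant).
#' @param p_threshold Uncorrected two-sided threshold for the suprathreshold
#'   counts (default 0.001).
#' @return A tibble (`voxel`, `slope`, `statistic`, `p.value`) with
#'   attributes `n_positive`, `n_negative` (suprathreshold counts) and
#'   `p_threshold`.
#' @export
covariate_map <- function(activation, covariate, p_threshold = 0.001) {
  require_columns(activation, c("participant", "voxel", "value"), "activation maps")
  require_columns(covariate, c("participant", "mean_coherence"), "covariate")
  n <- nrow(covariate)
  if (n < 3) {
    abort_glocoh("need at least 3 participants.", "glocoh_input_error")
  }
  if (stats::sd(covariate$mean_coherence) == 0) {
    abort_glocoh("covariate is constant across participants.", "glocoh_input_error")
  }
  wide <- activation |>
    dplyr::select("participant", "voxel", "value") |>
    tidyr::pivot_wider(names_from = "voxel", values_from = "value")
  wide <- dplyr::inner_join(covariate, wide, by = "participant")
  if (nrow(wide) != n || anyNA(wide)) {
    abort_glocoh("every participant needs a complete activation map and covariate value.",
                 "glocoh_input_error")
  }
  x <- wide$mean_coherence - mean(wide$mean_coherence)
  Y <- as.matrix(wide[, setdiff(names(wide), c("participant", "mean_coherence"))])
  sxx <- sum(x^2)
  slope <- drop(crossprod(Y, x)) / sxx
  intercept <- colMeans(Y)
  fitted <- outer(x, slope) + matrix(intercept, nrow = n, ncol = ncol(Y),
                                     byrow = TRUE)
  rss <- colSums((Y - fitted)^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  tstat <- ifelse(se > 0, slope / se, sign(slope) * Inf)
  p <- 2 * stats::pt(-abs(tstat), df = df)
  out <- tibble::tibble(voxel = colnames(Y), slope = unname(slope),
                        statistic = unname(tstat), p.value = unname(p))
  attr(out, "p_threshold") <- p_threshold
  attr(out, "n_positive") <- sum(out$p.value < p_threshold & out$slope > 0)
  attr(out, "n_negative") <- sum(out$p.value < p_threshold & out$slope < 0)
  out
}
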