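mask_tbl <- function(dmn, scn, mdn) {
  dplyr::bind_rows(
    tibble::tibble(network = "DMN", voxel = dmn),
    tibble::tibble(network = "SCN", voxel = scn),
    tibble::tibble(network = "MDN", voxel = mdn)
  )
}

vx <- function(i) sprintf("v%03d", i)

test_that("mask resolution applies the exclusion rules exactly", {
  # disjoint masks pass through untouched with a zero audit
  disjoint <- mask_tbl(vx(1:4), vx(5:8), vx(9:12))
  res <- resolve_networks(disjoint)
  expect_equal(dplyr::arrange(res$masks, network, voxel),
               dplyr::arrange(disjoint, network, voxel))
  expect_true(all(res$audit$n_removed == 0))

  # SCN inside DMN: 10-voxel DMN sharing 4 with SCN keeps 6
  res2 <- resolve_networks(mask_tbl(vx(1:10), vx(7:10), vx(21:25)))
  expect_setequal(res2$masks$voxel[res2$masks$network == "DMN"], vx(1:6))
  expect_equal(res2$audit$n_removed[res2$audit$network == "DMN" &
                                      res2$audit$rule == "removed_scn_overlap"], 4)

  # three-way overlap: counts match the hand-drawn Venn
  # DMN = 1..10, SCN = 8..13, MDN = 5..9 and 14..16
  raw <- mask_tbl(vx(1:10), vx(8:13), vx(c(5:9, 14:16)))
  res3 <- resolve_networks(raw)
  expect_setequal(res3$masks$voxel[res3$masks$network == "SCN"], vx(8:13))
  # MDN loses 8, 9 to SCN -> {5,6,7,14,15,16}
  expect_setequal(res3$masks$voxel[res3$masks$network == "MDN"],
                  vx(c(5:7, 14:16)))
  # DMN loses 8,9,10 to SCN then 5,6,7 to raw MDN -> {1,2,3,4}
  expect_setequal(res3$masks$voxel[res3$masks$network == "DMN"], vx(1:4))
  audit <- res3$audit
  expect_equal(audit$n_removed[audit$network == "DMN"], c(3, 3))
  expect_equal(audit$n_removed[audit$network == "MDN"], 2)

  # idempotence
  res4 <- resolve_networks(res3$masks)
  expect_equal(dplyr::arrange(res4$masks, network, voxel),
               dplyr::arrange(res3$masks, network, voxel))
  expect_true(all(res4$audit$n_removed == 0))

  # emptying a network is an error naming it
  expect_error(resolve_networks(mask_tbl(vx(1:3), vx(1:5), vx(6:8))),
               "DMN", class = "glocoh_empty_mask_error")
})

test_that("top-voxel selection uses ceil counts and stable tie-breaking", {
  con <- tibble::tibble(voxel = vx(1:20), value = c(20:1))
  expect_equal(select_top_voxels(con, vx(1:10), 0.2), vx(1:2))
  # ceil(0.2 * 11) = 3
  expect_equal(length(select_top_voxels(con, vx(1:11), 0.2)), 3)
  # equal values: lowest voxel ids win, deterministically
  tied <- tibble::tibble(voxel = vx(1:10), value = 1)
  expect_equal(select_top_voxels(tied, vx(1:10), 0.2), vx(1:2))
  expect_equal(select_top_voxels(tied, vx(1:10), 0.2),
               select_top_voxels(tied, vx(1:10), 0.2))
  # fraction 1 keeps the whole mask
  expect_setequal(select_top_voxels(con, vx(3:7), 1), vx(3:7))
  expect_error(select_top_voxels(con, character(0)), class = "glocoh_input_error")
  expect_error(select_top_voxels(con, vx(1:5), 0), class = "glocoh_input_error")
  expect_error(select_top_voxels(con[1:3, ], vx(1:5)), class = "glocoh_input_error")
})

test_that("network effect table means the coherence betas over selected voxels", {
  masks <- mask_tbl(vx(1:5), vx(6:10), vx(11:15))
  cells <- tidyr::expand_grid(participant = c("p01", "p02"),
                              task = c("production", "comprehension"))
  betas <- tidyr::expand_grid(cells, voxel = vx(1:15))
  betas$value <- seq(0.01, 0.6, length.out = nrow(betas))
  contrasts <- dplyr::mutate(betas, value = rep(15:1, times = 4))
  tab <- network_effect_table(betas, contrasts, masks, fraction = 0.4)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$n_selected_voxels == 2))
  # contrast ranks voxels descending within each mask: picks the 2 lowest ids
  row <- tab[tab$participant == "p01" & tab$task == "production" &
               tab$network == "DMN", ]
  sel_vox <- vx(1:2)
  want <- mean(betas$value[betas$participant == "p01" &
                             betas$task == "production" &
                             betas$voxel %in% sel_vox])
  expect_equal(row$mean_beta, want)
  # fraction 1: plain mask mean
  tab_full <- network_effect_table(betas, contrasts, masks, fraction = 1)
  row_full <- tab_full[tab_full$participant == "p02" &
                         tab_full$task == "comprehension" &
                         tab_full$network == "MDN", ]
  expect_equal(row_full$mean_beta,
               mean(betas$value[betas$participant == "p02" &
                                  betas$task == "comprehension" &
                                  betas$voxel %in% vx(11:15)]))
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(17)
  tab <- tidyr::expand_grid(participant = sprintf("p%02d", 1:6),
                            task = c("production", "comprehension"),
                            network = c("DMN", "SCN", "MDN"))
  tab$mean_beta <- rnorm(nrow(tab), sd = 0.3)
  fit <- network_anova(tab)
  oracle <- oracle_rm_anova(tab)
  a <- fit$anova
  expect_equal(a$statistic[a$effect == "task"], oracle$F_task, tolerance = 1e-8)
  expect_equal(a$statistic[a$effect == "network"], oracle$F_network,
               tolerance = 1e-8)
  expect_equal(a$statistic[a$effect == "task:network"], oracle$F_interaction,
               tolerance = 1e-8)
  expect_equal(unname(unlist(a[a$effect == "network", c("df1", "df2")])),
               oracle$df$network)
  expect_equal(unname(unlist(a[a$effect == "task:network", c("df1", "df2")])),
               oracle$df$interaction)
})

test_that("degenerate ANOVA tables behave as the model dictates", {
  grid <- tidyr::expand_grid(participant = sprintf("p%02d", 1:5),
                             task = c("production", "comprehension"),
                             network = c("DMN", "SCN", "MDN"))
  # all equal: F = 0 everywhere
  flat <- dplyr::mutate(grid, mean_beta = 0.4)
  fit_flat <- network_anova(flat)
  expect_true(all(is.na(fit_flat$anova$statistic) |
                    fit_flat$anova$statistic < 1e-20))
  # additive task and network effects without noise: interaction F = 0
  add <- grid |>
    dplyr::mutate(mean_beta = 0.2 * (task == "production") +
                    c(DMN = -0.3, SCN = 0.1, MDN = 0.2)[network] +
                    0.05 * as.integer(factor(participant)))
  fit_add <- network_anova(add)
  int_F <- fit_add$anova$statistic[fit_add$anova$effect == "task:network"]
  expect_lt(abs(int_F), 1e-10)
  # unbalanced table: error, no imputation
  expect_error(network_anova(add[-1, ]), class = "glocoh_input_error")
})

test_that("network F is invariant to participant-specific constants", {
  set.seed(23)
  tab <- tidyr::expand_grid(participant = sprintf("p%02d", 1:8),
                            task = c("production", "comprehension"),
                            network = c("DMN", "SCN", "MDN"))
  tab$mean_beta <- rnorm(nrow(tab))
  shifted <- tab |>
    dplyr::group_by(participant) |>
    dplyr::mutate(mean_beta = mean_beta +
                    5 * as.integer(factor(participant))[1]) |>
    dplyr::ungroup()
  f1 <- network_anova(tab)$anova
  f2 <- network_anova(shifted)$anova
  expect_equal(f1$statistic[f1$effect == "network"],
               f2$statistic[f2$effect == "network"], tolerance = 1e-8)
})

test_that("Holm-adjusted post hoc tests follow the step-down rules", {
  set.seed(29)
  tab <- tidyr::expand_grid(participant = sprintf("p%02d", 1:10),
                            task = c("production", "comprehension"),
                            network = c("DMN", "SCN", "MDN"))
  tab$mean_beta <- rnorm(nrow(tab)) - 0.8 * (tab$network == "DMN")
  fit <- network_anova(tab)
  ph <- fit$posthoc
  expect_equal(nrow(ph), 6)
  for (tk in unique(ph$task)) {
    fam <- ph[ph$task == tk, ]
    m <- nrow(fam)
    # smallest raw p multiplied by m (capped at 1)
    expect_equal(min(fam$p.adjusted),
                 min(1, m * min(fam$p.value)), tolerance = 1e-12)
    # adjusted sequence nondecreasing in the raw-p ordering
    ord <- order(fam$p.value)
    expect_true(!is.unsorted(fam$p.adjusted[ord]))
    expect_true(all(fam$p.adjusted >= fam$p.value))
    # paired-t oracle for one comparison
    a <- tab$mean_beta[tab$task == tk & tab$network == "DMN"]
    b <- tab$mean_beta[tab$task == tk & tab$network == "MDN"]
    want <- t.test(a, b, paired = TRUE)
    got <- fam[fam$comparison == "DMN - MDN", ]
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  }
})

test_that("covariate map recovers exact slopes and calibrates false positives", {
  # exact linear activation: slope = c, zero residual
  cov <- tibble::tibble(participant = sprintf("p%02d", 1:6),
                        mean_coherence = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7))
  act <- tidyr::expand_grid(participant = cov$participant, voxel = vx(1:3))
  slopes <- c(2, -1, 0.5)
  act$value <- slopes[match(act$voxel, vx(1:3))] *
    cov$mean_coherence[match(act$participant, cov$participant)]
  cm <- covariate_map(act, cov)
  expect_equal(cm$slope, slopes, tolerance = 1e-10)

  # 4-participant hand table: closed-form least squares
  cov4 <- tibble::tibble(participant = sprintf("p%02d", 1:4),
                         mean_coherence = c(0.1, 0.2, 0.4, 0.9))
  act4 <- tibble::tibble(participant = cov4$participant, voxel = "v001",
                         value = c(1.0, 0.4, 0.8, 0.2))
  x <- cov4$mean_coherence - mean(cov4$mean_coherence)
  want_slope <- sum(x * act4$value) / sum(x^2)
  cm4 <- covariate_map(act4, cov4)
  expect_equal(cm4$slope, want_slope, tolerance = 1e-12)
  lm_fit <- lm(act4$value ~ x)
  expect_equal(cm4$statistic, unname(summary(lm_fit)$coefficients[2, 3]),
               tolerance = 1e-10)

  expect_error(covariate_map(act4[1:2, ], cov4[1:2, ]), class = "glocoh_input_error")
  expect_error(covariate_map(act4, dplyr::mutate(cov4, mean_coherence = 1)),
               class = "glocoh_input_error")
})

test_that("permuted covariates produce the nominal suprathreshold rate", {
  set.seed(37)
  n_part <- 20
  cov <- tibble::tibble(participant = sprintf("p%02d", 1:n_part),
                        mean_coherence = runif(n_part))
  counts <- numeric(50)
  for (i in seq_len(50)) {
    act <- tidyr::expand_grid(participant = cov$participant, voxel = vx(1:200))
    act$value <- rnorm(nrow(act))
    cm <- covariate_map(act, cov, p_threshold = 0.01)
    counts[i] <- attr(cm, "n_positive") + attr(cm, "n_negative")
  }
  # expected 0.01 * 200 = 2 suprathreshold voxels per run on average
  expect_lt(abs(mean(counts) - 2), 1)
})
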