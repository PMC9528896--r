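# End-to-end pipeline: simulate speech and BOLD, build the semantic space,
# score coherence, fit the first-level GLMs, then run the gradient and
# network analyses. Deterministic given the config seed; optional TSV/YAML
# outputs with an md5 manifest.

#' Pipeline configuration
#'
#' Builds and validates the configuration list consumed by
#' [run_pipeline()]. Unknown keys are rejected before any stage runs. The
#' analysis parameters default to the study conventions this package
#' implements: 20-word coherence windows, 5-s modulator blocks over a 50-s
#' speech period, TR 1.7 s, 128-s high-pass cutoff, 10 gradient bins, and
#' top-20% voxel selection.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # speech simulation
    n_participants = 8L,
    n_prompts = 4L,
    n_comprehension_prompts = 2L,
    n_reference = 30L,
    vocab_size = 600L,
    concentration = 0.02,
    docs_per_topic = 40L,
    words_per_doc = 120L,
    word_rate = 2.6,
    drift = 0.1,
    drift_ramp = 1.2,
    drift_heterogeneity = 0.5,
    comprehension_drift_high = 0.1,
    comprehension_drift_low = 0.45,
    # semantic space
    space_k = 100L,
    space_weighting = "log_entropy",
    window = 20L,
    clamp_negative = FALSE,
    # glm timing
    period = 50,
    bin_length = 5,
    TR = 1.7,
    hp_cutoff = 128,
    microtime = 0.1,
    prep_duration = 6,
    baseline_duration = 10,
    isi = 5,
    # imaging simulation
    n_voxels = 300L,
    noise_sd = 1,
    ar1_rho = 0,
    coherence_a = 0.5,
    coherence_b_lin = -1.5,
    coherence_b_quad = 0,
    time_slope = -0.2,
    # downstream analysis
    n_bins = 10L,
    fraction = 0.2,
    random = "intercept_slope",
    out_dir = NULL
  )
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort_glocoh("all configuration overrides must be named.", "glocoh_config_error")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort_glocoh(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")),
                 "glocoh_config_error")
  }
  config <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  stopifnot(config$n_participants >= 2, config$n_prompts >= 1,
            config$period > 0, config$bin_length > 0, config$TR > 0,
            config$fraction > 0, config$fraction <= 1)
  structure(config, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file of configuration overrides.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full coherence-to-topography pipeline
#'
#' Stages, in order: simulate the topic model, training corpus, production
#' cohort, comprehension passages and reference cohort; build the semantic
#' space; score coherence (leave-one-out prototypes for production, fixed
#' reference prototypes for comprehension) and bin it into 5-s modulators;
#' build one design per participant (a production run and a comprehension
#' run), simulate BOLD with known gradient-dependent coherence sensitivity,
#' and fit the voxelwise GLM; run the gradient topography analysis
#' (voxelwise correlations, decile bin table, mixed models per task) and the
#' network analysis (mask resolution, top-voxel selection, repeated-measures
#' ANOVA with Holm post hoc tests, individual-differences covariate map).
#'
#' The run is deterministic given the config: rerunning with an identical
#' config reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or list of overrides passed to it).
#' @return A `pipeline_result` list; see `summary()` for the headline
#'   numbers. When `config$out_dir` is set, result tables, the config, and an
#'   md5 manifest are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  cfg <- config
  seed <- as.integer(cfg$seed)

  # --- stage: simulate speech -------------------------------------------
  n_topics <- cfg$n_prompts + cfg$n_comprehension_prompts
  model <- make_topic_model(n_topics = max(2L, n_topics),
                            vocab_size = cfg$vocab_size,
                            concentration = cfg$concentration,
                            seed = seed)
  corpus <- generate_corpus(model, docs_per_topic = cfg$docs_per_topic,
                            words_per_doc = cfg$words_per_doc, seed = seed + 1L)
  cohort <- generate_cohort(model, n_participants = cfg$n_participants,
                            n_prompts = cfg$n_prompts,
                            heterogeneity = cfg$drift_heterogeneity,
                            drift = cfg$drift, drift_ramp = cfg$drift_ramp,
                            duration = cfg$period, word_rate = cfg$word_rate,
                            seed = seed + 2L)
  comp_topics <- cfg$n_prompts + seq_len(cfg$n_comprehension_prompts)
  reference <- purrr::map_dfr(comp_topics, function(t) {
    purrr::map_dfr(seq_len(cfg$n_reference), function(i) {
      generate_response(model, topic = t, duration = cfg$period,
                        word_rate = cfg$word_rate, drift = cfg$drift,
                        drift_ramp = cfg$drift_ramp,
                        seed = seed + 5000L + t * 200L + i,
                        participant = sprintf("ref%02d", i),
                        task = "production")
    })
  })
  # One high- and one low-coherence passage per comprehension topic, heard by
  # every participant.
  passages <- purrr::map_dfr(seq_along(comp_topics), function(j) {
    t <- comp_topics[j]
    dplyr::bind_rows(
      generate_response(model, topic = t, duration = cfg$period,
                        word_rate = cfg$word_rate,
                        drift = cfg$comprehension_drift_high, drift_ramp = 0.3,
                        seed = seed + 9000L + t,
                        participant = "passage_high",
                        prompt = sprintf("%s_high", rownames(model$topics)[t]),
                        task = "comprehension"),
      generate_response(model, topic = t, duration = cfg$period,
                        word_rate = cfg$word_rate,
                        drift = cfg$comprehension_drift_low, drift_ramp = 0.3,
                        seed = seed + 9100L + t,
                        participant = "passage_low",
                        prompt = sprintf("%s_low", rownames(model$topics)[t]),
                        task = "comprehension")
    )
  })

  # --- stage: semantic space --------------------------------------------
  space <- build_space(corpus, k = cfg$space_k, weighting = cfg$space_weighting)

  # --- stage: coherence scoring -----------------------------------------
  scored_prod <- score_transcripts(cohort$transcripts, space,
                                   mode = "leave_one_out",
                                   window = cfg$window,
                                   clamp_negative = cfg$clamp_negative)
  ref_for_passages <- dplyr::mutate(reference, prompt_base = .data$prompt)
  comp_reference <- dplyr::bind_rows(
    dplyr::mutate(ref_for_passages, prompt = paste0(.data$prompt_base, "_high")),
    dplyr::mutate(ref_for_passages, prompt = paste0(.data$prompt_base, "_low"))
  ) |> dplyr::select(-"prompt_base")
  scored_comp <- score_transcripts(passages, space,
                                   mode = "fixed_reference",
                                   reference = comp_reference,
                                   window = cfg$window,
                                   clamp_negative = cfg$clamp_negative)
  binned_prod <- bin_coherence(scored_prod, bin_length = cfg$bin_length,
                               period = cfg$period)
  binned_comp <- bin_coherence(scored_comp, bin_length = cfg$bin_length,
                               period = cfg$period)
  participant_coherence <- participant_mean_coherence(scored_prod)

  # --- stage: imaging simulation + GLM ----------------------------------
  maps <- make_gradient_and_masks(cfg$n_voxels, seed = seed + 3L)
  fits <- fit_participant_glms(cfg, binned_prod, binned_comp, maps, seed)

  # --- stage: topography -------------------------------------------------
  bins <- decile_bins(maps$gradient, n_bins = cfg$n_bins)
  coh_betas <- fits$coherence_betas
  group_maps <- coh_betas |>
    dplyr::group_by(.data$task, .data$voxel) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  topo <- purrr::map(split(group_maps, group_maps$task), function(gm) {
    list(
      whole_brain = gradient_correlation(gm[, c("voxel", "value")], maps$gradient),
      semantic = gradient_correlation(gm[, c("voxel", "value")], maps$gradient,
                                      mask = maps$semantic_mask)
    )
  })
  bin_table <- gradient_bin_means(coh_betas, bins)
  trend <- purrr::map(split(bin_table, bin_table$task), function(bt) {
    fit_gradient_trend(bt, quadratic = TRUE, random = cfg$random)
  })

  # --- stage: networks ---------------------------------------------------
  resolved <- resolve_networks(maps$masks)
  effect_table <- network_effect_table(coh_betas, fits$contrast_maps,
                                       resolved$masks, fraction = cfg$fraction)
  anova_fit <- network_anova(effect_table)
  idiff <- covariate_map(
    fits$contrast_maps |>
      dplyr::filter(.data$task == "production") |>
      dplyr::select("participant", "voxel", "value"),
    participant_coherence
  )

  result <- structure(
    list(
      config = cfg,
      model = model,
      space = space,
      transcripts = cohort$transcripts,
      speech_truth = cohort$truth,
      scored = list(production = scored_prod, comprehension = scored_comp),
      binned = list(production = binned_prod, comprehension = binned_comp),
      participant_coherence = participant_coherence,
      gradient = maps$gradient,
      masks = maps$masks,
      semantic_mask = maps$semantic_mask,
      imaging_truth = fits$truth,
      coherence_betas = coh_betas,
      contrast_maps = fits$contrast_maps,
      topography = list(correlations = topo, bin_table = bin_table,
                        trend = trend),
      networks = list(resolved = resolved, effect_table = effect_table,
                      anova = anova_fit),
      individual_differences = idiff
    ),
    class = "pipeline_result"
  )
  if (!is.null(cfg$out_dir)) {
    write_pipeline_result(result, cfg$out_dir)
  }
  result
}

# Build events/modulators, simulate BOLD, and fit the GLM for every
# participant. Production modulators are participant-specific; comprehension
# passages (hence modulators) are shared.
fit_participant_glms <- function(cfg, binned_prod, binned_comp, maps, seed) {
  participants <- sort(unique(binned_prod$participant))
  n_bins_period <- as.integer(round(cfg$period / cfg$bin_length))

  layout_run <- function(prompts, condition, baseline_condition, n_baseline) {
    onset <- cfg$isi
    events <- list()
    blocks <- list()
    for (p in prompts) {
      events[[length(events) + 1]] <- tibble::tibble(
        condition = paste0("preparation_", condition),
        onset = onset, duration = cfg$prep_duration)
      onset <- onset + cfg$prep_duration
      events[[length(events) + 1]] <- tibble::tibble(
        condition = condition, onset = onset, duration = cfg$period)
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        condition = condition, period = p, block = seq_len(n_bins_period),
        onset = onset + (seq_len(n_bins_period) - 1) * cfg$bin_length,
        duration = cfg$bin_length)
      onset <- onset + cfg$period + cfg$isi
    }
    for (b in seq_len(n_baseline)) {
      events[[length(events) + 1]] <- tibble::tibble(
        condition = baseline_condition, onset = onset,
        duration = cfg$baseline_duration)
      onset <- onset + cfg$baseline_duration + cfg$isi
    }
    list(events = dplyr::bind_rows(events), blocks = dplyr::bind_rows(blocks),
         duration = onset + 20)
  }

  comp_prompts <- sort(unique(binned_comp$prompt))
  prod_prompts <- sort(unique(binned_prod$prompt))
  run_prod <- layout_run(prod_prompts, "discourse_production",
                         "baseline_production", max(2L, length(prod_prompts) - 1L))
  run_comp <- layout_run(comp_prompts, "discourse_comprehension",
                         "baseline_comprehension", max(2L, length(comp_prompts) - 1L))
  n_volumes <- c(ceiling(run_prod$duration / cfg$TR),
                 ceiling(run_comp$duration / cfg$TR))
  events <- dplyr::bind_rows(
    dplyr::mutate(run_prod$events, run = 1L, .before = 1),
    dplyr::mutate(run_comp$events, run = 2L, .before = 1)
  )

  comp_mods <- run_comp$blocks |>
    dplyr::mutate(run = 2L, .before = 1) |>
    dplyr::left_join(
      dplyr::select(binned_comp, period = "prompt", "bin",
                    coherence = "mean_coherence"),
      by = c("period", "block" = "bin")
    )

  coherence_betas <- list()
  contrast_maps <- list()
  truth <- NULL
  for (i in seq_along(participants)) {
    pp <- participants[i]
    prod_mods <- run_prod$blocks |>
      dplyr::mutate(run = 1L, .before = 1) |>
      dplyr::left_join(
        binned_prod |>
          dplyr::filter(.data$participant == pp) |>
          dplyr::select(period = "prompt", "bin", coherence = "mean_coherence"),
        by = c("period", "block" = "bin")
      )
    design <- build_design(events, dplyr::bind_rows(prod_mods, comp_mods),
                           n_volumes = n_volumes, TR = cfg$TR,
                           hp_cutoff = cfg$hp_cutoff, microtime = cfg$microtime)
    if (is.null(truth)) {
      truth <- make_truth(
        design, maps$gradient,
        coherence_params = c(a = cfg$coherence_a, b_lin = cfg$coherence_b_lin,
                             b_quad = cfg$coherence_b_quad),
        time_slope = cfg$time_slope, seed = seed + 4L
      )
    } else if (!identical(colnames(truth$B), colnames(design$X))) {
      abort_glocoh("participant designs have inconsistent columns.",
                   "glocoh_internal_error")
    }
    Y <- simulate_bold(design, truth, noise_sd = cfg$noise_sd,
                       ar1_rho = cfg$ar1_rho, seed = seed + 100L + i)
    fit <- fit_glm(Y, design)
    for (task in c("production", "comprehension")) {
      cond <- paste0("discourse_", task)
      coherence_betas[[length(coherence_betas) + 1]] <-
        beta_map(fit, paste0(cond, "_coherence")) |>
        dplyr::mutate(participant = pp, task = task, .before = 1)
      contrast_maps[[length(contrast_maps) + 1]] <-
        contrast_map(fit, stats::setNames(c(1, -1),
                                          c(cond, paste0("baseline_", task)))) |>
        dplyr::mutate(participant = pp, task = task, .before = 1)
    }
  }
  list(
    coherence_betas = dplyr::bind_rows(coherence_betas),
    contrast_maps = dplyr::bind_rows(contrast_maps),
    truth = truth
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d participants, %d voxels, seed %d\n",
              x$config$n_participants, nrow(x$gradient), x$config$seed))
  invisible(x)
}

#' Summarize a pipeline run
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A list of headline tibbles: gradient correlations per task, fixed
#'   effects of the gradient mixed models, the network ANOVA table, network
#'   cell means alongside the simulated-truth means, and the
#'   individual-differences suprathreshold counts. Printed compactly.
#' @export
summary.pipeline_result <- function(object, ...) {
  x <- object
  grad <- purrr::imap_dfr(x$topography$correlations, function(g, task) {
    dplyr::bind_rows(
      dplyr::mutate(g$whole_brain, task = task, scope = "whole_brain", .before = 1),
      dplyr::mutate(g$semantic, task = task, scope = "semantic_mask", .before = 1)
    )
  })
  trend <- purrr::imap_dfr(x$topography$trend, function(tr, task) {
    dplyr::mutate(tidy(tr), task = task, .before = 1)
  })
  truth_by_network <- x$networks$resolved$masks |>
    dplyr::left_join(x$imaging_truth$coherence_beta, by = "voxel") |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(true_mean_beta = mean(.data$value), .groups = "drop")
  network_means <- x$networks$effect_table |>
    dplyr::group_by(.data$task, .data$network) |>
    dplyr::summarise(mean_beta = mean(.data$mean_beta), .groups = "drop") |>
    dplyr::left_join(truth_by_network, by = "network")
  out <- list(
    gradient_correlations = grad,
    gradient_trend = trend,
    network_anova = x$networks$anova$anova,
    network_means = network_means,
    posthoc = x$networks$anova$posthoc,
    individual_differences = tibble::tibble(
      n_positive = attr(x$individual_differences, "n_positive"),
      n_negative = attr(x$individual_differences, "n_negative"),
      p_threshold = attr(x$individual_differences, "p_threshold")
    )
  )
  class(out) <- "summary.pipeline_result"
  out
}

#' @export
print.summary.pipeline_result <- function(x, ...) {
  cat("Gradient correlations (group-mean coherence betas vs gradient):\n")
  print(x$gradient_correlations)
  cat("\nGradient mixed-model fixed effects (centered bin index):\n")
  print(x$gradient_trend)
  cat("\nNetwork repeated-measures ANOVA:\n")
  print(x$network_anova)
  cat("\nNetwork cell means vs simulated truth:\n")
  print(x$network_means)
  cat("\nIndividual differences (suprathreshold voxels):\n")
  print(x$individual_differences)
  invisible(x)
}

# Write result tables, the config, and an md5 manifest.
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    transcripts = "transcripts.tsv",
    participant_coherence = "participant_coherence.tsv",
    gradient = "gradient.tsv",
    coherence_betas = "coherence_betas.tsv",
    bin_table = "gradient_bin_table.tsv",
    effect_table = "network_effect_table.tsv",
    anova = "network_anova.tsv",
    individual_differences = "individual_differences.tsv"
  )
  readr::write_tsv(result$transcripts, file.path(out_dir, paths$transcripts))
  readr::write_tsv(result$participant_coherence,
                   file.path(out_dir, paths$participant_coherence))
  readr::write_tsv(result$gradient, file.path(out_dir, paths$gradient))
  readr::write_tsv(result$coherence_betas, file.path(out_dir, paths$coherence_betas))
  readr::write_tsv(result$topography$bin_table, file.path(out_dir, paths$bin_table))
  readr::write_tsv(result$networks$effect_table,
                   file.path(out_dir, paths$effect_table))
  readr::write_tsv(result$networks$anova$anova, file.path(out_dir, paths$anova))
  readr::write_tsv(result$individual_differences,
                   file.path(out_dir, paths$individual_differences))
  cfg <- result$config
  cfg_list <- unclass(cfg)
  cfg_list$out_dir <- NULL
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  files <- c(unlist(paths, use.names = FALSE), "config.yaml")
  manifest <- list(
    package_version = as.character(utils::packageVersion("glocoh")),
    seed = cfg$seed,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
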