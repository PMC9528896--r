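# Global coherence of timed transcripts: whole-response vectors, leave-one-out
# or fixed-reference prototype vectors, 20-word moving-window cosines, and
# 5-s bin aggregation for the fMRI modulators.

validate_transcripts <- function(transcripts, period = NULL) {
  require_columns(transcripts,
                  c("participant", "prompt", "task", "token", "onset_s"),
                  "transcript table")
  grouped <- dplyr::group_by(transcripts, .data$participant, .data$prompt, .data$task)
  bad <- dplyr::summarise(grouped,
                          nondecreasing = !is.unsorted(.data$onset_s),
                          .groups = "drop")
  if (any(!bad$nondecreasing)) {
    abort_glocoh("onsets must be nondecreasing within each response.",
                 "glocoh_input_error")
  }
  if (any(transcripts$onset_s < 0)) {
    abort_glocoh("onsets must be nonnegative.", "glocoh_input_error")
  }
  if (!is.null(period) && any(transcripts$onset_s >= period)) {
    abort_glocoh(sprintf("onsets must fall within [0, %g) seconds.", period),
                 "glocoh_input_error")
  }
  invisible(transcripts)
}

#' Build prototype (composite) vectors for each prompt
#'
#' A prototype is the semantic representation of a typical response to a
#' prompt: the unweighted mean of whole-response vectors. In `leave_one_out`
#' mode (used for produced speech) the prototype for each target response
#' averages all *other* responses to the same prompt, so a response is never
#' compared with itself. In `fixed_reference` mode the prototypes are averages
#' over an external reference set of responses (used for comprehension
#' passages scored against a reference cohort).
#'
#' @param transcripts Transcript tibble with columns `participant`, `prompt`,
#'   `task`, `token`, `onset_s`. One response per (participant, prompt).
#' @param space A [build_space()] semantic space.
#' @param mode `"leave_one_out"` or `"fixed_reference"`.
#' @param reference For `fixed_reference`, the transcript tibble of the
#'   reference cohort.
#' @return A tibble with one row per prototype: columns `prompt`,
#'   `participant` (leave-one-out only; `NA` for fixed reference), and a
#'   list-column `prototype` of k-vectors.
#' @export
build_prototypes <- function(transcripts, space,
                             mode = c("leave_one_out", "fixed_reference"),
                             reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(space, "semantic_space"))
  if (mode == "fixed_reference") {
    if (is.null(reference)) {
      abort_glocoh("`reference` transcripts are required in fixed_reference mode.",
                   "glocoh_input_error")
    }
    validate_transcripts(reference)
    vecs <- response_vectors(reference, space)
    out <- vecs |>
      dplyr::group_by(.data$prompt) |>
      dplyr::summarise(prototype = list(colMeans(do.call(rbind, .data$vector))),
                       .groups = "drop") |>
      dplyr::mutate(participant = NA_character_, .after = "prompt")
    return(out)
  }
  validate_transcripts(transcripts)
  vecs <- response_vectors(transcripts, space)
  counts <- dplyr::count(vecs, .data$prompt)
  thin <- counts$prompt[counts$n < 2]
  if (length(thin) > 0) {
    abort_glocoh(
      sprintf("leave_one_out mode needs >= 2 responses per prompt; prompt(s) with fewer: %s",
              paste(thin, collapse = ", ")),
      "glocoh_input_error"
    )
  }
  vecs |>
    dplyr::group_by(.data$prompt) |>
    dplyr::group_modify(function(df, key) {
      mat <- do.call(rbind, df$vector)
      n <- nrow(mat)
      tibble::tibble(
        participant = df$participant,
        # direct mean over the other rows: exact for n = 2 (the prototype is
        # the other response's vector, bit for bit)
        prototype = lapply(seq_len(n),
                           function(i) colMeans(mat[-i, , drop = FALSE]))
      )
    }) |>
    dplyr::ungroup()
}

# One whole-response vector per (participant, prompt): the mean of all
# in-vocabulary token vectors of that response.
response_vectors <- function(transcripts, space) {
  transcripts |>
    dplyr::group_by(.data$participant, .data$prompt) |>
    dplyr::summarise(vector = list(strip_attrs(combine_tokens(space, .data$token))),
                     .groups = "drop")
}

strip_attrs <- function(x) {
  attributes(x) <- NULL
  x
}

#' Moving-window coherence of one token sequence
#'
#' For each token index `i >= window`, the coherence value is the cosine
#' between the mean vector of the window containing the current word and the
#' `window - 1` words preceding it, and the prototype vector. Earlier indices
#' carry no value (`NA`): no growing-window variant is used. A window whose
#' tokens are all out of vocabulary yields `NA` with a warning.
#'
#' @param tokens Character vector of tokens in production order.
#' @param prototype k-vector prototype (nonzero).
#' @param space A semantic space.
#' @param window Window length in words (default 20, the current word plus the
#'   19 preceding it).
#' @param clamp_negative If `TRUE`, negative cosines are floored at 0. Off by
#'   default: the raw cosine in \[-1, 1\] preserves information (the often
#'   quoted 0-to-1 range of text cosines is an empirical, not mathematical,
#'   property).
#' @return Numeric vector of length `length(tokens)`; entries before the first
#'   full window are `NA`.
#' @export
window_coherence <- function(tokens, prototype, space, window = 20,
                             clamp_negative = FALSE) {
  stopifnot(inherits(space, "semantic_space"))
  prototype <- as.numeric(prototype)
  if (sqrt(sum(prototype^2)) == 0) {
    abort_glocoh("prototype vector must be nonzero.", "glocoh_zero_norm_error")
  }
  n <- length(tokens)
  out <- rep(NA_real_, n)
  if (n < window) {
    return(out)
  }
  idx <- match(tokens, space$vocabulary)
  n_all_oov <- 0L
  for (i in window:n) {
    widx <- idx[(i - window + 1):i]
    widx <- widx[!is.na(widx)]
    if (length(widx) == 0) {
      n_all_oov <- n_all_oov + 1L
      next
    }
    wvec <- colMeans(space$vectors[widx, , drop = FALSE])
    if (sum(wvec^2) == 0) {
      n_all_oov <- n_all_oov + 1L
      next
    }
    out[i] <- cosine(wvec, prototype)
  }
  if (n_all_oov > 0) {
    rlang::warn(sprintf("%d window(s) had no usable in-vocabulary tokens; values set to NA.",
                        n_all_oov),
                class = "glocoh_oov_window_warning")
  }
  if (clamp_negative) {
    out <- pmax(out, 0)
  }
  out
}

#' Score every response of a transcript table
#'
#' High-level wrapper: builds (or accepts) prototypes and computes the
#' per-word moving-window coherence for each response.
#'
#' @inheritParams build_prototypes
#' @inheritParams window_coherence
#' @param prototypes Optional prototype tibble from [build_prototypes()];
#'   built internally when `NULL`.
#' @return The transcript tibble with `word_index` and `coherence` columns
#'   added (per-word coherence; `NA` before the first full window).
#' @export
score_transcripts <- function(transcripts, space,
                              mode = c("leave_one_out", "fixed_reference"),
                              reference = NULL, prototypes = NULL,
                              window = 20, clamp_negative = FALSE) {
  mode <- match.arg(mode)
  validate_transcripts(transcripts)
  if (is.null(prototypes)) {
    prototypes <- build_prototypes(transcripts, space, mode = mode,
                                   reference = reference)
  }
  by_response <- transcripts |>
    dplyr::group_by(.data$participant, .data$prompt, .data$task) |>
    dplyr::mutate(word_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::nest(.by = c("participant", "prompt", "task"))
  lookup_prototype <- function(participant, prompt) {
    if (mode == "leave_one_out") {
      hit <- prototypes$prompt == prompt & prototypes$participant == participant
    } else {
      hit <- prototypes$prompt == prompt
    }
    if (sum(hit) != 1) {
      abort_glocoh(sprintf("no unique prototype for prompt '%s'%s.", prompt,
                           if (mode == "leave_one_out")
                             sprintf(" / participant '%s'", participant) else ""),
                   "glocoh_input_error")
    }
    prototypes$prototype[[which(hit)]]
  }
  by_response$data <- purrr::pmap(
    list(by_response$participant, by_response$prompt, by_response$data),
    function(participant, prompt, df) {
      proto <- lookup_prototype(participant, prompt)
      df$coherence <- window_coherence(df$token, proto, space,
                                       window = window,
                                       clamp_negative = clamp_negative)
      df
    }
  )
  tidyr::unnest(by_response, "data")
}

#' Aggregate per-word coherence into fixed-length time bins
#'
#' Divides each speech period into `period / bin_length` bins (10 bins of 5 s
#' under the defaults) and averages the scored words whose onset falls in each
#' half-open interval `[b * bin_length, (b + 1) * bin_length)`. A bin with no
#' scored words is flagged missing (`NA` mean, `n_words = 0`), never silently
#' zero.
#'
#' @param scored Output of [score_transcripts()] (needs `coherence` and
#'   `onset_s`).
#' @param bin_length Bin length in seconds.
#' @param period Speech-period length in seconds.
#' @return A tibble with one row per (participant, prompt, task, bin):
#'   `bin` (1-based), `mean_coherence` (`NA` when missing), `n_words`.
#' @export
bin_coherence <- function(scored, bin_length = 5, period = 50) {
  require_columns(scored, c("participant", "prompt", "task", "onset_s", "coherence"),
                  "scored transcript table")
  validate_transcripts(scored, period = period)
  n_bins <- as.integer(round(period / bin_length))
  scored |>
    dplyr::filter(!is.na(.data$coherence)) |>
    dplyr::mutate(bin = pmin(floor(.data$onset_s / bin_length) + 1L, n_bins)) |>
    dplyr::group_by(.data$participant, .data$prompt, .data$task, .data$bin) |>
    dplyr::summarise(mean_coherence = mean(.data$coherence),
                     n_words = dplyr::n(), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("participant"), !!rlang::sym("prompt"),
                     !!rlang::sym("task")),
      bin = seq_len(n_bins),
      fill = list(mean_coherence = NA_real_, n_words = 0L)
    ) |>
    dplyr::arrange(.data$participant, .data$prompt, .data$task, .data$bin)
}

#' Response- and participant-level mean coherence
#'
#' `response_mean_coherence()` averages the defined per-word values of each
#' response; `participant_mean_coherence()` then averages the response means
#' per participant (unweighted, so short and long responses count equally).
#' The participant mean is the covariate used in the individual-differences
#' analysis.
#'
#' @param scored Output of [score_transcripts()].
#' @return A tibble of means keyed by response or participant.
#' @export
response_mean_coherence <- function(scored) {
  require_columns(scored, c("participant", "prompt", "task", "coherence"),
                  "scored transcript table")
  out <- scored |>
    dplyr::group_by(.data$participant, .data$prompt, .data$task) |>
    dplyr::summarise(
      mean_coherence = mean(.data$coherence[!is.na(.data$coherence)]),
      n_scored = sum(!is.na(.data$coherence)),
      .groups = "drop"
    )
  if (any(out$n_scored == 0)) {
    abort_glocoh("a response has no defined per-word coherence values.",
                 "glocoh_input_error")
  }
  out
}

#' @rdname response_mean_coherence
#' @export
participant_mean_coherence <- function(scored) {
  response_mean_coherence(scored) |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(mean_coherence = mean(.data$mean_coherence),
                     n_responses = dplyr::n(), .groups = "drop")
}

#' Read and write timed transcripts
#'
#' TSV dialect with columns `participant`, `prompt`, `task`, `token`,
#' `onset_s`.
#'
#' @param path File path.
#' @param transcripts Transcript tibble.
#' @return `read_transcripts()` returns the tibble; `write_transcripts()`
#'   returns `path` invisibly.
#' @export
read_transcripts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant = readr::col_character(),
                           prompt = readr::col_character(),
                           task = readr::col_character(),
                           token = readr::col_character(),
                           onset_s = readr::col_double()
                         ))
  validate_transcripts(out)
  out
}

#' @rdname read_transcripts
#' @export
write_transcripts <- function(transcripts, path) {
  validate_transcripts(transcripts)
  readr::write_tsv(transcripts, path)
  invisible(path)
}
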