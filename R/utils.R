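# Internal helpers shared across modules.

abort_glocoh <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "glocoh_error"), ...)
}

#' Tokenize text the way the coherence pipeline expects
#'
#' Lowercases, strips punctuation, and splits on whitespace. No stemming and
#' no stop-word removal: the simplest reproducible convention.
#'
#' @param text Character vector; each element is tokenized separately.
#' @return A list of character vectors (one per input element).
#' @export
#' @examples
#' tokenize("First, boil the kettle.")
tokenize <- function(text) {
  cleaned <- stringr::str_to_lower(text)
  cleaned <- stringr::str_replace_all(cleaned, "[^a-z0-9\\s]", " ")
  toks <- stringr::str_split(stringr::str_trim(cleaned), "\\s+")
  lapply(toks, function(x) x[nzchar(x)])
}

# Coerce a corpus argument (character vector of documents, or a list of
# already-tokenized character vectors) into a list of token vectors.
as_token_list <- function(corpus) {
  if (is.character(corpus)) {
    tokenize(corpus)
  } else if (is.list(corpus) && all(vapply(corpus, is.character, logical(1)))) {
    corpus
  } else {
    abort_glocoh("`corpus` must be a character vector of documents or a list of token vectors.",
                 "glocoh_input_error")
  }
}

# Stable ordering used wherever ties must be broken by voxel id.
order_by_value_then_voxel <- function(value, voxel, decreasing = FALSE) {
  if (decreasing) {
    order(-xtfrm(value), xtfrm(voxel))
  } else {
    order(xtfrm(value), xtfrm(voxel))
  }
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_glocoh(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "glocoh_input_error"
    )
  }
  invisible(df)
}
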