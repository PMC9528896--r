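# Latent semantic analysis space: weighted term-document matrix -> truncated
# SVD -> word vectors. Words are rows; a passage is the mean of its word
# vectors; similarity is the cosine.

#' Build a latent semantic analysis space from a training corpus
#'
#' Constructs a term-document count matrix, applies the requested term
#' weighting, and takes a rank-`k` truncated singular value decomposition.
#' Word vectors are the left singular vectors scaled by the singular values,
#' i.e. term coordinates in the `k`-dimensional latent space.
#'
#' The SVD sign ambiguity is resolved by forcing the largest-magnitude element
#' of each right singular vector to be positive, so two builds from identical
#' inputs produce identical stored vectors (cosines are sign-invariant either
#' way).
#'
#' @param corpus A character vector of documents (tokenized internally with
#'   [tokenize()]) or a list of token vectors.
#' @param k Dimensionality of the space. Must not exceed the rank of the
#'   weighted term-document matrix.
#' @param weighting `"log_entropy"` (log term frequency times an entropy-based
#'   global weight, standard LSA practice) or `"raw"` counts.
#' @return A `semantic_space` object: list with `vocabulary` (sorted unique
#'   tokens), `vectors` (|V| x k matrix, rownames = vocabulary), `k`,
#'   `weighting`, `singular_values`, and `n_documents`.
#' @export
#' @examples
#' sp <- build_space(c("tea kettle water", "dog park walk"), k = 2, weighting = "raw")
#' cosine(word_vector(sp, "tea"), word_vector(sp, "dog"))
build_space <- function(corpus, k = 100, weighting = c("log_entropy", "raw")) {
  weighting <- match.arg(weighting)
  docs <- as_token_list(corpus)
  if (length(docs) == 0) {
    abort_glocoh("`corpus` is empty.", "glocoh_input_error")
  }
  if (any(vapply(docs, length, integer(1)) == 0)) {
    abort_glocoh("every document must contain at least one token after tokenization.",
                 "glocoh_input_error")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort_glocoh("`k` must be a positive integer.", "glocoh_input_error")
  }
  vocab <- sort(unique(unlist(docs)))
  counts <- vapply(
    docs,
    function(d) tabulate(factor(d, levels = vocab), nbins = length(vocab)),
    numeric(length(vocab))
  )
  counts <- matrix(counts, nrow = length(vocab),
                   dimnames = list(vocab, NULL))
  weighted <- weight_term_matrix(counts, weighting)
  sv <- svd(weighted)
  tol <- max(dim(weighted)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (k > rank) {
    abort_glocoh(
      sprintf("k = %d exceeds the rank of the weighted term-document matrix; the attainable maximum is %d.",
              k, rank),
      "glocoh_rank_error"
    )
  }
  # Deterministic sign convention: largest-magnitude element of each right
  # singular vector is positive.
  for (j in seq_len(k)) {
    pivot <- which.max(abs(sv$v[, j]))
    if (sv$v[pivot, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  vectors <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(vectors) <- vocab
  colnames(vectors) <- paste0("dim", seq_len(k))
  stopifnot(all(is.finite(vectors)))
  structure(
    list(
      vocabulary = vocab,
      vectors = vectors,
      k = as.integer(k),
      weighting = weighting,
      singular_values = sv$d[seq_len(k)],
      n_documents = length(docs)
    ),
    class = "semantic_space"
  )
}

# Term weighting applied before the SVD. Log-entropy: local weight
# log2(1 + tf), global weight 1 + sum_j p_ij log2(p_ij) / log2(n_docs) with
# p_ij = tf_ij / gf_i.
weight_term_matrix <- function(counts, weighting) {
  if (weighting == "raw") {
    return(counts)
  }
  local <- log2(1 + counts)
  gf <- rowSums(counts)
  p <- counts / gf
  plogp <- ifelse(p > 0, p * log2(p), 0)
  n_docs <- ncol(counts)
  if (n_docs > 1) {
    global <- 1 + rowSums(plogp) / log2(n_docs)
  } else {
    global <- rep(1, nrow(counts))
  }
  local * global
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf(
    "<semantic_space> %d terms, k = %d, weighting = %s, built from %d documents\n",
    length(x$vocabulary), x$k, x$weighting, x$n_documents
  ))
  invisible(x)
}

#' Look up the vector for a single token
#'
#' @param space A `semantic_space`.
#' @param token A single token string.
#' @return The token's k-vector. Out-of-vocabulary tokens are an error, never
#'   a silent zero row.
#' @export
word_vector <- function(space, token) {
  stopifnot(inherits(space, "semantic_space"))
  idx <- match(token, space$vocabulary)
  if (is.na(idx)) {
    abort_glocoh(sprintf("token '%s' is not in the vocabulary.", token),
                 "glocoh_oov_error")
  }
  space$vectors[idx, ]
}

#' Combine tokens into one passage vector
#'
#' The unweighted mean of the in-vocabulary token vectors. Out-of-vocabulary
#' tokens are skipped; the number skipped is attached as the `n_skipped`
#' attribute.
#'
#' @param space A `semantic_space`.
#' @param tokens Character vector of tokens.
#' @return A k-vector with attribute `n_skipped`. If every token is out of
#'   vocabulary an error of class `glocoh_oov_error` is signalled (so callers
#'   can distinguish vocabulary failure from numerical failure).
#' @export
combine_tokens <- function(space, tokens) {
  stopifnot(inherits(space, "semantic_space"))
  idx <- match(tokens, space$vocabulary)
  in_vocab <- !is.na(idx)
  if (!any(in_vocab)) {
    abort_glocoh("all tokens are out of vocabulary; cannot form a passage vector.",
                 "glocoh_oov_error")
  }
  v <- colMeans(space$vectors[idx[in_vocab], , drop = FALSE])
  attr(v, "n_skipped") <- sum(!in_vocab)
  v
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length with nonzero norm.
#' @return The cosine, in \[-1, 1\]. Zero-norm input is an error of class
#'   `glocoh_zero_norm_error`, never NaN.
#' @export
cosine <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort_glocoh("cosine is undefined for a zero-norm vector.",
                 "glocoh_zero_norm_error")
  }
  sum(u * v) / (nu * nv)
}

#' Serialize a semantic space to plain-text files
#'
#' Writes three files under a common prefix: `<prefix>_vocab.txt` (one token
#' per line), `<prefix>_vectors.tsv` (dense matrix, one row per token, full
#' double precision), and `<prefix>_meta.yaml` (k, weighting, singular values,
#' document count). The round trip through [read_space()] is lossless.
#'
#' @param space A `semantic_space`.
#' @param prefix Path prefix for the three files.
#' @return `prefix`, invisibly.
#' @export
write_space <- function(space, prefix) {
  stopifnot(inherits(space, "semantic_space"))
  writeLines(space$vocabulary, paste0(prefix, "_vocab.txt"))
  # %.17g guarantees a lossless double round trip.
  formatted <- apply(space$vectors, 2, function(col) sprintf("%.17g", col))
  lines <- c(paste(colnames(space$vectors), collapse = "\t"),
             apply(formatted, 1, paste, collapse = "\t"))
  writeLines(lines, paste0(prefix, "_vectors.tsv"))
  yaml::write_yaml(
    list(
      k = space$k,
      weighting = space$weighting,
      n_documents = space$n_documents,
      singular_values = format(space$singular_values, digits = 17)
    ),
    paste0(prefix, "_meta.yaml")
  )
  invisible(prefix)
}

#' @rdname write_space
#' @export
read_space <- function(prefix) {
  vocab <- readLines(paste0(prefix, "_vocab.txt"))
  # base strtod parsing is bit-exact for %.17g output
  vectors <- as.matrix(utils::read.delim(paste0(prefix, "_vectors.tsv"),
                                         sep = "\t", check.names = FALSE))
  rownames(vectors) <- vocab
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  structure(
    list(
      vocabulary = vocab,
      vectors = vectors,
      k = as.integer(meta$k),
      weighting = meta$weighting,
      singular_values = as.numeric(meta$singular_values),
      n_documents = as.integer(meta$n_documents)
    ),
    class = "semantic_space"
  )
}

#' Read a training corpus from disk
#'
#' Accepts either a UTF-8 text file with one document per line, or a directory
#' of `.txt` files (one document per file).
#'
#' @param path File or directory path.
#' @return Character vector of documents.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0) {
      abort_glocoh(sprintf("no .txt files found in '%s'.", path), "glocoh_input_error")
    }
    vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = " "),
           character(1), USE.NAMES = FALSE)
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines[nzchar(trimws(lines))]
  } else {
    abort_glocoh(sprintf("corpus path '%s' does not exist.", path), "glocoh_input_error")
  }
}
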