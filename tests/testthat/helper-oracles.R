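# Independent oracles and hand-built fixtures. These deliberately avoid the
# package's own code paths: cosines and window means are recomputed with
# explicit loops, ANOVA F statistics from raw sums of squares.

# Construct a semantic_space object directly from a known vector matrix, so
# hand arithmetic on the vectors is possible.
manual_space <- function(vectors) {
  stopifnot(!is.null(rownames(vectors)))
  structure(
    list(
      vocabulary = rownames(vectors),
      vectors = vectors,
      k = ncol(vectors),
      weighting = "raw",
      singular_values = rep(1, ncol(vectors)),
      n_documents = nrow(vectors)
    ),
    class = "semantic_space"
  )
}

# A k = 3 toy space with simple integer-valued vectors.
toy_space3 <- function() {
  m <- rbind(
    aa = c(1, 0, 0),
    bb = c(0, 1, 0),
    cc = c(0, 0, 1),
    dd = c(1, 1, 0),
    ee = c(1, 1, 1),
    ff = c(2, 0, 1)
  )
  colnames(m) <- paste0("dim", 1:3)
  manual_space(m)
}

oracle_cosine <- function(u, v) {
  num <- 0
  su <- 0
  sv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    su <- su + u[i]^2
    sv <- sv + v[i]^2
  }
  num / (sqrt(su) * sqrt(sv))
}

# Brute-force mean-then-cosine moving-window coherence, written as plain
# loops over an explicit vocabulary lookup.
oracle_window_coherence <- function(tokens, prototype, space, window = 20) {
  n <- length(tokens)
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  for (i in window:n) {
    acc <- rep(0, space$k)
    cnt <- 0
    for (j in (i - window + 1):i) {
      hit <- which(space$vocabulary == tokens[j])
      if (length(hit) == 1) {
        acc <- acc + space$vectors[hit, ]
        cnt <- cnt + 1
      }
    }
    if (cnt == 0) next
    wv <- acc / cnt
    if (sum(wv^2) == 0) next
    out[i] <- oracle_cosine(wv, as.numeric(prototype))
  }
  out
}

# Independent two-way repeated-measures ANOVA from raw sums of squares.
# table: participant, task (a levels), network (b levels), mean_beta.
oracle_rm_anova <- function(table) {
  y <- table$mean_beta
  s <- factor(table$participant)
  a <- factor(table$task)
  b <- factor(table$network)
  n <- nlevels(s); p <- nlevels(a); q <- nlevels(b)
  grand <- mean(y)
  m_a <- tapply(y, a, mean)
  m_b <- tapply(y, b, mean)
  m_s <- tapply(y, s, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)
  ss_a <- n * q * sum((m_a - grand)^2)
  ss_b <- n * p * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - grand, m_b - grand, "+") - grand)^2)
  ss_as <- q * sum((m_as - outer(m_a - grand, m_s - grand, "+") - grand)^2)
  ss_bs <- p * sum((m_bs - outer(m_b - grand, m_s - grand, "+") - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_s <- p * q * sum((m_s - grand)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  f_or_zero <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= 0) return(NaN)
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  list(
    F_task = f_or_zero(ss_a, p - 1, ss_as, (p - 1) * (n - 1)),
    F_network = f_or_zero(ss_b, q - 1, ss_bs, (q - 1) * (n - 1)),
    F_interaction = f_or_zero(ss_ab, (p - 1) * (q - 1), ss_abs,
                              (p - 1) * (q - 1) * (n - 1)),
    df = list(task = c(p - 1, (p - 1) * (n - 1)),
              network = c(q - 1, (q - 1) * (n - 1)),
              interaction = c((p - 1) * (q - 1), (p - 1) * (q - 1) * (n - 1)))
  )
}

# Random timed transcript over a space's vocabulary (plus optional OOV
# tokens), for property tests.
random_transcript <- function(space, n_tokens, participant = "p01",
                              prompt = "t1", period = 50, oov_rate = 0) {
  tokens <- sample(space$vocabulary, n_tokens, replace = TRUE)
  if (oov_rate > 0) {
    swap <- runif(n_tokens) < oov_rate
    tokens[swap] <- "zzz_oov"
  }
  tibble::tibble(
    participant = participant,
    prompt = prompt,
    task = "production",
    token = tokens,
    onset_s = sort(runif(n_tokens, 0, period - 1e-6))
  )
}

# A degenerate fully on-topic cohort: every response is the same cyclic
# repetition of a 20-token block, so every full 20-word window contains each
# block token exactly once.
degenerate_cohort <- function(space, n_participants = 3, n_repeats = 3,
                              window = 20, prompt = "t1") {
  block <- rep(space$vocabulary, length.out = window)
  tokens <- rep(block, n_repeats)
  purrr::map_dfr(seq_len(n_participants), function(i) {
    tibble::tibble(
      participant = sprintf("p%02d", i),
      prompt = prompt,
      task = "production",
      token = tokens,
      onset_s = seq(0, 49.9, length.out = length(tokens))
    )
  })
}
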