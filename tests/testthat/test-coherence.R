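make_transcript <- function(tokens, participant = "p01", prompt = "t1",
                            task = "production", period = 50) {
  tibble::tibble(
    participant = participant, prompt = prompt, task = task, token = tokens,
    onset_s = seq(0, period - 1e-3, length.out = length(tokens))
  )
}

test_that("leave-one-out prototypes exclude the target and average the rest", {
  sp <- toy_space3()
  # 2 responses: prototype for each is exactly the other's vector
  tr2 <- dplyr::bind_rows(
    make_transcript(c("aa", "bb"), participant = "p01"),
    make_transcript(c("cc", "dd"), participant = "p02")
  )
  pro2 <- build_prototypes(tr2, sp, mode = "leave_one_out")
  u <- as.numeric(combine_tokens(sp, c("aa", "bb")))
  v <- as.numeric(combine_tokens(sp, c("cc", "dd")))
  expect_equal(pro2$prototype[[which(pro2$participant == "p01")]], v)
  expect_equal(pro2$prototype[[which(pro2$participant == "p02")]], u)

  # 3 identical responses: every prototype equals the shared vector
  tr3 <- purrr::map_dfr(1:3, function(i)
    make_transcript(c("aa", "ee"), participant = sprintf("p%02d", i)))
  pro3 <- build_prototypes(tr3, sp, mode = "leave_one_out")
  shared <- as.numeric(combine_tokens(sp, c("aa", "ee")))
  for (p in pro3$prototype) expect_equal(p, shared)

  # 4 responses on the k = 3 toy space match hand-averaged exclusions
  resp <- list(p01 = "aa", p02 = "bb", p03 = "cc", p04 = "dd")
  tr4 <- purrr::imap_dfr(resp, function(tok, pp)
    make_transcript(rep(tok, 2), participant = pp))
  pro4 <- build_prototypes(tr4, sp, mode = "leave_one_out")
  vecs <- lapply(resp, function(tok) as.numeric(word_vector(sp, tok)))
  for (pp in names(resp)) {
    others <- do.call(rbind, vecs[setdiff(names(resp), pp)])
    expect_equal(pro4$prototype[[which(pro4$participant == pp)]],
                 colMeans(others))
  }

  expect_error(
    build_prototypes(make_transcript(c("aa", "bb")), sp, mode = "leave_one_out"),
    "t1", class = "glocoh_input_error"
  )
})

test_that("perturbing the target response never changes its own prototype", {
  sp <- toy_space3()
  base <- dplyr::bind_rows(
    make_transcript(c("aa", "bb", "cc"), participant = "p01"),
    make_transcript(c("dd", "ee"), participant = "p02"),
    make_transcript(c("ff", "aa"), participant = "p03")
  )
  perturbed <- base
  perturbed$token[perturbed$participant == "p01"] <- c("ee", "ee", "ff")
  p1 <- build_prototypes(base, sp, mode = "leave_one_out")
  p2 <- build_prototypes(perturbed, sp, mode = "leave_one_out")
  expect_equal(p1$prototype[[which(p1$participant == "p01")]],
               p2$prototype[[which(p2$participant == "p01")]])
})

test_that("fixed-reference prototypes average the reference cohort", {
  sp <- toy_space3()
  ref <- dplyr::bind_rows(
    make_transcript(c("aa", "bb"), participant = "r1"),
    make_transcript(c("cc", "cc"), participant = "r2")
  )
  pro <- build_prototypes(make_transcript(c("aa", "aa")), sp,
                          mode = "fixed_reference", reference = ref)
  expected <- colMeans(rbind(as.numeric(combine_tokens(sp, c("aa", "bb"))),
                             as.numeric(combine_tokens(sp, c("cc", "cc")))))
  expect_equal(pro$prototype[[1]], expected)
})

test_that("window coherence matches definitions on degenerate inputs", {
  sp <- toy_space3()
  # 20 copies of one token against that token's vector: single value 1 at i=20
  vals <- window_coherence(rep("ee", 20), word_vector(sp, "ee"), sp, window = 20)
  expect_equal(which(!is.na(vals)), 20L)
  expect_equal(vals[20], 1)
  # prototype orthogonal to every window vector: all zeros
  vals0 <- window_coherence(rep(c("aa", "bb"), 12), c(0, 0, 1), sp, window = 4)
  expect_true(all(abs(vals0[!is.na(vals0)]) < 1e-12))
  # too-short transcript: all NA
  expect_true(all(is.na(window_coherence(rep("aa", 5), c(1, 0, 0), sp, window = 20))))
  expect_error(window_coherence(rep("aa", 20), c(0, 0, 0), sp),
               class = "glocoh_zero_norm_error")
})

test_that("25-token toy transcript matches the brute-force oracle", {
  sp <- toy_space3()
  set.seed(42)
  tokens <- sample(sp$vocabulary, 25, replace = TRUE)
  proto <- as.numeric(combine_tokens(sp, c("aa", "ee", "ff")))
  got <- window_coherence(tokens, proto, sp, window = 20)
  want <- oracle_window_coherence(tokens, proto, sp, window = 20)
  expect_equal(sum(!is.na(got)), 6)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("all-OOV windows are flagged missing with a warning", {
  sp <- toy_space3()
  tokens <- c(rep("zzz", 4), "aa", "bb")
  expect_warning(
    vals <- window_coherence(tokens, c(1, 1, 0), sp, window = 4),
    class = "glocoh_oov_window_warning"
  )
  expect_true(is.na(vals[4]))
  expect_false(is.na(vals[5]))
})

test_that("binning uses half-open 5-s intervals and flags empty bins", {
  scored <- tibble::tibble(
    participant = "p01", prompt = "t1", task = "production",
    token = c("x", "x", "x", "x"),
    onset_s = c(0, 4.9, 5.0, 12.0),
    coherence = c(0.2, 0.4, 0.6, NA)
  )
  bins <- bin_coherence(scored, bin_length = 5, period = 50)
  expect_equal(nrow(bins), 10)
  expect_equal(bins$mean_coherence[bins$bin == 1], mean(c(0.2, 0.4)))
  expect_equal(bins$mean_coherence[bins$bin == 2], 0.6)  # onset 5.0 in bin 2
  expect_equal(bins$n_words[bins$bin == 3], 0L)          # NA word doesn't count
  expect_true(is.na(bins$mean_coherence[bins$bin == 3]))
  expect_true(all(is.na(bins$mean_coherence[bins$bin >= 3])))
})

test_that("constant per-word coherence gives that constant in every nonempty bin", {
  scored <- tibble::tibble(
    participant = "p01", prompt = "t1", task = "production",
    token = rep("x", 30),
    onset_s = sort(runif(30, 0, 49.9)),
    coherence = 0.37
  )
  bins <- bin_coherence(scored)
  expect_true(all(bins$mean_coherence[bins$n_words > 0] == 0.37))
})

test_that("per-word values depend on token order only, not on onset shifts", {
  sp <- toy_space3()
  set.seed(7)
  tr <- random_transcript(sp, 30)
  proto <- as.numeric(combine_tokens(sp, c("aa", "bb")))
  shifted <- dplyr::mutate(tr, onset_s = onset_s + 2)
  expect_equal(window_coherence(tr$token, proto, sp),
               window_coherence(shifted$token, proto, sp))
})

test_that("response and participant means follow the spreadsheet arithmetic", {
  scored <- dplyr::bind_rows(
    tibble::tibble(participant = "p01", prompt = "t1", task = "production",
                   token = "x", onset_s = c(1, 2), coherence = c(0.5, 0.5)),
    tibble::tibble(participant = "p01", prompt = "t2", task = "production",
                   token = "x", onset_s = c(1, 2, 3), coherence = c(0.2, NA, 0.2)),
    tibble::tibble(participant = "p02", prompt = "t1", task = "production",
                   token = "x", onset_s = 1, coherence = 0.6),
    tibble::tibble(participant = "p03", prompt = "t1", task = "production",
                   token = "x", onset_s = c(1, 2), coherence = c(0.1, 0.3))
  )
  rm <- response_mean_coherence(scored)
  expect_equal(rm$mean_coherence[rm$participant == "p01" & rm$prompt == "t1"], 0.5)
  expect_equal(rm$mean_coherence[rm$participant == "p01" & rm$prompt == "t2"], 0.2)
  pm <- participant_mean_coherence(scored)
  expect_equal(pm$mean_coherence[pm$participant == "p01"], mean(c(0.5, 0.2)))
  expect_equal(pm$mean_coherence[pm$participant == "p02"], 0.6)
  expect_equal(pm$mean_coherence[pm$participant == "p03"], 0.2)

  bad <- tibble::tibble(participant = "p09", prompt = "t1", task = "production",
                        token = "x", onset_s = 1, coherence = NA_real_)
  expect_error(response_mean_coherence(bad), class = "glocoh_input_error")
})

test_that("score_transcripts ties prototypes to responses and round-trips TSV", {
  sp <- toy_space3()
  set.seed(11)
  tr <- dplyr::bind_rows(
    random_transcript(sp, 24, participant = "p01"),
    random_transcript(sp, 26, participant = "p02"),
    random_transcript(sp, 25, participant = "p03")
  )
  scored <- score_transcripts(tr, sp, mode = "leave_one_out", window = 20)
  expect_equal(nrow(scored), nrow(tr))
  expect_true(all(is.na(scored$coherence[scored$word_index < 20])))
  # spot-check one response against the oracle with its own prototype
  pro <- build_prototypes(tr, sp, mode = "leave_one_out")
  p2 <- pro$prototype[[which(pro$participant == "p02")]]
  want <- oracle_window_coherence(tr$token[tr$participant == "p02"], p2, sp, 20)
  expect_equal(scored$coherence[scored$participant == "p02"], want,
               tolerance = 1e-12)

  path <- file.path(withr::local_tempdir(), "tr.tsv")
  write_transcripts(tr, path)
  expect_equal(as.data.frame(read_transcripts(path)), as.data.frame(tr),
               tolerance = 1e-12)
})

test_that("transcript validation rejects malformed tables", {
  bad <- tibble::tibble(participant = "p01", prompt = "t1", task = "production",
                        token = c("a", "b"), onset_s = c(5, 1))
  expect_error(validate_transcripts <- glocoh:::validate_transcripts(bad),
               class = "glocoh_input_error")
  neg <- tibble::tibble(participant = "p01", prompt = "t1", task = "production",
                        token = "a", onset_s = -1)
  expect_error(glocoh:::validate_transcripts(neg), class = "glocoh_input_error")
})
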