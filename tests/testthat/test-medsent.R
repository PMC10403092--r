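test_that("sentences render events as med/action token pairs in order", {
  meds <- data.frame(
    encounter_id = "e1",
    time = c(60, 120, 240, 300),
    medication = c("A", "B", "A", "B"),
    action = c("given", "given", "rate changed", "stopped"),
    sequence_no = 1:4)
  expect_equal(build_sentence(meds, "e1", t = 360),
               "a given b given a rate_changed b stopped")
  ## half-open window: the event exactly at t - 6 h (b given at 120) drops
  expect_equal(build_sentence(meds, "e1", t = 420 + 60, window_minutes = 360),
               "a rate_changed b stopped")
  ## empty window -> sentinel
  expect_equal(build_sentence(meds, "e1", t = 30), "<no_meds>")
  ## simultaneous events ordered by sequence_no
  tie <- data.frame(encounter_id = "e1", time = c(100, 100),
                    medication = c("x", "y"), action = "given",
                    sequence_no = c(2L, 1L))
  expect_equal(build_sentence(tie, "e1", t = 200), "y given x given")
  bad <- transform(meds, action = "held")
  expect_error(build_sentence(bad, "e1", t = 360), "unknown medication action")
})

test_that("the training corpus truncates MV histories at preparation time", {
  coh <- toy_cohort()
  corpus <- build_training_corpus(coh$medications, coh$encounters)
  ## mv1: prep = 1170; the sedative given at 1185 must not appear
  expect_equal(corpus$sentences[["mv1"]], "med_a given med_a rate_changed")
  ## controls use the full stay
  expect_equal(corpus$sentences[["ctl1"]], "med_b given")
  expect_equal(corpus$labels, c(1L, 0L, 0L))
  expect_length(corpus$sentences, nrow(coh$encounters))
})

test_that("co-occurrence counts are symmetric and match hand counts", {
  co <- cooccurrence_counts(rep("a given", 100), window = 25)
  expect_equal(co[co$token_i == "a" & co$token_j == "given", ]$x, 100)
  expect_equal(co[co$token_i == "given" & co$token_j == "a", ]$x, 100)
  ## distance weighting: pair at distance 2 counts 1/2
  co2 <- cooccurrence_counts("a b c", window = 25)
  expect_equal(co2[co2$token_i == "a" & co2$token_j == "c", ]$x, 0.5)
})

test_that("embeddings have the requested dimension and sentinel handling", {
  sents <- c(rep("a given b given", 20), rep("b stopped", 10))
  emb <- fit_embeddings(sents, dim = 10, seed = 2)
  expect_equal(ncol(emb$vectors), 10L)
  expect_true(all(c("<pad>", "<no_meds>", "a", "b", "given", "stopped") %in%
                    emb$vocab))
  expect_equal(unname(emb$vectors["<pad>", ]), rep(0, 10))
  expect_true(all(is.finite(emb$vectors)))
  expect_error(fit_embeddings(rep("solo", 5)), "vocabulary")
})

test_that("extractor feature dimension is filters x lengths for any config", {
  sents <- c(rep(c("a given b given", "c stopped"), 30))
  labs <- rep(c(1L, 0L), 30)
  emb <- fit_embeddings(sents, seed = 1)
  for (cfg in list(conv_extractor_config(folds = 0, epochs = 2),
                   conv_extractor_config(filter_lengths = c(2L, 3L),
                                         filters_per_length = 4L,
                                         folds = 0, epochs = 2))) {
    ex <- train_extractor(sents, labs, cfg, emb)
    expect_equal(ex$n_features,
                 cfg$filters_per_length * length(cfg$filter_lengths))
    f <- extract_medhist(ex, sents[1:3])
    expect_equal(ncol(f), ex$n_features)
    expect_true(all(is.finite(f)))
  }
  expect_error(train_extractor(sents, rep(1L, 60),
                               conv_extractor_config(folds = 0), emb),
               "both classes")
})

test_that("extraction is deterministic and batch-independent", {
  sents <- c(rep(c("a given b given a rate_changed", "c given"), 25))
  labs <- rep(c(1L, 0L), 25)
  emb <- fit_embeddings(sents, seed = 4)
  cfg <- conv_extractor_config(folds = 0, epochs = 3, seed = 9)
  ex1 <- train_extractor(sents, labs, cfg, emb)
  ex2 <- train_extractor(sents, labs, cfg, emb)
  expect_identical(ex1$params$W, ex2$params$W)
  expect_identical(ex1$U, ex2$U)
  ## identical sentences -> identical features, even in different batches
  f1 <- extract_medhist(ex1, c("a given", "a given b stopped"))
  f2 <- extract_medhist(ex1, c("a given b stopped", "c given", "a given"))
  expect_equal(f1[1, ], f2[3, ])
  expect_equal(f1[2, ], f2[1, ])
  ## the empty-history sentinel maps to one fixed baseline vector
  fe <- extract_medhist(ex1, c("<no_meds>", "<no_meds>"))
  expect_equal(fe[1, ], fe[2, ])
  ## out-of-vocabulary tokens fall back to the sentinel vector
  expect_equal(extract_medhist(ex1, "unseen_drug given")[1, ],
               extract_medhist(ex1, "<no_meds> given")[1, ])
})

test_that("max-pooled convolution is order-sensitive within filter span", {
  sents <- rep(c("a given b given c given d given", "d stopped c stopped"), 30)
  labs <- rep(c(1L, 0L), 30)
  emb <- fit_embeddings(sents, seed = 6)
  ex <- train_extractor(sents, labs, conv_extractor_config(folds = 0, epochs = 5),
                        emb)
  fwd <- extract_medhist(ex, "a given b given c given d given")
  rev <- extract_medhist(ex, "given d given c given b given a")
  expect_false(isTRUE(all.equal(fwd, rev)))
})

test_that("a token carried only by positives is learned almost perfectly", {
  set.seed(31)
  n <- 500
  vocab <- paste0("med_", 1:8)
  mk <- function() paste(rbind(sample(vocab, 4, TRUE),
                               sample(c("given", "rate_changed", "stopped"),
                                      4, TRUE)), collapse = " ")
  sents <- vapply(seq_len(n), function(i) mk(), "")
  labs <- rep(c(1L, 0L), length.out = n)
  sents[labs == 1L] <- paste(sents[labs == 1L], "intub_prep given")
  tr <- seq_len(400); te <- 401:500
  emb <- fit_embeddings(sents[tr], seed = 2)
  ex <- train_extractor(sents[tr], labs[tr],
                        conv_extractor_config(folds = 0, seed = 2), emb)
  acc <- mean((predict_sentence_prob(ex, sents[te]) > 0.5) == (labs[te] == 1L))
  expect_gt(acc, 0.9)
})

test_that("an enriched motif is recovered near the detection ceiling", {
  ## motif present in every positive and 20% of negatives (5:1 presence
  ## enrichment, n = 1000). A max-pooled detector reads motif presence, so
  ## the information-theoretic AUROC ceiling is exactly
  ## 1 * (1 - 0.2) + 0.5 * 0.2 = 0.90; the trained classifier must land
  ## near that ceiling and its scores must track presence almost perfectly.
  set.seed(77)
  n <- 1000
  vocab <- paste0("med_", 1:10)
  mk <- function(k) paste(rbind(sample(vocab, k, TRUE),
                                sample(c("given", "rate_changed", "stopped"),
                                       k, TRUE)), collapse = " ")
  sents <- vapply(seq_len(n), function(i) mk(sample(3:6, 1)), "")
  labs <- rep(c(1L, 0L), length.out = n)
  motif <- "pressor given pressor rate_changed"
  hit <- labs == 1L | runif(n) < 0.2
  sents[hit] <- paste(sents[hit], motif)
  emb <- fit_embeddings(sents, seed = 3)
  ex <- train_extractor(sents, labs,
                        conv_extractor_config(folds = 10, epochs = 25, seed = 3),
                        emb)
  expect_gt(ex$cv_auroc, 0.85)
  ## the refit classifier's scores separate motif carriers almost perfectly
  p <- predict_sentence_prob(ex, sents)
  expect_gt(auroc(p, hit), 0.95)
})
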