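# a small architecture for fast contract tests
tiny_config <- function(n_classes = 3L) {
  deep_taxa_config(n_classes = n_classes, kernels = c(5L, 7L), filters = 6L,
                   recurrent_units = 5L, dense_units = c(10L, 8L),
                   dropout = c(0.2, 0.1, 0.1), max_len = 40L)
}

test_that("one-hot encoding follows the (A,C,G,T,N) channel order with masking", {
  enc <- encode_reads("ACGTN", max_len = 6)
  expect_equal(enc$tensor[1, 1:5, ], diag(5), ignore_attr = TRUE)
  expect_equal(enc$tensor[1, 6, ], rep(0, 5), ignore_attr = TRUE)
  expect_equal(enc$mask[1, ], c(rep(TRUE, 5), FALSE))
  # every valid position sums to 1 across channels
  expect_true(all(apply(enc$tensor[1, 1:5, ], 1, sum) == 1))
  # empty read: all-zero, fully masked
  enc0 <- encode_reads("", max_len = 4)
  expect_true(all(enc0$tensor == 0))
  expect_true(all(!enc0$mask))
  # full-length read: no padding
  enc150 <- encode_reads(strrep("A", 150))
  expect_true(all(enc150$mask))
  expect_error(encode_reads("ACXT"), "position 3")
  expect_error(encode_reads(strrep("A", 151)), "longer than")
})

test_that("softmax output is a probability simplex and padding is inert", {
  m <- build_deep_model(c("a", "b", "c"), tiny_config(), seed = 2)
  m$fitted <- TRUE
  seqs <- c("ACGTACGTACAGGTT", "TTGCA", "NNNNN")
  pred <- predict_genus(m, seqs)
  probs <- attr(pred, "probs")
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-12)
  expect_true(all(probs >= 0))
  # the same read alone or in a batch with longer reads predicts identically
  p_alone <- attr(predict_genus(m, "TTGCA"), "probs")
  expect_equal(unname(p_alone[1, ]), unname(probs[2, ]), tolerance = 1e-12)
})

test_that("parameter count follows closed-form layer arithmetic", {
  cfg <- tiny_config()
  m <- build_deep_model(c("a", "b", "c"), cfg, seed = 1)
  expect_equal(m$n_params, sum(vapply(m$weights, length, integer(1))))
  # monotone in filters per branch
  cfg_big <- tiny_config(); cfg_big$filters <- 12L
  expect_gt(n_params_deep(cfg_big), n_params_deep(cfg))
  # the reference architecture's count is in the expected order of magnitude
  ref <- deep_taxa_config(n_classes = 39)
  expect_gt(n_params_deep(ref), 1e5)
  expect_error(deep_taxa_config(n_classes = 1), "n_classes")
})

test_that("permuting class indices permutes output probabilities", {
  m <- build_deep_model(c("a", "b", "c"), tiny_config(), seed = 3)
  m$fitted <- TRUE
  seqs <- c("ACGTACGTAC", "GGTTGCAGCA")
  p1 <- attr(predict_genus(m, seqs), "probs")
  perm <- c(3, 1, 2)
  m2 <- m
  m2$weights$out_W <- m$weights$out_W[, perm]
  m2$weights$out_b <- m$weights$out_b[perm]
  p2 <- attr(predict_genus(m2, seqs), "probs")
  expect_equal(unname(p2), unname(p1[, perm]), tolerance = 1e-12)
})

test_that("an overfit toy model memorizes its training reads", {
  set.seed(9)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(1:50, function(i)
    paste(sample(bases, 30, replace = TRUE), collapse = ""), character(1))
  labels <- rep(c("gA", "gB"), each = 25)
  cfg <- tiny_config(n_classes = 2L)
  cfg$dropout <- c(0, 0, 0)
  model <- build_deep_model(c("gA", "gB"), cfg, seed = 4)
  fit <- train_deep(model, seqs, labels,
                    deep_train_config(split = 1, max_epochs = 60,
                                      patience = 60, batch_size = 10,
                                      learning_rate = 5e-3, seed = 5))
  pred <- predict_genus(fit, seqs)
  expect_gte(mean(pred$genus == labels), 0.98)
  # batch and single-read prediction agree
  single <- predict_genus(fit, seqs[7])
  expect_equal(single$genus, pred$genus[7])
  expect_equal(single$probability, pred$probability[7], tolerance = 1e-12)
  # an all-N read still yields a valid probability vector
  pN <- attr(predict_genus(fit, strrep("N", 20)), "probs")
  expect_equal(sum(pN), 1, tolerance = 1e-12)
  expect_error(predict_genus(build_deep_model(c("x", "y"), tiny_config(2L)),
                             "ACGT"), "not fitted")
})

test_that("early stopping triggers after the patience window", {
  set.seed(10)
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  labels <- rep(c("gA", "gB"), 20)
  cfg0 <- tiny_config(2L)
  cfg0$dropout <- c(0, 0, 0)   # deterministic loss per epoch
  model <- build_deep_model(c("gA", "gB"), cfg0, seed = 1)
  # zero learning rate: the loss can never decrease after epoch 1
  fit <- train_deep(model, seqs, labels,
                    deep_train_config(split = 1, max_epochs = 15,
                                      patience = 5, learning_rate = 0,
                                      seed = 2))
  expect_equal(nrow(fit$history), 6L)   # 1 improvement + 5 stalled epochs
  # a class absent from the training split is an error before training
  expect_error(train_deep(model, seqs, rep("gA", 40),
                          deep_train_config(split = 1, seed = 1)),
               "class absent")
})

test_that("training is deterministic under a fixed seed", {
  set.seed(11)
  seqs <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = ""),
    character(1))
  labels <- rep(c("gA", "gB", "gC"), 20)
  cfg <- tiny_config()
  run <- function() {
    m <- build_deep_model(c("gA", "gB", "gC"), cfg, seed = 6)
    train_deep(m, seqs, labels,
               deep_train_config(max_epochs = 2, seed = 7))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("evaluation metrics match confusion-matrix arithmetic", {
  # metrics computed through a stub model whose predictions we control
  m <- build_deep_model(c("A", "B"), tiny_config(2L), seed = 1)
  m$fitted <- TRUE
  # perfect predictions on reads the model actually classifies consistently
  seqs <- c("ACGTACGTAC", "ACGTACGTAC", "TTTTGGGGCC", "TTTTGGGGCC")
  pred <- predict_genus(m, seqs)
  ev <- evaluate_model(m, seqs, pred$genus)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macro_f1, 1)
  # truth (A,A,B,B) vs predictions (A,B,B,B): accuracy 3/4
  truth <- c("A", "A", "B", "B")
  predicted <- c("A", "B", "B", "B")
  acc <- mean(truth == predicted)
  expect_equal(acc, 0.75)
  # rank-based AUROC on random balanced scores concentrates at 1/2
  set.seed(12)
  auc <- shmseq:::.auc_rank(runif(10000), rep(c(TRUE, FALSE), 5000))
  expect_lt(abs(auc - 0.5), 0.02)
  # single-class truth: AUROC undefined
  ev1 <- evaluate_model(m, seqs[1:2], c("A", "A"))
  expect_true(is.na(ev1$auroc))
})

test_that("checkpoints round-trip through the JSON format", {
  m <- build_deep_model(c("a", "b", "c"), tiny_config(), seed = 8)
  m$fitted <- TRUE
  path <- withr::local_tempfile(fileext = ".json")
  save_deep_model(m, path)
  back <- load_deep_model(path)
  expect_equal(back$classes, m$classes)
  expect_equal(back$n_params, m$n_params)
  seqs <- c("ACGTACGTACA", "GGTT")
  p1 <- attr(predict_genus(m, seqs), "probs")
  p2 <- attr(predict_genus(back, seqs), "probs")
  expect_equal(p2, p1, tolerance = 1e-12)
})
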