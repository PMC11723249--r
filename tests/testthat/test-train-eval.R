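# Loss, metric formulas, schedule, determinism and the evaluation surface.

test_that("cross-entropy matches its closed forms", {
  # perfect one-hot predictions give zero loss
  p <- diag(3)
  expect_equal(cross_entropy(p, 1:3, from = "prob"), 0)

  # uniform 8-class prediction costs ln 8
  u <- matrix(1 / 8, 4, 8)
  expect_equal(cross_entropy(u, c(1, 3, 5, 8), from = "prob"), log(8),
               tolerance = 1e-12)
  expect_equal(cross_entropy(matrix(0, 4, 8), c(1, 3, 5, 8)), log(8),
               tolerance = 1e-12)

  # batch loss is the mean of row losses
  set.seed(60)
  l1 <- matrix(rnorm(5), 1); l2 <- matrix(rnorm(5), 1)
  expect_equal(cross_entropy(rbind(l1, l2), c(2, 4)),
               (cross_entropy(l1, 2) + cross_entropy(l2, 4)) / 2,
               tolerance = 1e-12)

  # logits path equals explicit softmax + prob path
  lg <- matrix(rnorm(12), 3, 4)
  pr <- exp(lg) / rowSums(exp(lg))
  expect_equal(cross_entropy(lg, c(1, 2, 3)),
               cross_entropy(pr, c(1, 2, 3), from = "prob"), tolerance = 1e-10)

  expect_error(cross_entropy(u, c(0, 1, 2, 3)), "out of range")
  expect_error(cross_entropy(matrix(0.3, 2, 3), c(1, 2), from = "prob"),
               "sum to 1")
})

test_that("metric formulas reproduce the binary confusion example exactly", {
  # TP=3, FP=1, FN=2, TN=4 with class 1 as positive
  labels <- c(rep(1L, 5), rep(2L, 5))
  preds <- c(1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L, 2L, 2L)
  r <- compute_metrics(preds, labels, 2L)
  expect_equal(r$accuracy, 0.7)
  expect_equal(r$per_class$precision[1], 0.75)
  expect_equal(r$per_class$recall[1], 0.6)
  expect_equal(r$per_class$f1[1], 2 / 3, tolerance = 1e-4)
  expect_equal(unlist(r$per_class[1, c("TP", "TN", "FP", "FN")]),
               c(TP = 3L, TN = 4L, FP = 1L, FN = 2L))

  # all-correct predictions
  r1 <- compute_metrics(1:4, 1:4, 4L)
  expect_equal(c(r1$accuracy, r1$precision, r1$recall, r1$f1), rep(1, 4))

  expect_error(compute_metrics(integer(), integer(), 2L), "empty")
})

test_that("metrics agree with an independent per-class tally on random data", {
  set.seed(61)
  for (rep in 1:5) {
    M <- sample(2:8, 1)
    n <- sample(20:200, 1)
    labels <- sample(M, n, replace = TRUE)
    preds <- sample(M, n, replace = TRUE)
    r <- compute_metrics(preds, labels, M)

    # brute-force one-vs-rest tally
    for (cls in seq_len(M)) {
      tp <- sum(preds == cls & labels == cls)
      fp <- sum(preds == cls & labels != cls)
      fn <- sum(preds != cls & labels == cls)
      tn <- sum(preds != cls & labels != cls)
      expect_equal(unlist(r$per_class[cls, c("TP", "TN", "FP", "FN")]),
                   c(TP = tp, TN = tn, FP = fp, FN = fn))
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      expect_equal(r$per_class$precision[cls], pr)
      expect_equal(r$per_class$recall[cls], rc)
      # F1 is the harmonic mean where defined
      if (pr + rc > 0) {
        expect_equal(r$per_class$f1[cls], 2 * pr * rc / (pr + rc))
      }
    }
    expect_equal(r$accuracy, mean(preds == labels))
    # confusion row sums equal per-class label counts
    expect_equal(rowSums(r$confusion),
                 as.vector(table(factor(labels, levels = 1:M))))
    expect_true(all(c(r$accuracy, r$precision, r$recall, r$f1) >= 0 &
                      c(r$accuracy, r$precision, r$recall, r$f1) <= 1))
  }
})

test_that("the cosine schedule decays from lr0 to below lr0/100", {
  lr0 <- 1e-4
  expect_equal(affnet:::cosine_lr(0, 100, lr0), lr0)
  expect_lt(affnet:::cosine_lr(99, 100, lr0), lr0 / 100)
  lrs <- vapply(0:99, affnet:::cosine_lr, 0, epochs = 100, lr0 = lr0)
  expect_true(all(diff(lrs) < 0))
})

test_that("training is deterministic and the loop decreases the loss", {
  dir <- tempfile("tr")
  sp <- synthetic_spec(per_class = 8L)
  man <- generate_synthetic_dataset(sp, dir, seed = 11L)
  man$split <- "train"
  run <- function(epochs) {
    m <- build_model(tiny_config())
    train(m, man, train_config(lr = 1e-3, batch_size = 16L,
                               epochs = epochs, seed = 42L))
  }
  r1 <- run(2L)
  r2 <- run(2L)
  expect_identical(r1$history$train_loss[1], r2$history$train_loss[1])
  expect_identical(r1$history$train_loss[2], r2$history$train_loss[2])

  r12 <- run(12L)
  expect_lt(mean(tail(r12$history$train_loss, 4)),
            mean(head(r12$history$train_loss, 4)))
})

test_that("evaluation is chance-level with a zeroed head and self-consistent", {
  dir <- tempfile("ev")
  sp <- synthetic_spec(per_class = 8L)
  man <- generate_synthetic_dataset(sp, dir, seed = 12L)
  man$split <- "test"
  m <- build_model(tiny_config())
  ps <- model_params(m)
  ps[["head.w"]]$v[] <- 0
  ps[["head.b"]]$v[] <- 0
  r <- evaluate(m, man, split = "test")
  # uniform logits: accuracy within binomial error of chance (M = 2)
  expect_lt(abs(r$accuracy - 0.5), 0.4)
  # the report equals compute_metrics on its own prediction vector
  r2 <- compute_metrics(r$predictions, r$labels, 2L)
  expect_equal(r$accuracy, r2$accuracy)
  expect_equal(r$confusion, r2$confusion)

  emb <- extract_embeddings(m, man, split = "test")
  expect_equal(nrow(emb), sum(man$split == "test"))
  expect_equal(ncol(emb) - 2L, 128L)

  expect_error(evaluate(m, man, split = "val"), "empty or missing")
})
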