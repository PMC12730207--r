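# Voting rules, dual-network decisions, metrics, and the split machinery.

test_that("majority voting handles the canonical five-frame example", {
  expect_equal(majority_vote(c("class1", "class1", "class3", "class1", "class5"), 5),
               "class1")
  labs <- c("a", "b", "a", "c")
  expect_equal(majority_vote(labs, 1), labs)
  # tie inside a group: earliest-appearing label wins
  expect_equal(majority_vote(c("A", "B", "A", "B"), 4), "A")
  expect_equal(majority_vote(c("B", "A", "A", "B"), 4), "B")
  # partial trailing group voted as-is
  expect_equal(majority_vote(c("x", "x", "y", "y", "y"), 3), c("x", "y"))
  expect_error(majority_vote(character(0), 5), "non-empty")
})

test_that("group decisions equal a brute-force mode oracle on 1000 random groups", {
  set.seed(21)
  for (i in 1:1000) {
    labs <- sample(letters[1:5], sample(1:12, 1), replace = TRUE)
    expect_identical(majority_vote(labs, length(labs)), oracle_mode(labs))
  }
})

test_that("vocalization decision is the mode of all frame labels", {
  expect_equal(vocalization_decision(rep("dog", 7)), "dog")
  expect_equal(vocalization_decision(c(rep("cat", 6), rep("dog", 4))), "cat")
  set.seed(22)
  for (i in 1:200) {
    labs <- sample(LETTERS[1:4], sample(1:30, 1), replace = TRUE)
    expect_identical(vocalization_decision(labs), oracle_mode(labs))
  }
})

test_that("dual decision accepts agreement and rejects disagreement", {
  expect_equal(dual_decision("cat", "cat"), "cat")
  expect_true(is.na(dual_decision("cat", "dog")))
  expect_equal(dual_decision(c("a", "b", "c"), c("a", "x", "c")),
               c("a", NA, "c"))
})

test_that("dual agreement rate matches the symmetric-confusion closed form", {
  # two independent classifiers with per-class accuracy p and errors spread
  # uniformly over the K-1 other classes agree with probability
  # p^2 + (1-p)^2 / (K-1)
  set.seed(23)
  K <- 5
  p <- 0.7
  n <- 60000
  truth <- sample(1:K, n, replace = TRUE)
  draw <- function() {
    correct <- runif(n) < p
    wrong <- ((truth - 1 + sample(1:(K - 1), n, replace = TRUE)) %% K) + 1
    ifelse(correct, truth, wrong)
  }
  a <- draw()
  b <- draw()
  agree_rate <- mean(!is.na(dual_decision(as.character(a), as.character(b))))
  expect_equal(agree_rate, p ^ 2 + (1 - p) ^ 2 / (K - 1), tolerance = 0.02)
})

test_that("metrics match a hand-computed 2x2 example", {
  cm <- matrix(c(8, 3, 2, 7), 2, 2) # rows true, cols predicted
  rownames(cm) <- colnames(cm) <- c("c1", "c2")
  rep <- compute_metrics(cm)
  expect_equal(rep$accuracy, 0.75)
  p1 <- 8 / 11
  r1 <- 0.8
  expect_equal(rep$per_class$precision[1], p1)
  expect_equal(rep$per_class$recall[1], r1)
  expect_equal(rep$per_class$f1[1], 2 * p1 * r1 / (p1 + r1))
  # diagonal matrix: everything perfect
  perfect <- compute_metrics(diag(c(5, 3, 9)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  # P_i = R_i = p gives F1_i = p (symmetric confusion)
  sym <- matrix(c(6, 2, 2, 6), 2, 2)
  rs <- compute_metrics(sym)
  expect_equal(rs$per_class$f1, rs$per_class$precision)
  expect_error(compute_metrics(matrix(0, 2, 2)), "no observations")
  expect_error(compute_metrics(matrix(-1, 2, 2)), "non-negative")
})

test_that("metrics agree with brute-force enumeration on 1000 random matrices", {
  set.seed(24)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 3), k, k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    rep <- compute_metrics(cm)
    acc <- sum(diag(cm)) / sum(cm)
    prec <- rec <- f1 <- numeric(k)
    for (j in 1:k) {
      prec[j] <- if (sum(cm[, j]) > 0) cm[j, j] / sum(cm[, j]) else 0
      rec[j] <- if (sum(cm[j, ]) > 0) cm[j, j] / sum(cm[j, ]) else 0
      f1[j] <- if (prec[j] + rec[j] > 0) 2 * prec[j] * rec[j] / (prec[j] + rec[j]) else 0
    }
    expect_equal(rep$accuracy, acc)
    expect_equal(rep$macro_precision, mean(prec))
    expect_equal(rep$macro_recall, mean(rec))
    expect_equal(rep$macro_f1, mean(f1))
  }
})

test_that("confusion matrices count truth rows and prediction columns", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(cm["a", "a"], 1L, ignore_attr = TRUE)
  expect_equal(cm["a", "b"], 1L, ignore_attr = TRUE)
  expect_equal(sum(cm), 3L)
})

test_that("split plans validate sizes and split per class without leakage", {
  expect_error(split_plan(per_class_test = 0), "per_class_test")
  ds <- protocol_dataset()
  plan <- split_plan(1, 10, 4, seed = 3)
  split <- cochleaR:::split_recordings(ds, plan, 99L)
  counts <- table(split$species, split$role)
  expect_true(all(counts[, "train"] == 10))
  expect_true(all(counts[, "test"] == 4))
  expect_length(intersect(split$source_id[split$role == "train"],
                          split$source_id[split$role == "test"]), 0)
  tight <- split_plan(1, 45, 5)
  expect_error(cochleaR:::split_recordings(ds, tight, 1L), "Insufficient")
})

test_that("identical repeat seeds reproduce identical per-repeat reports", {
  ds <- protocol_dataset()[protocol_dataset()$species %in% c("lion", "dolphin", "frog"), ]
  plan <- split_plan(2, 6, 2, seed = 8)
  plan$seeds <- rep(plan$seeds[1], 2)
  rep <- run_protocol(ds, "P4", feature_params(N = 10),
                      plan = plan, config = mlp_config(max_iter = 60),
                      group_sizes = c(5))
  r1 <- rep$repeats[rep$repeats$`repeat` == 1, -1]
  r2 <- rep$repeats[rep$repeats$`repeat` == 2, -1]
  expect_identical(r1, r2)
  # averaged accuracy is exactly the mean of per-repeat accuracies
  frame_rows <- rep$repeats[rep$repeats$granularity == "frame", ]
  smry <- rep$summary[rep$summary$granularity == "frame", ]
  expect_identical(smry$accuracy_mean, mean(frame_rows$accuracy))
})
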