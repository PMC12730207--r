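# The feed-forward network: balancing, training, stopping rules, prediction.

test_that("class balancing subsamples every class to the minimum count", {
  feats <- tibble::tibble(
    species = rep(c("A", "B", "C"), c(100, 60, 80)),
    v001 = rnorm(240)
  )
  bal <- balance_classes(feats, seed = 4)
  expect_equal(unname(table(bal$species)), rep(60L, 3), ignore_attr = TRUE)
  # already balanced input keeps the same multiset
  even <- tibble::tibble(species = rep(c("A", "B"), each = 5), v001 = 1:10)
  bal2 <- balance_classes(even, seed = 1)
  expect_setequal(bal2$v001, even$v001)
  # determinism
  expect_identical(balance_classes(feats, seed = 9), balance_classes(feats, seed = 9))
  expect_error(balance_classes(feats, classes = c("A", "B", "C", "D")), "D")
})

test_that("separable 2-class Gaussians are fit to >= 99% training accuracy", {
  task <- two_class_task(100, seed = 10)
  net <- train_network(task, mlp_config(seed = 1))
  expect_gte(mean(predict(net, task$x) == task$y), 0.99)
  # identical features for both classes: chance-level accuracy
  set.seed(2)
  x_same <- rbind(matrix(rnorm(400), 200, 2), matrix(rnorm(400), 200, 2))
  x_same[201:400, ] <- x_same[1:200, ]
  y_same <- rep(c("a", "b"), each = 200)
  net_null <- train_network(list(x = x_same, y = y_same),
                            mlp_config(seed = 3, max_iter = 100))
  acc <- mean(predict(net_null, x_same) == y_same)
  expect_lt(abs(acc - 0.5), 0.12) # binomial noise around chance
})

test_that("probability rows sum to one and duplicated inputs agree", {
  task <- gaussian_task(3, 40, dim = 4, seed = 11)
  net <- train_network(task, mlp_config(seed = 5, max_iter = 200))
  probs <- as.matrix(predict(net, task$x, type = "prob"))
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
  expect_true(all(probs >= 0))
  dup <- task$x[c(1, 1, 5, 5), ]
  expect_identical(predict(net, dup)[1], predict(net, dup)[2])
  expect_error(predict(net, task$x[, 1:2]), "dimension mismatch", ignore.case = TRUE)
})

test_that("argmax ties break toward the lowest class index", {
  net <- list(weights = list(list(W = matrix(0, 2, 3), b = c(0, 0, 0))),
              par = rep(0, 9), sizes = c(2L, 3L), classes = c("a", "b", "c"),
              standardizer = list(center = c(0, 0), scale = c(1, 1), standardize = TRUE))
  class(net) <- "cochlear_mlp"
  # all-zero net: uniform softmax, every class tied
  expect_equal(predict(net, matrix(rnorm(10), 5, 2)), rep("a", 5))
})

test_that("training log loss is non-increasing over accepted steps", {
  task <- gaussian_task(4, 50, dim = 6, seed = 12)
  net <- train_network(task, mlp_config(seed = 7, max_iter = 300))
  ckpt <- net$training_log$checkpoint_loss
  expect_gte(length(ckpt), 2)
  expect_true(all(diff(ckpt) <= 1e-10))
})

test_that("stopping rules honor max_iter and the 1e-6 loss/gradient criteria", {
  cfg <- mlp_config()
  expect_equal(cfg$max_iter, 1000L)
  expect_equal(cfg$tol_loss, 1e-6)
  expect_equal(cfg$tol_grad, 1e-6)
  # heavily overlapping classes cannot reach the loss criterion in 7 steps
  hard <- gaussian_task(3, 80, dim = 4, sep = 0.5, seed = 13)
  capped <- train_network(hard, mlp_config(seed = 2, max_iter = 7, chunk_size = 3))
  expect_lte(capped$training_log$iterations, 7)
  expect_equal(capped$training_log$stop_reason, "max_iter")
  # a separable task trains until the loss/gradient criterion trips early
  task <- gaussian_task(3, 60, dim = 4, seed = 13)
  full <- train_network(task, mlp_config(seed = 2, max_iter = 2000))
  expect_lt(full$training_log$iterations, 2000)
  expect_true(full$training_log$final_loss < 1e-6 ||
                full$training_log$final_grad_norm < 1e-6)
  expect_true(full$training_log$stop_reason %in%
                c("loss_below_tol", "grad_below_tol"))
})

test_that("standardizer is fitted on training data only and training is reproducible", {
  task <- gaussian_task(2, 80, dim = 3, seed = 14)
  net1 <- train_network(task, mlp_config(seed = 20, max_iter = 50))
  # appending extra (test) rows to a prediction call must not change the scaler
  more <- gaussian_task(2, 40, dim = 3, seed = 15)
  net_on_train_only <- train_network(task, mlp_config(seed = 20, max_iter = 50))
  expect_identical(net1$standardizer, net_on_train_only$standardizer)
  expect_identical(net1$standardizer$center, colMeans(task$x))
  # same seed -> bit-identical weights
  expect_identical(net1$par, net_on_train_only$par)
  # different seed -> different weights
  net2 <- train_network(task, mlp_config(seed = 21, max_iter = 50))
  expect_false(identical(net1$par, net2$par))
})

test_that("analytic gradient matches a finite-difference check", {
  set.seed(16)
  sizes <- c(3L, 4L, 2L)
  x <- matrix(rnorm(15), 5, 3)
  onehot <- diag(2)[sample(1:2, 5, TRUE), ]
  par <- rnorm(3 * 4 + 4 + 4 * 2 + 2, sd = 0.5)
  lg <- cochleaR:::mlp_loss_grad(par, x, onehot, sizes)
  num <- vapply(seq_along(par), function(i) {
    h <- 1e-6
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (cochleaR:::mlp_loss_grad(pp, x, onehot, sizes, want_grad = FALSE)$loss -
       cochleaR:::mlp_loss_grad(pm, x, onehot, sizes, want_grad = FALSE)$loss) / (2 * h)
  }, numeric(1))
  expect_equal(lg$grad, num, tolerance = 1e-5)
})

test_that("non-finite features are rejected before optimization", {
  expect_error(train_network(list(x = matrix(c(1, NA, 2, 3), 2, 2), y = c("a", "b"))),
               "non-finite")
  expect_error(train_network(list(x = matrix(1:4, 2, 2), y = c("a", "a"))), "2 classes")
})
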