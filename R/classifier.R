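# Feed-forward species classifier: 2 hidden layers (50, 25) with ReLU,
# softmax output, trained by minimizing softmax cross-entropy with a
# quasi-Newton solver (limited-memory BFGS). Training stops at `max_iter`
# iterations or as soon as the loss or the infinity norm of its gradient
# falls below 1e-6.

#' Network configuration
#'
#' Defaults follow the reference architecture: hidden layers of 50 and 25
#' rectified-linear cells, softmax output, BFGS-family solver, at most 1000
#' training iterations, stopping early when the loss or its gradient
#' infinity-norm falls below `1e-6`.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param max_iter maximum quasi-Newton iterations.
#' @param tol_loss stop when the cross-entropy loss falls below this.
#' @param tol_grad stop when the gradient infinity-norm falls below this.
#' @param seed integer seed for weight initialization.
#' @param standardize z-score features using training-set statistics
#'   (recommended: scalar features in Hz/seconds and cepstral coefficients
#'   live on very different scales, and quasi-Newton training is
#'   scale-sensitive).
#' @param chunk_size solver iterations between stopping-rule checks.
#' @return a named list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(50, 25), max_iter = 1000,
                       tol_loss = 1e-6, tol_grad = 1e-6, seed = 1,
                       standardize = TRUE, chunk_size = 50) {
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1), max_iter >= 1)
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), max_iter = as.integer(max_iter),
         tol_loss = tol_loss, tol_grad = tol_grad, seed = as.integer(seed),
         standardize = isTRUE(standardize), chunk_size = as.integer(chunk_size)),
    class = "mlp_config"
  )
}

#' Balance classes by subsampling to the smallest class
#'
#' Every class retains exactly the minimum per-class count of vectors,
#' chosen uniformly at random under `seed` — the training-set balancing
#' applied before frame-based training.
#'
#' @param features a feature tibble with a `species` column (see
#'   [build_feature_table()]).
#' @param seed integer seed; the subsample is deterministic given it.
#' @param classes optional full class list; a listed class with no vectors
#'   is a configuration error.
#' @return the subsampled tibble (equal per-class counts).
#' @export
balance_classes <- function(features, seed = 1, classes = NULL) {
  stopifnot(is.data.frame(features), "species" %in% names(features))
  if (!is.null(classes)) {
    missing <- setdiff(classes, unique(features$species))
    if (length(missing) > 0) {
      stopf("No feature vectors for class(es): %s", paste(missing, collapse = ", "))
    }
  }
  n_min <- min(table(features$species))
  with_seed(seed, {
    features |>
      dplyr::group_by(.data$species) |>
      dplyr::slice_sample(n = n_min) |>
      dplyr::ungroup()
  })
}

#' Train the feed-forward species classifier
#'
#' Minimizes softmax cross-entropy over the network weights with a
#' limited-memory BFGS solver, honoring the stopping rules in the
#' [mlp_config()]. Weight initialization and the solver are deterministic
#' given `config$seed`, so retraining reproduces identical weights.
#'
#' @param features a feature tibble (with `species` and `v...` columns), or
#'   a list with elements `x` (numeric matrix) and `y` (labels).
#' @param config an [mlp_config()].
#' @return a `cochlear_mlp`: weights, ordered `classes`, the fitted
#'   `standardizer` (train-set means/sds), the `config`, and a
#'   `training_log` (loss trace, checkpoint losses at accepted iterations,
#'   iterations used, stop reason, final loss and gradient norm).
#' @export
train_network <- function(features, config = mlp_config()) {
  dat <- if (is.list(features) && !is.data.frame(features) &&
             all(c("x", "y") %in% names(features))) {
    features
  } else {
    feature_matrix(features)
  }
  x <- as.matrix(dat$x)
  y <- as.character(dat$y)
  if (any(!is.finite(x))) stopf("Features contain non-finite values")
  classes <- sort(unique(y))
  if (length(classes) < 2) stopf("Need at least 2 classes, got %d", length(classes))
  yi <- match(y, classes)
  k <- length(classes)

  ctr <- if (config$standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (config$standardize) {
    s <- sqrt(colMeans(sweep(x, 2, ctr) ^ 2))
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  sizes <- c(ncol(x), config$hidden_sizes, k)
  par0 <- init_weights(sizes, config$seed)
  onehot <- matrix(0, nrow(xs), k)
  onehot[cbind(seq_len(nrow(xs)), yi)] <- 1

  trace_env <- new.env(parent = emptyenv())
  trace_env$losses <- numeric(0)
  fn <- function(par) {
    l <- mlp_loss_grad(par, xs, onehot, sizes, want_grad = FALSE)$loss
    trace_env$losses <- c(trace_env$losses, l)
    l
  }
  gr <- function(par) mlp_loss_grad(par, xs, onehot, sizes, want_grad = TRUE)$grad

  par <- par0
  iters <- 0L
  checkpoints <- numeric(0)
  stop_reason <- "max_iter"
  repeat {
    cur <- mlp_loss_grad(par, xs, onehot, sizes, want_grad = TRUE)
    checkpoints <- c(checkpoints, cur$loss)
    if (cur$loss < config$tol_loss) { stop_reason <- "loss_below_tol"; break }
    if (max(abs(cur$grad)) < config$tol_grad) { stop_reason <- "grad_below_tol"; break }
    if (iters >= config$max_iter) { stop_reason <- "max_iter"; break }
    maxit <- min(config$chunk_size, config$max_iter - iters)
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10))
    par <- opt$par
    used <- min(maxit, max(1L, opt$counts[["gradient"]] - 1L))
    iters <- iters + used
    if (opt$convergence == 0) {
      final <- mlp_loss_grad(par, xs, onehot, sizes, want_grad = TRUE)
      checkpoints <- c(checkpoints, final$loss)
      stop_reason <- if (final$loss < config$tol_loss) "loss_below_tol"
        else if (max(abs(final$grad)) < config$tol_grad) "grad_below_tol"
        else "solver_converged"
      break
    }
  }
  final <- mlp_loss_grad(par, xs, onehot, sizes, want_grad = TRUE)

  structure(
    list(weights = unpack_weights(par, sizes), par = par, sizes = sizes,
         classes = classes,
         standardizer = list(center = ctr, scale = scl,
                             standardize = config$standardize),
         config = config,
         training_log = list(
           loss_trace = trace_env$losses,
           checkpoint_loss = checkpoints,
           iterations = iters,
           stop_reason = stop_reason,
           final_loss = final$loss,
           final_grad_norm = max(abs(final$grad)))),
    class = "cochlear_mlp"
  )
}

# He-style seeded initialization, flattened [W1, b1, W2, b2, ...].
init_weights <- function(sizes, seed) {
  with_seed(seed, {
    unlist(lapply(seq_len(length(sizes) - 1), function(l) {
      w <- rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l]))
      c(w, rep(0, sizes[l + 1]))
    }))
  })
}

unpack_weights <- function(par, sizes) {
  out <- list()
  pos <- 0L
  for (l in seq_len(length(sizes) - 1)) {
    nw <- sizes[l] * sizes[l + 1]
    out[[l]] <- list(
      W = matrix(par[pos + seq_len(nw)], sizes[l], sizes[l + 1]),
      b = par[pos + nw + seq_len(sizes[l + 1])]
    )
    pos <- pos + nw + sizes[l + 1]
  }
  out
}

mlp_forward <- function(weights, x) {
  a <- x
  n_layers <- length(weights)
  zs <- vector("list", n_layers)
  as <- vector("list", n_layers + 1)
  as[[1]] <- a
  for (l in seq_len(n_layers)) {
    z <- sweep(a %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    zs[[l]] <- z
    a <- if (l < n_layers) pmax(z, 0) else z
    as[[l + 1]] <- a
  }
  zmax <- apply(a, 1, max)
  ez <- exp(a - zmax)
  probs <- ez / rowSums(ez)
  list(probs = probs, zs = zs, as = as)
}

mlp_loss_grad <- function(par, x, onehot, sizes, want_grad = TRUE) {
  w <- unpack_weights(par, sizes)
  fwd <- mlp_forward(w, x)
  n <- nrow(x)
  eps <- 1e-300
  loss <- -sum(onehot * log(fwd$probs + eps)) / n
  if (!want_grad) return(list(loss = loss))
  n_layers <- length(w)
  grads <- vector("list", n_layers)
  delta <- (fwd$probs - onehot) / n
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(W = crossprod(fwd$as[[l]], delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(w[[l]]$W)) * (fwd$zs[[l - 1]] > 0)
    }
  }
  g <- unlist(lapply(grads, function(gl) c(as.numeric(gl$W), gl$b)))
  list(loss = loss, grad = g)
}

#' @export
print.cochlear_mlp <- function(x, ...) {
  cat(sprintf("<cochlear_mlp> %s -> %s -> %d classes; %d iterations (%s), loss %.3g\n",
              x$sizes[1], paste(x$sizes[-c(1, length(x$sizes))], collapse = "-"),
              length(x$classes), x$training_log$iterations,
              x$training_log$stop_reason, x$training_log$final_loss))
  invisible(x)
}

#' Predict species labels or class probabilities
#'
#' Standardizes inputs with the training-set statistics and runs the
#' forward pass. Labels are the argmax class, ties broken by the lowest
#' class index.
#'
#' @param object a `cochlear_mlp` from [train_network()].
#' @param newdata a feature tibble or numeric matrix with the trained
#'   dimensionality.
#' @param type `"class"` for labels, `"prob"` for a tibble of per-class
#'   probabilities (rows sum to 1).
#' @param ... unused.
#' @return a character vector of labels, or a tibble of probabilities.
#' @export
predict.cochlear_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)$x
  p_expected <- object$sizes[1]
  if (ncol(x) != p_expected) {
    stopf("Feature dimension mismatch: expected %d, got %d", p_expected, ncol(x))
  }
  xs <- sweep(sweep(x, 2, object$standardizer$center), 2, object$standardizer$scale, "/")
  probs <- mlp_forward(object$weights, xs)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(as_tibble(probs))
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
tidy.cochlear_mlp <- function(x, ...) {
  tibble(step = seq_along(x$training_log$checkpoint_loss),
         loss = x$training_log$checkpoint_loss)
}

#' @export
glance.cochlear_mlp <- function(x, ...) {
  tibble(n_parameters = length(x$par),
         n_classes = length(x$classes),
         iterations = x$training_log$iterations,
         stop_reason = x$training_log$stop_reason,
         final_loss = x$training_log$final_loss,
         final_grad_norm = x$training_log$final_grad_norm)
}
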