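# Uniform train/score contract over the four base learners (logistic
# regression, back-propagation neural network, SVM, gradient-boosted trees)
# and the registry of their tunable hyperparameter spaces. Learner internals
# delegate to glmnet, e1071 and xgboost; the BP network is a compact
# in-house multi-layer perceptron (Adam, seeded) because the tuning space
# spans multi-layer architectures and relu/tanh/logistic activations.
# Continuous features are z-scored with statistics from the training rows
# only; categorical features are one-hot encoded; binary passed through.

hp_spec <- function(name, kind, range = NULL, categories = NULL,
                    active_when = NULL) {
  kind <- match.arg(kind, c("continuous", "log_uniform", "integer",
                            "categorical"))
  if (kind == "categorical") {
    stopifnot(length(categories) >= 1)
  } else {
    stopifnot(length(range) == 2, range[1] < range[2])
    if (kind == "log_uniform") stopifnot(range[1] > 0)
  }
  list(name = name, kind = kind, range = range, categories = categories,
       active_when = active_when)
}

#' Hyperparameter search space of a base learner
#'
#' The tuning ranges over which the synchronous optimizer searches:
#' \describe{
#'   \item{lr}{penalty (l1/l2), C (log-uniform 0.001-100), max_iter
#'     (integer 50-500).}
#'   \item{bp}{hidden_layer_sizes (categorical: 50, 100, 50+50), activation
#'     (relu/tanh/logistic), learning_rate_init and alpha (log-uniform
#'     0.0001-0.1), batch_size (integer 16-128).}
#'   \item{svm}{C (log-uniform 0.1-100), kernel (linear/rbf/poly), gamma
#'     (log-uniform 0.0001-10), degree (integer 2-5, active only for the
#'     polynomial kernel).}
#'   \item{xgb}{learning_rate (0.01-0.3), max_depth (integer 3-12),
#'     min_child_weight (integer 1-10), subsample and colsample_bytree
#'     (0.5-1), reg_alpha (0-1), reg_lambda (0-2).}
#' }
#'
#' @param name One of `"lr"`, `"bp"`, `"svm"`, `"xgb"`.
#' @return Named list of hyperparameter specifications.
#' @export
learner_space <- function(name) {
  name <- match.arg(name, c("lr", "bp", "svm", "xgb"))
  sp <- switch(name,
    lr = list(
      hp_spec("penalty", "categorical", categories = list("l1", "l2")),
      hp_spec("C", "log_uniform", c(0.001, 100)),
      hp_spec("max_iter", "integer", c(50, 500))
    ),
    bp = list(
      hp_spec("hidden_layer_sizes", "categorical",
              categories = list(c(50L), c(100L), c(50L, 50L))),
      hp_spec("activation", "categorical",
              categories = list("relu", "tanh", "logistic")),
      hp_spec("learning_rate_init", "log_uniform", c(1e-4, 0.1)),
      hp_spec("alpha", "log_uniform", c(1e-4, 0.1)),
      hp_spec("batch_size", "integer", c(16, 128))
    ),
    svm = list(
      hp_spec("C", "log_uniform", c(0.1, 100)),
      hp_spec("kernel", "categorical",
              categories = list("linear", "rbf", "poly")),
      hp_spec("gamma", "log_uniform", c(1e-4, 10)),
      hp_spec("degree", "integer", c(2, 5),
              active_when = list(param = "kernel", value = "poly"))
    ),
    xgb = list(
      hp_spec("learning_rate", "continuous", c(0.01, 0.3)),
      hp_spec("max_depth", "integer", c(3, 12)),
      hp_spec("min_child_weight", "integer", c(1, 10)),
      hp_spec("subsample", "continuous", c(0.5, 1)),
      hp_spec("colsample_bytree", "continuous", c(0.5, 1)),
      hp_spec("reg_alpha", "continuous", c(0, 1)),
      hp_spec("reg_lambda", "continuous", c(0, 2))
    ))
  names(sp) <- vapply(sp, `[[`, character(1), "name")
  sp
}

# Reject hyperparameter values outside their declared space before training.
validate_hyperparams <- function(space, hp) {
  for (s in space) {
    if (!s$name %in% names(hp)) stop("missing hyperparameter '", s$name, "'")
    v <- hp[[s$name]]
    if (s$kind == "categorical") {
      if (!any(vapply(s$categories, identical, logical(1), v)))
        stop("hyperparameter '", s$name, "' outside its category set")
    } else {
      if (!is.numeric(v) || v < s$range[1] || v > s$range[2])
        stop("hyperparameter '", s$name, "' outside its range [",
             s$range[1], ", ", s$range[2], "]")
      if (s$kind == "integer" && v != round(v))
        stop("hyperparameter '", s$name, "' must be an integer")
    }
  }
  invisible(TRUE)
}

# ---- leakage-safe preprocessing -------------------------------------------

fit_preprocessor <- function(X) {
  stopifnot(is.data.frame(X))
  info <- lapply(names(X), function(v) {
    x <- X[[v]]
    if (is.numeric(x)) {
      if (all(x %in% c(0, 1))) list(var = v, type = "binary")
      else list(var = v, type = "continuous", center = mean(x),
                scale = if (sd(x) > 0) sd(x) else 1)
    } else {
      list(var = v, type = "categorical",
           levels = if (is.factor(x)) levels(x) else sort(unique(as.character(x))))
    }
  })
  structure(list(columns = info), class = "igkso_preproc")
}

apply_preprocessor <- function(pp, X) {
  cols <- list()
  for (ci in pp$columns) {
    x <- X[[ci$var]]
    if (is.null(x)) stop("missing feature column '", ci$var, "'")
    if (ci$type == "continuous") {
      m <- matrix((x - ci$center) / ci$scale, ncol = 1,
                  dimnames = list(NULL, ci$var))
    } else if (ci$type == "binary") {
      m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, ci$var))
    } else {
      x <- as.character(x)
      if (!all(x %in% ci$levels))
        stop("unseen category in column '", ci$var, "'")
      m <- vapply(ci$levels, function(l) as.numeric(x == l),
                  numeric(length(x)))
      if (length(x) == 1L) m <- matrix(m, nrow = 1)
      colnames(m) <- paste(ci$var, ci$levels, sep = ".")
    }
    cols[[ci$var]] <- m
  }
  do.call(cbind, cols)
}

# ---- in-house multi-layer perceptron --------------------------------------

mlp_activations <- list(
  relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
  tanh = list(f = tanh, df = function(z, a) 1 - a^2),
  logistic = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(z, a) a * (1 - a))
)

mlp_train <- function(X, y, layers, activation, lr, alpha, batch_size,
                      epochs = 500L, seed = 1L) {
  act <- mlp_activations[[activation]]
  sizes <- c(ncol(X), layers, 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    n <- nrow(X); t_adam <- 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        # forward
        A <- vector("list", L + 1); Z <- vector("list", L)
        A[[1]] <- Xb
        for (l in seq_len(L)) {
          Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
          A[[l + 1]] <- if (l < L) act$f(Z[[l]])
                        else 1 / (1 + exp(-Z[[l]]))
        }
        # backward (cross-entropy + sigmoid output)
        delta <- (A[[L + 1]] - yb) / length(idx)
        t_adam <- t_adam + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta) + alpha * W[[l]]
          gb <- colSums(delta)
          if (l > 1)
            delta <- (delta %*% t(W[[l]])) * act$df(Z[[l - 1]], A[[l]])
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          c1 <- 1 - beta1^t_adam; c2 <- 1 - beta2^t_adam
          W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
        }
      }
    }
    list(W = W, b = b, activation = activation)
  })
}

mlp_predict <- function(model, X) {
  act <- mlp_activations[[model$activation]]
  A <- X
  L <- length(model$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    A <- if (l < L) act$f(Z) else 1 / (1 + exp(-Z))
  }
  as.numeric(A)
}

# ---- uniform training contract --------------------------------------------

#' Train a base learner
#'
#' Fits one of the four base learners under the uniform contract: features
#' preprocessed with training-row statistics only, probability scores in
#' \[0, 1\], deterministic given `seed`. Hyperparameters outside their
#' declared space are rejected before any fitting.
#'
#' @param name Learner name: `"lr"`, `"bp"`, `"svm"`, `"xgb"`.
#' @param hyperparams Named list matching [learner_space()].
#' @param X Data frame of feature columns (training rows).
#' @param y Binary 0/1 outcome vector; both classes must be present.
#' @param seed Integer seed.
#' @param bp_epochs Training epochs for the BP network (fixed budget, no
#'   early stopping).
#' @return Object of class `"trained_predictor"`; score new rows with
#'   [predict()][predict.trained_predictor].
#' @export
train_learner <- function(name, hyperparams, X, y, seed = 1L,
                          bp_epochs = 500L) {
  name <- match.arg(name, c("lr", "bp", "svm", "xgb"))
  stopifnot(is.data.frame(X), nrow(X) == length(y))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  validate_hyperparams(learner_space(name), hyperparams)
  num_ok <- vapply(X, function(x) !is.numeric(x) || all(is.finite(x)),
                   logical(1))
  if (!all(num_ok)) stop("non-finite feature values in column(s): ",
                         paste(names(X)[!num_ok], collapse = ", "))
  pp <- fit_preprocessor(X)
  M <- apply_preprocessor(pp, X)
  hp <- hyperparams
  fit <- switch(name,
    lr = {
      # single-column designs get a zero padding column (glmnet requires
      # >= 2 columns; the pad never enters the model)
      Mx <- if (ncol(M) == 1) cbind(M, .pad = 0) else M
      glmnet::glmnet(Mx, y, family = "binomial",
                     alpha = if (identical(hp$penalty, "l1")) 1 else 0,
                     lambda = 1 / (hp$C * nrow(Mx)),
                     maxit = 100 * hp$max_iter, standardize = FALSE)
    },
    bp = mlp_train(M, y, hp$hidden_layer_sizes, hp$activation,
                   hp$learning_rate_init, hp$alpha,
                   as.integer(min(hp$batch_size, nrow(M))),
                   epochs = bp_epochs, seed = derive_seed(seed, "bp")),
    svm = with_seed(derive_seed(seed, "svm"), {
      e1071::svm(M, factor(y, levels = c(0, 1)), type = "C-classification",
                 cost = hp$C, kernel = hp$kernel,
                 gamma = hp$gamma,
                 degree = if (identical(hp$kernel, "poly")) hp$degree else 3,
                 probability = TRUE, scale = FALSE)
    }),
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(M, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = hp$learning_rate, max_depth = hp$max_depth,
                      min_child_weight = hp$min_child_weight,
                      subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      alpha = hp$reg_alpha, lambda = hp$reg_lambda,
                      nthread = 1, seed = derive_seed(seed, "xgb")),
        data = dtrain, nrounds = 100, verbose = 0)
    })
  structure(list(learner = name, hyperparams = hyperparams, fit = fit,
                 preproc = pp, n_train = nrow(X), seed = seed),
            class = "trained_predictor")
}

#' Score new rows with a trained base learner
#'
#' @param object A [train_learner()] fit.
#' @param newdata Data frame with the training feature columns.
#' @param ... Unused.
#' @return Numeric probability scores in \[0, 1\].
#' @export
predict.trained_predictor <- function(object, newdata, ...) {
  M <- apply_preprocessor(object$preproc, newdata)
  p <- switch(object$learner,
    lr = {
      Mx <- if (ncol(M) == 1) cbind(M, .pad = 0) else M
      as.numeric(predict(object$fit, Mx, type = "response"))
    },
    bp = mlp_predict(object$fit, M),
    svm = {
      pr <- predict(object$fit, M, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    xgb = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(M))))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("trained %s learner (%d training rows)\n", x$learner, x$n_train))
  hp <- vapply(x$hyperparams, function(v) paste(format(v), collapse = "+"),
               character(1))
  cat(paste0("  ", names(hp), " = ", hp, collapse = "\n"), "\n")
  invisible(x)
}
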