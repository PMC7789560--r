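# Multilayer-perceptron regressors predicting the four distal joint angles
# (elbow flexion, forearm supination, wrist deviation, wrist extension) from
# the three shoulder angles, optionally augmented with target context
# (shoulder-to-target vector + tilt). Fixed architecture:
# input (3 or 7) -> dense 256 (ReLU) -> dense 256 (ReLU) -> dropout 0.5
# (training only) -> dense 64 (ReLU) -> linear 4.
# Training: Adam on mean squared error over standardized outputs, minibatch
# 64, early stopping on a held-out validation split; deterministic given the
# seed.

MLP_HIDDEN <- c(256L, 256L, 64L)
DISTAL_DOFS <- c("el_flex", "for_sup", "wr_dev", "wr_ext")

#' Predictor training hyperparameters
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs (early stopping usually ends
#'   training sooner).
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction Fraction of rows held out for validation.
#' @param dropout Drop fraction of the dropout layer (training only).
#' @return A list of hyperparameters.
#' @export
predictor_hyper <- function(learning_rate = 1e-3, batch_size = 64L,
                            max_epochs = 150L, patience = 20L,
                            val_fraction = 0.1, dropout = 0.5) {
  list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       val_fraction = val_fraction, dropout = dropout)
}

mlp_init <- function(d_in, d_out = 4L) {
  dims <- c(d_in, MLP_HIDDEN, d_out)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    # He initialisation for the ReLU layers, Glorot-like for the output
    sdv <- sqrt(2 / dims[l])
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sdv),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b, dims = dims)
}

mlp_forward <- function(net, X, dropout = 0, rng_dropout = FALSE) {
  A <- list(X)
  H <- length(net$W)
  Z <- X
  n <- nrow(X)
  masks <- vector("list", H)
  for (l in seq_len(H)) {
    Z <- Z %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = n)
    if (l < H) {
      Z <- Z * (Z > 0)
      # dropout after the second hidden layer, inverted scaling
      if (l == 2 && dropout > 0 && rng_dropout) {
        m <- matrix(stats::runif(length(Z)) >= dropout, nrow(Z), ncol(Z))
        Z <- Z * m / (1 - dropout)
        masks[[l]] <- m
      }
    }
    A[[l + 1]] <- Z
  }
  list(out = Z, acts = A, masks = masks)
}

mlp_backward <- function(net, fwd, dY, dropout) {
  H <- length(net$W)
  gW <- vector("list", H); gb <- vector("list", H)
  delta <- dY
  for (l in rev(seq_len(H))) {
    A_prev <- fwd$acts[[l]]
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$W[[l]])
      act <- fwd$acts[[l]]
      if (l - 1 == 2 && !is.null(fwd$masks[[2]])) {
        delta <- delta * fwd$masks[[2]] / (1 - dropout)
      }
      delta <- delta * (act > 0)
    }
  }
  list(W = gW, b = gb)
}

standardize_fit <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  list(center = ctr, scale = scl)
}
standardize_apply <- function(M, st) {
  n <- nrow(M)
  (M - rep(st$center, each = n)) / rep(st$scale, each = n)
}

#' Train a distal-angle predictor
#'
#' Trains the fixed-architecture MLP on a training dataset (see
#' [build_dataset()]). Inputs and outputs are standardized internally using
#' training-set statistics; training minimises mean squared error on the
#' standardized outputs with Adam, minibatches, dropout after the second
#' hidden layer, and early stopping on a held-out validation split.
#' Deterministic given `seed`.
#'
#' @param dataset A `training_dataset`.
#' @param hyper A [predictor_hyper()].
#' @param seed Integer seed (weights, shuffling, dropout, split).
#' @param limits Optional 7 x 2 joint-limit matrix used to clamp predictions
#'   at inference (defaults to [default_joint_limits()]).
#' @return An object of class `mlp_model`.
#' @export
train_predictor <- function(dataset, hyper = predictor_hyper(), seed = 1L,
                            limits = default_joint_limits()) {
  stopifnot(inherits(dataset, "training_dataset"))
  X <- dataset$inputs; Y <- dataset$outputs
  if (!nrow(X)) stop("empty training dataset")
  d_in <- ncol(X)
  expected <- if (dataset$mode == "C+") 7L else 3L
  if (d_in != expected) {
    stop(sprintf("input width %d does not match mode %s", d_in,
                 dataset$mode))
  }
  set.seed(seed)
  n <- nrow(X)
  n_val <- max(1L, floor(hyper$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  st_x <- standardize_fit(X[tr_idx, , drop = FALSE])
  st_y <- standardize_fit(Y[tr_idx, , drop = FALSE])
  Xs <- standardize_apply(X, st_x); Ys <- standardize_apply(Y, st_y)
  Xt <- Xs[tr_idx, , drop = FALSE]; Yt <- Ys[tr_idx, , drop = FALSE]
  Xv <- Xs[val_idx, , drop = FALSE]; Yv <- Ys[val_idx, , drop = FALSE]
  net <- mlp_init(d_in)
  H <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- hyper$learning_rate
  step <- 0
  best <- list(val = Inf, W = net$W, b = net$b, epoch = 0L)
  loss_curve <- numeric(0)
  for (epoch in seq_len(hyper$max_epochs)) {
    ord <- sample.int(nrow(Xt))
    nb <- ceiling(nrow(Xt) / hyper$batch_size)
    for (ib in seq_len(nb)) {
      rowsel <- ord[((ib - 1) * hyper$batch_size + 1):
                      min(ib * hyper$batch_size, nrow(Xt))]
      xb <- Xt[rowsel, , drop = FALSE]; yb <- Yt[rowsel, , drop = FALSE]
      fwd <- mlp_forward(net, xb, hyper$dropout, rng_dropout = TRUE)
      dY <- 2 * (fwd$out - yb) / length(yb)
      g <- mlp_backward(net, fwd, dY, hyper$dropout)
      step <- step + 1
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      for (l in seq_len(H)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
        net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
        net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    val_pred <- mlp_forward(net, Xv)$out
    val_mse <- mean((val_pred - Yv)^2)
    if (!is.finite(val_mse)) {
      stop("training diverged (non-finite validation loss) at epoch ", epoch)
    }
    loss_curve <- c(loss_curve, val_mse)
    if (val_mse < best$val - 1e-7) {
      best <- list(val = val_mse, W = net$W, b = net$b, epoch = epoch)
    } else if (epoch - best$epoch >= hyper$patience) {
      break
    } else if ((epoch - best$epoch) %% max(2L, hyper$patience %/% 2) ==
               0) {
      lr <- max(lr * 0.5, 1e-5)   # reduce-on-plateau
    }
  }
  net$W <- best$W; net$b <- best$b
  structure(list(mode = dataset$mode, net = net,
                 x_stats = st_x, y_stats = st_y,
                 limits = limits[DISTAL_DOFS, , drop = FALSE],
                 seed = as.integer(seed),
                 report = list(loss_curve = loss_curve,
                               best_epoch = best$epoch,
                               best_val_mse = best$val,
                               n_train = length(tr_idx),
                               n_val = n_val)),
            class = "mlp_model")
}

check_architecture <- function(model) {
  dims <- model$net$dims
  if (!(length(dims) == 5 && dims[1] %in% c(3L, 7L) &&
        all(dims[2:4] == MLP_HIDDEN) && dims[5] == 4L)) {
    stop("model architecture does not match the fixed ",
         "input-256-256-64-4 layout")
  }
  invisible(model)
}

#' Predict distal joint angles
#'
#' Pure function of the trained weights and the input row(s); dropout is
#' inactive. Outputs are clamped to the distal joint limits so that the
#' displayed virtual arm remains anatomical.
#'
#' @param object An `mlp_model`.
#' @param newdata Numeric matrix (n x 3 for C-, n x 7 for C+) or a single
#'   row as a vector.
#' @param ... Unused.
#' @return n x 4 matrix of distal angles (deg), columns `el_flex`,
#'   `for_sup`, `wr_dev`, `wr_ext`.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  check_architecture(object)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$net$dims[1]) {
    stop(sprintf("input width %d does not match model mode %s (expects %d)",
                 ncol(newdata), object$mode, object$net$dims[1]))
  }
  Xs <- standardize_apply(newdata, object$x_stats)
  Ys <- mlp_forward(object$net, Xs)$out
  n <- nrow(Ys)
  Y <- Ys * rep(object$y_stats$scale, each = n) +
    rep(object$y_stats$center, each = n)
  for (j in seq_along(DISTAL_DOFS)) {
    Y[, j] <- pmin(pmax(Y[, j], object$limits[j, 1]), object$limits[j, 2])
  }
  colnames(Y) <- DISTAL_DOFS
  Y
}

# analytic Jacobian of the (unclamped) prediction w.r.t. the input row,
# 4 x d_in on the original (unstandardized) scales; used by the closed-loop
# user model
predict_jacobian <- function(model, x) {
  net <- model$net
  xs <- (as.numeric(x) - model$x_stats$center) / model$x_stats$scale
  fwd <- mlp_forward(net, matrix(xs, 1))
  H <- length(net$W)
  J <- diag(length(xs))
  for (l in seq_len(H)) {
    J <- J %*% net$W[[l]]
    if (l < H) J <- J * rep(as.numeric(fwd$acts[[l + 1]] > 0),
                            each = nrow(J))
  }
  # chain the standardization scalings
  J <- J / model$x_stats$scale  # rows: d inputs
  J <- t(J) * model$y_stats$scale
  dimnames(J) <- list(DISTAL_DOFS, NULL)
  J
}

#' Offline prediction error (RMSE)
#'
#' Pooled root-mean-square error over all samples and the four distal DoFs,
#' with a per-DoF breakdown, of a model evaluated on a dataset.
#'
#' @param model An `mlp_model`.
#' @param dataset A `training_dataset` with matching input width.
#' @return A list of class `rmse_report`: `pooled` (deg), `per_dof`
#'   (named, deg), `n`.
#' @export
offline_rmse <- function(model, dataset) {
  stopifnot(inherits(dataset, "training_dataset"))
  if (!nrow(dataset$inputs)) stop("empty dataset")
  pred <- predict(model, dataset$inputs)
  err <- pred - dataset$outputs
  per_dof <- sqrt(colMeans(err^2))
  names(per_dof) <- DISTAL_DOFS
  structure(list(pooled = sqrt(mean(err^2)), per_dof = per_dof,
                 n = nrow(err), mode = model$mode),
            class = "rmse_report")
}
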