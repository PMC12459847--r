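#' Multilayer-perceptron classifier specification
#'
#' Architecture and training hyper-parameters of the three-class zone
#' classifier: two hidden layers of 128 and 64 rectified-linear units with
#' dropout 0.5 after each, a 3-unit softmax output trained with sparse
#' categorical cross-entropy and the Adam optimiser (learning rate 0.001)
#' on an 80/20 train/test split.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param dropout_rate Dropout probability after each hidden layer.
#' @param learning_rate Adam learning rate.
#' @param train_fraction Fraction of labeled points used for training.
#' @param max_epochs Training epoch cap.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement) on a 10% validation split of the training fraction.
#' @param seed Seed for split, initialisation, shuffling and dropout.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden_sizes = c(128L, 64L), dropout_rate = 0.5,
                            learning_rate = 0.001, train_fraction = 0.8,
                            max_epochs = 200L, batch_size = 32L,
                            patience = 20L, seed = 1L) {
  stopifnot(all(hidden_sizes > 0), dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, train_fraction > 0, train_fraction < 1,
            max_epochs >= 1, batch_size >= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 train_fraction = train_fraction,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "classifier_spec")
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; when `drop_masks` is supplied (training), inverted dropout
# is applied after each hidden activation
mlp_forward <- function(W, b, X, drop_masks = NULL) {
  acts <- list(X)
  A <- X
  L <- length(W)
  for (l in seq_len(L - 1)) {
    A <- relu(sweep(A %*% W[[l]], 2, b[[l]], `+`))
    if (!is.null(drop_masks)) A <- A * drop_masks[[l]]
    acts[[l + 1]] <- A
  }
  logits <- sweep(A %*% W[[L]], 2, b[[L]], `+`)
  list(acts = acts, probs = softmax_rows(logits))
}

#' Train the zone classifier
#'
#' Fits the multilayer perceptron of a [classifier_spec()] to labeled
#' feature points. Features are z-standardised with training-set moments
#' (zero-variance features standardise to 0); weights use He
#' initialisation; optimisation is minibatch Adam with inverted dropout and
#' early stopping on a validation split. The held-out accuracy is the
#' ratio of correctly predicted test samples.
#'
#' @param points Labeled `data.frame` from [generate_labeled_points()]
#'   (six feature columns plus `label` in `{0, 1, 2}`).
#' @param spec A [classifier_spec()].
#' @return Object of class `zone_classifier` with weights, standardisation
#'   moments, the train/test split, held-out `accuracy` and per-class
#'   `recall`.
#' @export
train_classifier <- function(points, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  fn <- feature_names()
  if (!all(fn %in% names(points)) || is.null(points$label)) {
    stop("points must carry the six features and a label column")
  }
  X <- as.matrix(points[, fn])
  y <- as.integer(points$label)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (length(unique(y)) < 3) stop("all three classes must be present")

  n <- nrow(X)
  idx <- with_seed(derive_seed(spec$seed, "split"), sample.int(n))
  n_tr <- round(spec$train_fraction * n)
  tr <- idx[seq_len(n_tr)]
  te <- idx[-seq_len(n_tr)]
  if (length(unique(y[tr])) < 3) stop("class missing from training split")

  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sdv[sdv < 1e-12] <- 1  # zero-variance feature -> standardised to 0
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)

  sizes <- c(ncol(X), spec$hidden_sizes, 3L)
  L <- length(sizes) - 1
  fit <- with_seed(derive_seed(spec$seed, "train"), {
    W <- lapply(seq_len(L), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                          sd = sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

    # 10% of the training rows held out for early stopping
    n_val <- max(1L, round(0.1 * length(tr)))
    val <- tr[seq_len(n_val)]
    trn <- tr[-seq_len(n_val)]
    Ztr <- Z[trn, , drop = FALSE]; ytr <- y[trn]
    Zval <- Z[val, , drop = FALSE]; yval <- y[val]

    best <- list(W = W, b = b, loss = Inf)
    stall <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(nrow(Ztr))
      for (start in seq(1, nrow(Ztr), by = spec$batch_size)) {
        bi <- ord[start:min(start + spec$batch_size - 1, nrow(Ztr))]
        Xb <- Ztr[bi, , drop = FALSE]; yb <- ytr[bi]
        masks <- NULL
        if (spec$dropout_rate > 0) {
          masks <- lapply(spec$hidden_sizes, function(hh) {
            matrix((stats::runif(length(bi) * hh) >= spec$dropout_rate) /
                     (1 - spec$dropout_rate), length(bi), hh)
          })
        }
        fw <- mlp_forward(W, b, Xb, masks)
        # softmax + cross-entropy gradient
        delta <- fw$probs
        delta[cbind(seq_along(yb), yb + 1L)] <-
          delta[cbind(seq_along(yb), yb + 1L)] - 1
        delta <- delta / length(yb)
        t_step <- t_step + 1
        for (l in L:1) {
          gW <- t(fw$acts[[l]]) %*% delta
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(W[[l]])
            if (!is.null(masks)) delta <- delta * masks[[l - 1]]
            delta <- delta * (fw$acts[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          cor1 <- 1 - beta1^t_step; cor2 <- 1 - beta2^t_step
          W[[l]] <- W[[l]] - spec$learning_rate * (mW[[l]] / cor1) /
            (sqrt(vW[[l]] / cor2) + eps)
          b[[l]] <- b[[l]] - spec$learning_rate * (mb[[l]] / cor1) /
            (sqrt(vb[[l]] / cor2) + eps)
        }
      }
      pv <- mlp_forward(W, b, Zval)$probs
      vloss <- -mean(log(pmax(pv[cbind(seq_along(yval), yval + 1L)], 1e-12)))
      if (vloss < best$loss - 1e-5) {
        best <- list(W = W, b = b, loss = vloss)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= spec$patience) break
      }
    }
    best
  })

  model <- structure(list(W = fit$W, b = fit$b, mu = mu, sd = sdv,
                          feature_names = fn, spec = spec),
                     class = "zone_classifier")
  pred <- predict(model, X[te, , drop = FALSE])
  acc <- mean(pred == y[te])
  recall <- vapply(0:2, function(z) {
    if (!any(y[te] == z)) return(NA_real_)
    mean(pred[y[te] == z] == z)
  }, 0)
  names(recall) <- names(zone_codes())
  model$accuracy <- acc
  model$recall <- recall
  model$test_index <- te
  model
}

#' Predict zone classes for feature rows
#'
#' @param object A `zone_classifier`.
#' @param newdata Numeric matrix or data.frame with the six feature
#'   columns.
#' @param type `"class"` (default, argmax with ties broken toward the
#'   lower class code) or `"prob"`.
#' @param ... Unused.
#' @return Integer class codes or a probability matrix.
#' @export
predict.zone_classifier <- function(object, newdata, type = c("class", "prob"),
                                    ...) {
  type <- match.arg(type)
  X <- as.matrix(if (is.data.frame(newdata)) newdata[, object$feature_names]
                 else newdata)
  Z <- sweep(sweep(X, 2, object$mu), 2, object$sd, `/`)
  probs <- mlp_forward(object$W, object$b, Z)$probs
  if (type == "prob") return(probs)
  # ties break toward the lower class code (rural < fringe < urban)
  apply(probs, 1, function(p) which(p >= max(p) - 1e-12)[1] - 1L)
}

#' @export
print.zone_classifier <- function(x, ...) {
  cat(sprintf("<zone_classifier> hidden %s, held-out accuracy %.4f\n",
              paste(x$spec$hidden_sizes, collapse = "/"),
              x$accuracy))
  invisible(x)
}

#' Classify a feature grid into zones
#'
#' Applies a trained classifier to every unmasked feature cell; masked
#' cells carry nodata.
#'
#' @param features A [assemble_features()] grid.
#' @param model A trained `zone_classifier`.
#' @param date_tag Date label for the resulting map.
#' @return A [zone_map()].
#' @export
classify_zones <- function(features, model, date_tag = "t") {
  stopifnot(inherits(features, "feature_grid"),
            inherits(model, "zone_classifier"))
  if (!identical(names(features$features), model$feature_names)) {
    stop("feature schema mismatch between grid and classifier")
  }
  ok <- which(!features$mask)
  X <- vapply(features$features, function(m) m[ok], numeric(length(ok)))
  out <- matrix(NA_integer_, nrow(features$mask), ncol(features$mask))
  if (length(ok)) out[ok] <- predict(model, X)
  zone_map(out, date_tag, features$cell_size_m, features$origin)
}
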