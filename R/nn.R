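# Single-hidden-layer sigmoidal network trained by full-batch resilient
# backpropagation (iRprop-) on weighted cross-entropy, with early stopping
# on validation loss. Small (2-5 hidden neurons) and seed-deterministic.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; X already normalized. Returns list(H, out).
.nn_forward <- function(par, X) {
  H <- .sigmoid(sweep(X %*% par$W1, 2, par$b1, "+"))
  out <- .sigmoid(drop(H %*% par$W2) + par$b2)
  list(H = H, out = out)
}

# Weighted cross-entropy loss and gradient.
.nn_loss_grad <- function(par, X, y, w) {
  fw <- .nn_forward(par, X)
  o <- pmin(pmax(fw$out, 1e-12), 1 - 1e-12)
  loss <- -sum(w * (y * log(o) + (1 - y) * log(1 - o))) / sum(w)
  delta_o <- w * (o - y) / sum(w)          # d loss / d pre-activation(out)
  gW2 <- drop(t(fw$H) %*% delta_o)
  gb2 <- sum(delta_o)
  delta_h <- outer(delta_o, par$W2) * fw$H * (1 - fw$H)
  gW1 <- t(X) %*% delta_h
  gb1 <- colSums(delta_h)
  list(loss = loss, grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# iRprop- update of one parameter block.
.rprop_step <- function(p, g, g_prev, step) {
  s <- sign(g)
  same <- s * sign(g_prev)
  step <- ifelse(same > 0, pmin(step * 1.2, 1),
                 ifelse(same < 0, pmax(step * 0.5, 1e-6), step))
  g <- ifelse(same < 0, 0, g)  # iRprop-: forget gradient after sign flip
  list(p = p - sign(g) * step, g = g, step = step)
}

#' Specification of the radiomic neural-network classifier
#'
#' A fully connected network with one hidden layer of `hidden_neurons`
#' sigmoidal units and one sigmoidal output; inputs are affinely mapped to
#' `[-1, 1]` using training-set min/max. The trainable parameter count is
#' `(n_inputs + 1) * h + (h + 1)` — 13 for 2 inputs and 3 hidden neurons.
#' Positive (LN-metastatic) cases receive `positive_weight` times the loss
#' weight of negatives to compensate for class imbalance.
#'
#' @param input_features ordered character vector of input feature names.
#' @param hidden_neurons hidden layer size.
#' @param positive_weight loss weight multiplier for positive cases
#'   (default 4).
#' @param output_threshold classification threshold on the (averaged)
#'   network output (default 0.5).
#' @return a `model_spec` object.
#' @export
model_spec <- function(input_features, hidden_neurons = 3,
                       positive_weight = 4, output_threshold = 0.5) {
  stopifnot(length(input_features) >= 1, hidden_neurons >= 1,
            positive_weight > 0)
  structure(list(input_features = as.character(input_features),
                 hidden_neurons = as.integer(hidden_neurons),
                 positive_weight = positive_weight,
                 output_threshold = output_threshold),
            class = "model_spec")
}

#' @param spec a [model_spec()].
#' @rdname model_spec
#' @export
n_parameters <- function(spec) {
  d <- length(spec$input_features)
  h <- spec$hidden_neurons
  (d + 1L) * h + (h + 1L)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Neural-network spec:", length(x$input_features), "inputs (",
      paste(x$input_features, collapse = ", "), "),",
      x$hidden_neurons, "hidden neurons,", n_parameters(x),
      "parameters\n")
  invisible(x)
}

# Fit the [-1,1] normalization on a training matrix.
.fit_norm <- function(X) {
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  flat <- which(mx - mn < 1e-15)
  if (length(flat)) {
    stop("constant input feature(s) on the training set: ",
         paste(colnames(X)[flat], collapse = ", "))
  }
  list(min = mn, max = mx)
}

.apply_norm <- function(X, norm) {
  sweep(sweep(X, 2, norm$min), 2, (norm$max - norm$min) / 2, "/") - 1
}

# Pull the input matrix + labels for a spec from a cohort.
.model_xy <- function(cohort, spec) {
  df <- as.data.frame(cohort)
  miss <- setdiff(spec$input_features, names(df))
  if (length(miss)) stop("missing input feature(s): ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(df[, spec$input_features, drop = FALSE])
  list(X = X, y = cohort$ln_histology)
}

#' Train one network
#'
#' Full-batch resilient backpropagation on weighted cross-entropy with
#' random initialization (seeded), early stopping on validation loss
#' (default patience 25 epochs, at most `max_epochs`), returning the
#' parameters of the best-validation epoch.
#'
#' @param train,validation cohorts with the spec's input features and
#'   `ln_histology`.
#' @param spec a [model_spec()].
#' @param seed integer initialization seed.
#' @param max_epochs,patience training-length controls.
#' @return an object of class `rad_nn` with a `predict()` method.
#' @export
train_network <- function(train, validation, spec, seed = 1,
                          max_epochs = 500, patience = 25) {
  stopifnot(inherits(spec, "model_spec"))
  tr <- .model_xy(train, spec)
  va <- .model_xy(validation, spec)
  if (length(unique(tr$y)) < 2) stop("training set must contain both classes")
  norm <- .fit_norm(tr$X)
  Xt <- .apply_norm(tr$X, norm)
  Xv <- .apply_norm(va$X, norm)
  d <- ncol(Xt)
  h <- spec$hidden_neurons
  w_tr <- ifelse(tr$y == 1, spec$positive_weight, 1)
  w_va <- ifelse(va$y == 1, spec$positive_weight, 1)
  par <- with_seed_local(seed, list(
    W1 = matrix(runif(d * h, -0.5, 0.5), d, h),
    b1 = runif(h, -0.5, 0.5),
    W2 = runif(h, -0.5, 0.5),
    b2 = runif(1, -0.5, 0.5)))
  g_prev <- lapply(par, function(p) p * 0)
  step <- lapply(par, function(p) p * 0 + 0.05)
  val_loss <- function(p) {
    o <- pmin(pmax(.nn_forward(p, Xv)$out, 1e-12), 1 - 1e-12)
    -sum(w_va * (va$y * log(o) + (1 - va$y) * log(1 - o))) / sum(w_va)
  }
  best <- par
  best_val <- val_loss(par)
  wait <- 0
  epochs_run <- 0
  for (ep in seq_len(max_epochs)) {
    lg <- .nn_loss_grad(par, Xt, tr$y, w_tr)
    for (nm in names(par)) {
      up <- .rprop_step(par[[nm]], lg$grad[[nm]], g_prev[[nm]], step[[nm]])
      par[[nm]] <- up$p
      g_prev[[nm]] <- up$g
      step[[nm]] <- up$step
    }
    epochs_run <- ep
    vl <- val_loss(par)
    if (vl < best_val - 1e-9) {
      best_val <- vl
      best <- par
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  structure(list(par = best, norm = norm, spec = spec, seed = seed,
                 val_loss = best_val, epochs = epochs_run),
            class = "rad_nn")
}

#' @export
predict.rad_nn <- function(object, newdata, type = c("response", "class"),
                           ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) {
    newdata[, object$spec$input_features, drop = FALSE]
  } else {
    as.matrix(as.data.frame(newdata)[, object$spec$input_features,
                                     drop = FALSE])
  }
  o <- .nn_forward(object$par, .apply_norm(X, object$norm))$out
  if (type == "class") as.integer(o >= object$spec$output_threshold) else o
}

#' @export
print.rad_nn <- function(x, ...) {
  print(x$spec)
  cat("Trained for", x$epochs, "epochs; best validation loss",
      format(x$val_loss, digits = 4), "\n")
  invisible(x)
}
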