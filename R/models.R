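#' Specify a probabilistic binary classifier
#'
#' Two families are supported: `"logistic"` (a zero-hidden-layer network with
#' optional weight decay, i.e. L2-regularized logistic regression trained by
#' gradient descent) and `"feedforward"` (fully-connected rectifier network
#' with dropout). The grids used in the experiments are layers {1, 3}, hidden
#' size {128, 256}, dropout {0.25, 0.75}, learning rate {1e-4, 1e-5} for
#' feedforward networks, and weight decay {0, 0.01, 0.001} for the logistic
#' family; any admissible value is accepted here.
#'
#' @param family `"logistic"` or `"feedforward"`.
#' @param hidden_layers,hidden_size Feedforward only: number and width of
#'   hidden layers.
#' @param dropout Feedforward only: dropout probability in `[0, 1)`.
#' @param weight_decay Logistic only: L2 penalty coefficient (>= 0).
#' @param learning_rate Adam step size for the model parameters. This is
#'   distinct from the exponentiated-gradient rate `eta` of the DRO weight
#'   update.
#' @param init_seed Seed for parameter initialization.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("logistic", "feedforward"),
                       hidden_layers = 1L, hidden_size = 128L,
                       dropout = 0.25, weight_decay = 0,
                       learning_rate = 1e-4, init_seed = 1L) {
  family <- match.arg(family)
  stopifnot(learning_rate > 0)
  if (family == "feedforward") {
    stopifnot(hidden_layers >= 1, hidden_size >= 1,
              dropout >= 0, dropout < 1)
    if (weight_decay != 0) {
      abort("configuration error: weight decay applies to the logistic family only",
            class = "groupdro_config_error")
    }
  } else {
    stopifnot(weight_decay >= 0)
  }
  structure(list(family = family,
                 hidden_layers = if (family == "feedforward") as.integer(hidden_layers),
                 hidden_size = if (family == "feedforward") as.integer(hidden_size),
                 dropout = if (family == "feedforward") dropout,
                 weight_decay = if (family == "logistic") weight_decay,
                 learning_rate = learning_rate,
                 init_seed = as.integer(init_seed)),
            class = "model_spec")
}

#' Build a model from a spec
#'
#' Parameters are initialized reproducibly from `init_seed` with
#' Glorot-uniform weights and zero biases.
#'
#' @param spec A [model_spec()].
#' @param m Feature dimension (>= 1).
#' @return A `dro_model` with elements `spec`, `m` and `layers` (a list of
#'   `W`/`b` pairs; the final layer feeds a logistic output unit).
#' @export
build_model <- function(spec, m) {
  stopifnot(inherits(spec, "model_spec"), m >= 1)
  dims <- if (spec$family == "logistic") c(m, 1L) else {
    c(m, rep(spec$hidden_size, spec$hidden_layers), 1L)
  }
  layers <- withr::with_seed(derive_seed(spec$init_seed, "init"), {
    lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]; fan_out <- dims[l + 1]
      r <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(runif(fan_in * fan_out, -r, r), fan_in, fan_out),
           b = rep(0, fan_out))
    })
  })
  structure(list(spec = spec, m = as.integer(m), layers = layers),
            class = "dro_model")
}

#' @export
print.dro_model <- function(x, ...) {
  cat("<dro_model>", x$spec$family, "| m =", x$m,
      "| parameters:", n_params(x), "\n")
  invisible(x)
}

n_params <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

relu <- function(x) pmax(x, 0)

# forward pass; when train = TRUE, inverted dropout masks are drawn from the
# current RNG state and cached for backprop
model_forward <- function(model, X, train = FALSE) {
  L <- length(model$layers)
  acts <- vector("list", L + 1)   # layer inputs
  masks <- vector("list", L)
  acts[[1]] <- X
  p_drop <- if (model$spec$family == "feedforward") model$spec$dropout else 0
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% model$layers[[l]]$W, 2, model$layers[[l]]$b, "+")
    if (l < L) {
      h <- relu(z)
      if (train && p_drop > 0) {
        mask <- matrix(runif(length(h)) >= p_drop, nrow(h), ncol(h)) /
          (1 - p_drop)
        h <- h * mask
        masks[[l]] <- mask
      }
      acts[[l + 1]] <- h
    } else {
      acts[[l + 1]] <- plogis(drop(z))
    }
  }
  list(score = acts[[L + 1]], acts = acts, masks = masks)
}

# gradients of sum_i w_i * bce(y_i, s_i) wrt all parameters; fwd from
# model_forward(train = TRUE)
model_backward <- function(model, fwd, y, w) {
  L <- length(model$layers)
  grads <- vector("list", L)
  # d/dz_out of w * bce = w * (s - y)
  delta <- matrix(w * (fwd$score - y), ncol = 1)
  for (l in rev(seq_len(L))) {
    a_in <- fwd$acts[[l]]
    gW <- crossprod(a_in, delta)
    gb <- colSums(delta)
    wd <- model$spec$weight_decay %||% 0
    if (wd > 0) gW <- gW + wd * model$layers[[l]]$W
    grads[[l]] <- list(W = gW, b = gb)
    if (l > 1) {
      delta <- delta %*% t(model$layers[[l]]$W)
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(model, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(model$layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW_hat <- s$mW / (1 - beta1^t); vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t); vb_hat <- s$vb / (1 - beta2^t)
    model$layers[[l]]$W <- model$layers[[l]]$W -
      lr * mW_hat / (sqrt(vW_hat) + eps)
    model$layers[[l]]$b <- model$layers[[l]]$b -
      lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(model = model, state = state)
}

#' Predict risk scores
#'
#' Evaluation-mode prediction (dropout disabled): deterministic given the
#' parameters.
#'
#' @param object A `dro_model`.
#' @param newdata A cohort, data frame containing the feature columns, or a
#'   numeric matrix with `m` columns.
#' @param ... Unused.
#' @return Numeric vector of scores in (0, 1) (up to floating-point
#'   saturation; downstream losses clip at [clip_prob()]'s epsilon).
#' @export
predict.dro_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(X) != object$m) {
    abort(paste0("dimension mismatch: model expects m = ", object$m,
                 ", got ", ncol(X)))
  }
  model_forward(object, X, train = FALSE)$score
}

# flatten parameters for trajectory comparisons / checkpoints
model_params <- function(model) {
  unlist(lapply(model$layers, function(l) c(as.numeric(l$W), l$b)))
}

#' Serialize a model to JSON
#'
#' @param model A `dro_model`.
#' @param path Output path.
#' @return `path` invisibly; `read_model()` returns the restored model.
#' @export
write_model <- function(model, path) {
  payload <- list(
    spec = model$spec[!vapply(model$spec, is.null, logical(1))],
    m = model$m,
    layers = lapply(model$layers, function(l) {
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(model_spec, as.list(x$spec))
  layers <- lapply(seq_len(nrow_safe(x$layers)), function(l) {
    row <- if (is.data.frame(x$layers)) x$layers[l, ] else x$layers[[l]]
    W <- matrix(unlist(row$W), unlist(row$dim)[1], unlist(row$dim)[2])
    list(W = W, b = as.numeric(unlist(row$b)))
  })
  structure(list(spec = spec, m = as.integer(x$m), layers = layers),
            class = "dro_model")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
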