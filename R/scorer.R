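#' Reference linear scorer
#'
#' A single-logit logistic scorer: `score(x) = plogis(w'x + b)`. This is
#' exactly the positive-class probability of a two-output linear layer
#' followed by softmax (the softmax of two logits depends only on their
#' difference), so scores — and therefore the ranking margin — live on
#' \[0, 1\]. The scorer is deliberately small: it makes every training
#' property checkable at desk scale, while the trainer itself accepts
#' any scorer exposing the same `forward`/`grad_params` interface.
#'
#' @param input_dim Number of input features.
#' @param init_sd Standard deviation of the Gaussian weight
#'   initialisation (0 gives the all-ties start).
#' @param seed Integer seed for the initialisation draw.
#' @return A `fairdx_scorer` with elements `params` (`w`, `b`),
#'   `forward(params, X)` returning scores in (0, 1), and
#'   `grad_params(params, X, g_score)` back-propagating a gradient on
#'   the scores to the parameters.
#' @export
linear_scorer <- function(input_dim, init_sd = 0.01, seed = 1L) {
  stopifnot(input_dim >= 1L)
  params <- with_seed_(derive_seed(seed, 17L), {
    list(w = rnorm(input_dim, sd = init_sd), b = rnorm(1, sd = init_sd))
  })
  structure(list(
    input_dim = input_dim,
    params = params,
    forward = function(params, X) plogis(drop(X %*% params$w) + params$b),
    # g_score = dL/d(score); chain through the logistic: ds/dz = s(1-s)
    grad_params = function(params, X, g_score) {
      s <- plogis(drop(X %*% params$w) + params$b)
      g_z <- g_score * s * (1 - s)
      list(w = drop(crossprod(X, g_z)), b = sum(g_z))
    }
  ), class = "fairdx_scorer")
}

#' @export
print.fairdx_scorer <- function(x, ...) {
  cat("<fairdx_scorer> linear,", x$input_dim, "inputs\n")
  invisible(x)
}

# seed derivation: keeps every derived seed a valid 32-bit integer
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt)) %% 2147483647)
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# Payload matrix for a record set: numeric feature columns f0..fk when
# present, otherwise images loaded from the `path` column, preprocessed
# to [0,1] grayscale at `side` x `side` and flattened row-wise.
payload_matrix <- function(records, side = 32L) {
  fcols <- grep("^f[0-9]+$", names(records), value = TRUE)
  if (length(fcols)) return(feature_matrix(records))
  if (!"path" %in% names(records))
    abort("records carry neither feature columns f0..fk nor an image path column",
          class = "fairdx_spec_error")
  rows <- lapply(records$path, function(p) {
    img <- load_image(p)
    img <- resize_to_input(img, side = side, channels = 1L)
    as.numeric(img) / 255
  })
  do.call(rbind, rows)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
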