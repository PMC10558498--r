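#' Training configuration
#'
#' Bundles the hyperparameters of the training protocol. Defaults
#' follow the evaluation protocol: Adam with learning rate 1e-4, batch
#' size 96, 20 epochs, model selection by highest development-set AUC.
#' The margin default of 0.1 lives on the probability scale of the
#' scorer output.
#'
#' @param loss_mode One of `"proposed"` (worst-group marginal ranking
#'   loss), `"bce"` (binary cross-entropy baseline), `"oversample"`
#'   (bce on a minority-class oversampled multiset).
#' @param margin Ranking margin for the proposed loss.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size (>= 2).
#' @param epochs Number of passes over the training data (>= 0).
#' @param dev_fraction Fraction of training *patients* carved out as the
#'   development set used for model selection; in (0, 1).
#' @param seed Integer seed governing initialisation, data order,
#'   dev-set carving, oversampling and augmentation.
#' @param negative_buffer FIFO buffer size of recent negative
#'   predictions appended (as constants) to the ranking-loss reference
#'   pool; 0 disables it.
#' @param init_sd Weight initialisation scale of the reference scorer.
#' @param augment Apply random rotation/flip augmentation to image
#'   payloads during training.
#' @param input_side Image side length the scorer consumes.
#' @return A `train_config` object.
#' @export
train_config <- function(loss_mode = c("proposed", "bce", "oversample"),
                         margin = 0.1, learning_rate = 1e-4, batch_size = 96L,
                         epochs = 20L, dev_fraction = 0.1, seed = 1L,
                         negative_buffer = 0L, init_sd = 0.01,
                         augment = FALSE, input_side = 32L) {
  loss_mode <- match.arg(loss_mode)
  if (batch_size < 2L) abort("batch_size must be >= 2", class = "fairdx_spec_error")
  if (dev_fraction <= 0 || dev_fraction >= 1)
    abort("dev_fraction must be in (0,1)", class = "fairdx_spec_error")
  if (epochs < 0L) abort("epochs must be >= 0", class = "fairdx_spec_error")
  if (margin < 0) abort("margin must be >= 0", class = "fairdx_spec_error")
  structure(list(loss_mode = loss_mode, margin = margin,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dev_fraction = dev_fraction,
                 seed = as.integer(seed), negative_buffer = as.integer(negative_buffer),
                 init_sd = init_sd, augment = isTRUE(augment),
                 input_side = as.integer(input_side)),
            class = "train_config")
}

#' Oversample the minority class to balance class counts
#'
#' Returns an index multiset over `records` in which minority-class
#' indices are resampled with replacement until both classes have the
#' majority count; deterministic under `seed`.
#'
#' @param records Data frame with a 0/1 `label` column.
#' @param seed Integer seed.
#' @return Integer index vector (a multiset over `seq_len(nrow(records))`).
#' @export
oversample_minority <- function(records, seed = 1L) {
  y <- records$label
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    abort("oversampling needs both classes present", class = "fairdx_spec_error")
  if (n1 == n0) return(seq_along(y))
  minority <- if (n1 < n0) which(y == 1L) else which(y == 0L)
  need <- abs(n0 - n1)
  extra <- with_seed_(derive_seed(seed, 29L),
                      sample(minority, need, replace = TRUE))
  c(seq_along(y), extra)
}

#' Train a scorer under one of three loss modes
#'
#' Implements the fairness-aware training procedure and its two
#' baselines. Every epoch visits the training data in a seeded random
#' order in minibatches; per batch:
#' * `proposed` — score the batch, compute batch-level Pairwise
#'   Fairness per subgroup, select the subgroup with the lowest value,
#'   and take an Adam step on the marginal ranking loss of that
#'   subgroup's positives against all batch negatives. Batches with no
#'   positives or no negatives are skipped (counted in the history).
#' * `bce` — standard binary cross-entropy.
#' * `oversample` — bce over a minority-oversampled index multiset
#'   (class counts equalised once, before training).
#'
#' A development set is carved from the training records at patient
#' level; after each epoch the development AUC is recorded and the
#' parameters of the epoch with the highest development AUC are the
#' ones returned (ties resolve to the earliest such epoch).
#'
#' @param records Training records (features `f0..fk` or image `path`).
#' @param assignment A `group_assignment` over the records (required
#'   for `loss_mode = "proposed"`; used only for the per-step log
#'   otherwise).
#' @param config A [train_config()].
#' @param scorer Optional scorer to start from; defaults to a fresh
#'   [linear_scorer()] sized to the payload.
#' @return A `trained_scorer`: list with `scorer` (best parameters
#'   installed), `history` tibble (epoch, mean_loss, dev_auc,
#'   n_skipped), `best_epoch`, `selection_log` tibble (epoch, step,
#'   category, batch_pf) for the proposed mode, and `config`.
#' @export
train_scorer <- function(records, assignment = NULL, config = train_config("bce"),
                         scorer = NULL) {
  stopifnot(inherits(config, "train_config"))
  y <- as.integer(records$label)
  if (length(unique(y)) < 2L)
    abort("training set must contain both classes", class = "fairdx_spec_error")
  groups <- if (!is.null(assignment)) unname(assignment$group_of[records$sample_id])
            else rep("all", length(y))
  if (config$loss_mode == "proposed" && length(unique(groups)) < 2L)
    abort("proposed loss needs >= 2 subgroups", class = "fairdx_spec_error")

  # patient-level dev carve-out for model selection
  pats <- unique(records$patient_id)
  n_dev <- max(1L, round(config$dev_fraction * length(pats)))
  if (n_dev >= length(pats))
    abort("dev_fraction leaves no training patients", class = "fairdx_spec_error")
  dev_pats <- with_seed_(derive_seed(config$seed, 41L), sample(pats, n_dev))
  is_dev <- records$patient_id %in% dev_pats
  # a dev carve-out that loses a class cannot rank; fall back to training AUC
  dev_usable <- length(unique(y[is_dev])) == 2L

  X <- payload_matrix(records, side = config$input_side)
  if (is.null(scorer)) scorer <- linear_scorer(ncol(X), config$init_sd, config$seed)
  params <- scorer$params
  opt <- adam_init(params)

  tr_idx <- which(!is_dev)
  if (length(unique(y[tr_idx])) < 2L)
    abort("training split lost a class; lower dev_fraction", class = "fairdx_spec_error")
  if (config$loss_mode == "oversample")
    tr_idx <- tr_idx[oversample_minority(records[tr_idx, , drop = FALSE],
                                         seed = config$seed)]

  history <- list(); sel_log <- list()
  snapshots <- list()
  neg_buffer <- numeric(0)

  for (ep in seq_len(config$epochs)) {
    ord <- with_seed_(derive_seed(config$seed, 100L + ep), sample(tr_idx))
    Xe <- X
    if (config$augment && "path" %in% names(records) &&
        !length(grep("^f[0-9]+$", names(records)))) {
      Xe <- augment_payloads(records, config, ep)
    }
    losses <- c(); skipped <- 0L
    nb <- length(ord) %/% config$batch_size +
      as.integer(length(ord) %% config$batch_size > 0L)
    for (bi in seq_len(nb)) {
      rows <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, length(ord))]
      Xb <- Xe[rows, , drop = FALSE]
      yb <- y[rows]
      p <- scorer$forward(params, Xb)
      if (config$loss_mode %in% c("bce", "oversample")) {
        eps <- 1e-12
        losses <- c(losses, -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps)))
        g_score <- (p - yb) / (p * (1 - p) + eps) / length(yb)  # d(bce)/d(score)
        g <- scorer$grad_params(params, Xb, g_score)
        st <- adam_step(params, g, opt, config$learning_rate)
        params <- st$params; opt <- st$state
      } else {
        batch <- scored_set(p, yb, groups[rows])
        step <- fairness_training_step(batch, config$margin,
                                       extra_negatives = neg_buffer)
        if (step$skip) { skipped <- skipped + 1L; next }
        sel <- step$selection
        idx_p <- which(yb == 1L & groups[rows] == sel$selected)
        idx_n <- which(yb == 0L)
        gr <- ranking_loss_grad(p[idx_p], c(p[idx_n], neg_buffer), config$margin)
        g_score <- numeric(length(yb))
        g_score[idx_p] <- gr$d_p
        g_score[idx_n] <- gr$d_n[seq_along(idx_n)]  # buffered negatives are constants
        g <- scorer$grad_params(params, Xb, g_score)
        st <- adam_step(params, g, opt, config$learning_rate)
        params <- st$params; opt <- st$state
        losses <- c(losses, step$loss)
        sel_log[[length(sel_log) + 1L]] <- tibble::tibble(
          epoch = ep, step = bi, category = sel$selected,
          batch_pf = unname(sel$batch_pf[sel$selected]))
        if (config$negative_buffer > 0L) {
          neg_buffer <- c(neg_buffer, p[idx_n])
          if (length(neg_buffer) > config$negative_buffer)
            neg_buffer <- neg_buffer[(length(neg_buffer) - config$negative_buffer + 1L):length(neg_buffer)]
        }
      }
    }
    eval_idx <- if (dev_usable) which(is_dev) else tr_idx
    s_eval <- scorer$forward(params, X[eval_idx, , drop = FALSE])
    dev_auc <- auc_mw(s_eval[y[eval_idx] == 1L], s_eval[y[eval_idx] == 0L])
    history[[ep]] <- tibble::tibble(epoch = ep,
                                    mean_loss = if (length(losses)) mean(losses) else NA_real_,
                                    dev_auc = dev_auc, n_skipped = skipped)
    snapshots[[ep]] <- params
  }

  history <- if (length(history)) do.call(rbind, history)
             else tibble::tibble(epoch = integer(0), mean_loss = numeric(0),
                                 dev_auc = numeric(0), n_skipped = integer(0))
  best_epoch <- if (nrow(history)) which.max(history$dev_auc) else 0L
  if (best_epoch > 0L) scorer$params <- snapshots[[best_epoch]]
  structure(list(scorer = scorer, history = history, best_epoch = best_epoch,
                 selection_log = if (length(sel_log)) do.call(rbind, sel_log)
                                 else tibble::tibble(epoch = integer(0), step = integer(0),
                                                     category = character(0), batch_pf = numeric(0)),
                 config = config),
            class = "trained_scorer")
}

augment_payloads <- function(records, config, epoch) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    img <- load_image(records$path[i])
    img <- augment_image(img, seed = derive_seed(config$seed, 10000L * epoch + i))
    img <- resize_to_input(img, side = config$input_side, channels = 1L)
    as.numeric(img) / 255
  })
  do.call(rbind, rows)
}

#' @export
print.trained_scorer <- function(x, ...) {
  cat("<trained_scorer>", x$config$loss_mode, "mode,",
      nrow(x$history), "epochs, best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Score records with a trained scorer
#'
#' Order-preserving, one finite score per record; scores do not depend
#' on any evaluation batching.
#'
#' @param trained A `trained_scorer` (or bare `fairdx_scorer`).
#' @param records Records whose payloads match the scorer input.
#' @param assignment Optional `group_assignment` to attach categories.
#' @return A [scored_set()].
#' @export
predict_scores <- function(trained, records, assignment = NULL) {
  scorer <- if (inherits(trained, "trained_scorer")) trained$scorer else trained
  stopifnot(inherits(scorer, "fairdx_scorer"))
  if (nrow(records) == 0L)
    return(scored_set(numeric(0), integer(0), character(0), character(0)))
  side <- if (inherits(trained, "trained_scorer")) trained$config$input_side else 32L
  X <- payload_matrix(records, side = side)
  if (ncol(X) != scorer$input_dim)
    abort(sprintf("payload has %d features but scorer expects %d", ncol(X), scorer$input_dim),
          class = "fairdx_spec_error")
  s <- scorer$forward(scorer$params, X)
  if (!all(is.finite(s))) abort("non-finite score produced", class = "fairdx_spec_error")
  groups <- if (!is.null(assignment)) unname(assignment$group_of[records$sample_id]) else NULL
  scored_set(s, records$label, groups, records$sample_id)
}
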