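#' Marginal ranking loss
#'
#' Mean hinge penalty over all positive/negative prediction pairs:
#' `L = (1/n) * sum max(0, -x_p + x_n + margin)` where `n` is the number
#' of pairs. A pair contributes whenever the positive fails to outscore
#' the negative by at least the margin, so minimising L pushes the
#' selected subgroup's positives above the negative pool — the
#' quantity Pairwise Fairness measures.
#'
#' @param x_p Predictions for positive samples of the selected subgroup.
#' @param x_n Predictions for negative samples of the reference pool.
#' @param margin Nonnegative slack below which a ranking counts as
#'   incorrect or too close.
#' @return Nonnegative scalar.
#' @export
marginal_ranking_loss <- function(x_p, x_n, margin = 0.1) {
  if (!length(x_p) || !length(x_n))
    abort("marginal ranking loss needs nonempty x_p and x_n (skip the step instead)",
          class = "fairdx_spec_error")
  if (!all(is.finite(c(x_p, x_n))) || margin < 0)
    abort("predictions must be finite and margin >= 0", class = "fairdx_spec_error")
  h <- outer(-x_p, x_n, `+`) + margin    # -x_p + x_n + margin
  mean(pmax(h, 0))
}

# Subgradient of the marginal ranking loss wrt x_p and x_n.
# d/dx_p = -(# active pairs in row)/n ; d/dx_n = (# active in column)/n.
# The hinge boundary (h == 0) takes subgradient 0.
ranking_loss_grad <- function(x_p, x_n, margin) {
  h <- outer(-x_p, x_n, `+`) + margin
  act <- h > 0
  n <- length(x_p) * length(x_n)
  list(d_p = -rowSums(act) / n, d_n = colSums(act) / n)
}

#' Select the subgroup with the lowest batch Pairwise Fairness
#'
#' Computes batch-level Pairwise Fairness for every category with at
#' least one positive in the batch (against all batch negatives) and
#' picks the minimum; exact ties break lexicographically so reruns are
#' deterministic. When no category is eligible or the batch has no
#' negatives, a skip signal is returned rather than an error: the
#' training step is simply not performed on such a batch.
#'
#' @param batch A [scored_set()] for the current minibatch.
#' @return A `batch_selection`: list with `selected` (category or `NA`),
#'   `batch_pf` (named PF vector over eligible categories), `eligible`
#'   (named logical over all batch categories), `skip` (logical).
#' @export
select_worst_group <- function(batch) {
  stopifnot(inherits(batch, "scored_set"))
  cats <- sort_c(unique(batch$groups))
  has_pos <- vapply(cats, function(cc) any(batch$labels == 1L & batch$groups == cc), logical(1))
  eligible <- setNames(has_pos, cats)
  if (!any(batch$labels == 0L) || !any(has_pos))
    return(structure(list(selected = NA_character_, batch_pf = numeric(0),
                          eligible = eligible, skip = TRUE),
                     class = "batch_selection"))
  pf <- vapply(cats[has_pos], function(cc) pairwise_fairness(batch, cc), numeric(1))
  sel <- names(pf)[which.min(pf)]   # names are sorted; which.min takes first = lexicographic tie-break
  structure(list(selected = sel, batch_pf = pf, eligible = eligible, skip = FALSE),
            class = "batch_selection")
}

#' One fairness-aware training-step computation
#'
#' The core of the fairness-aware procedure: estimate Pairwise Fairness
#' per subgroup on the batch, select the worst subgroup, and return the
#' marginal ranking loss of that subgroup's positives against the
#' negative pool (all batch negatives, optionally extended by a FIFO
#' buffer of recent negatives). Ineligible batches return a skip signal
#' and no loss.
#'
#' @param batch A [scored_set()] of minibatch predictions.
#' @param margin Ranking margin, lives on the probability scale.
#' @param extra_negatives Optional numeric vector of buffered negative
#'   predictions appended to the reference pool for the loss (they do
#'   not influence worst-group selection, which is batch-local).
#' @return List with `loss` (scalar or `NULL` when skipped), `selection`
#'   (a `batch_selection`), `skip`.
#' @export
fairness_training_step <- function(batch, margin = 0.1, extra_negatives = NULL) {
  sel <- select_worst_group(batch)
  if (sel$skip) return(list(loss = NULL, selection = sel, skip = TRUE))
  x_p <- batch$scores[batch$labels == 1L & batch$groups == sel$selected]
  x_n <- c(batch$scores[batch$labels == 0L], extra_negatives)
  list(loss = marginal_ranking_loss(x_p, x_n, margin), selection = sel, skip = FALSE)
}
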