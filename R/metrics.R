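#' Bundle scores, labels and group categories
#'
#' The substrate for all fairness metrics: parallel vectors of model
#' scores (higher = more disease-like), binary labels, and subgroup
#' categories.
#'
#' @param scores Numeric vector of model outputs, finite.
#' @param labels 0/1 vector, 1 = disease-positive.
#' @param groups Character vector of category labels (optional when only
#'   overall metrics are needed).
#' @param sample_id Optional ids carried through to reports.
#' @return A `scored_set` object.
#' @export
scored_set <- function(scores, labels, groups = NULL, sample_id = NULL) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  n <- length(scores)
  if (length(labels) != n || (!is.null(groups) && length(groups) != n))
    abort("scores, labels and groups must have equal length", class = "fairdx_spec_error")
  if (n && !all(is.finite(scores)))
    abort("scores must be finite", class = "fairdx_spec_error")
  if (n && !all(labels %in% c(0L, 1L)))
    abort("labels must be 0/1", class = "fairdx_spec_error")
  if (is.null(groups)) groups <- rep("all", n)
  structure(list(scores = scores, labels = labels,
                 groups = as.character(groups),
                 sample_id = if (is.null(sample_id)) as.character(seq_len(n)) else as.character(sample_id)),
            class = "scored_set")
}

#' @export
print.scored_set <- function(x, ...) {
  cat("<scored_set>", length(x$scores), "samples,",
      sum(x$labels), "positives,", length(unique(x$groups)), "groups\n")
  invisible(x)
}

# Mann-Whitney AUC with half credit for ties, via average ranks:
# U = sum(rank of positives in pooled sample) - n_p(n_p+1)/2
# equals #{f_p > f_n} + 0.5 #{f_p = f_n}.
auc_mw <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Pairwise Fairness of one subgroup
#'
#' The marginal pairwise equal opportunity metric: the probability that
#' the model scores a randomly selected positive sample of the subgroup
#' above a randomly selected negative sample of the *entire* dataset,
#' with ties receiving half credit. It is the bipartite-ranking AUC of
#' the subgroup's positives against the global negative pool, hence
#' scale- and classification-threshold-invariant.
#'
#' @param s A [scored_set()].
#' @param category Subgroup category to evaluate.
#' @return A probability in \[0, 1\].
#' @export
pairwise_fairness <- function(s, category) {
  stopifnot(inherits(s, "scored_set"))
  pos <- s$scores[s$labels == 1L & s$groups == category]
  neg <- s$scores[s$labels == 0L]
  if (!length(pos))
    abort(paste0("Pairwise Fairness undefined: no positives in group '", category, "'"),
          class = "fairdx_metric_undefined")
  if (!length(neg))
    abort("Pairwise Fairness undefined: no negatives in the dataset",
          class = "fairdx_metric_undefined")
  auc_mw(pos, neg)
}

#' Pairwise Fairness for every eligible subgroup
#'
#' @param s A [scored_set()].
#' @return Named numeric vector over categories with at least one
#'   positive, ordered lexicographically. Categories without positives
#'   are omitted (the metric is undefined there).
#' @export
pairwise_fairness_all <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  cats <- sort_c(unique(s$groups))
  eligible <- cats[vapply(cats, function(cc) any(s$labels == 1L & s$groups == cc), logical(1))]
  vapply(eligible, function(cc) pairwise_fairness(s, cc), numeric(1))
}

#' Pairwise fairness difference (PFD)
#'
#' The spread of Pairwise Fairness across subgroups: maximum minus
#' minimum over categories that have at least one positive. A large PFD
#' means the model ranks positives of some subgroups far less reliably
#' than others — an unfair ranker.
#'
#' @param s A [scored_set()] whose `groups` carry the audit categories.
#' @return List with `per_group` (named PF vector over eligible
#'   categories), `pfd` (max - min), and `excluded` (categories with no
#'   positives).
#' @export
pfd <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  pf <- pairwise_fairness_all(s)
  cats <- sort_c(unique(s$groups))
  if (length(pf) < 2L)
    abort("PFD undefined: fewer than 2 categories with positives",
          class = "fairdx_metric_undefined")
  list(per_group = pf, pfd = max(pf) - min(pf),
       excluded = setdiff(cats, names(pf)))
}

#' Overall AUC of a scored set
#'
#' Mann-Whitney AUC (half tie credit) of all positives against all
#' negatives; identical to [pairwise_fairness()] when the whole set is
#' one group.
#'
#' @param s A [scored_set()].
#' @return A probability in \[0, 1\].
#' @export
overall_auc <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  pos <- s$scores[s$labels == 1L]
  neg <- s$scores[s$labels == 0L]
  if (!length(pos) || !length(neg))
    abort("AUC undefined: single-class input", class = "fairdx_metric_undefined")
  auc_mw(pos, neg)
}

#' Relative change between a baseline and a proposed value
#'
#' `(proposed - baseline) / baseline`, a signed fraction; multiply by
#' 100 to report a percent as in comparison tables.
#'
#' @param x_baseline,x_proposed Numeric scalars; baseline nonzero.
#' @return Signed fraction.
#' @export
relative_change <- function(x_baseline, x_proposed) {
  if (!is.finite(x_baseline) || x_baseline == 0)
    abort("relative change undefined for zero baseline", class = "fairdx_metric_undefined")
  (x_proposed - x_baseline) / x_baseline
}

#' Full fairness report for a scored set
#'
#' Per-group Pairwise Fairness and within-group AUC, plus overall AUC
#' and PFD.
#'
#' @param s A [scored_set()].
#' @return A `fairness_report`: list with `per_group` tibble (category,
#'   n_pos_in_group, n_neg_global, pairwise_fairness, group_auc),
#'   `overall_auc`, `pfd`, `excluded`.
#' @export
fairness_report <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  p <- pfd(s)
  nneg <- sum(s$labels == 0L)
  rows <- lapply(names(p$per_group), function(cc) {
    in_g <- s$groups == cc
    gpos <- s$scores[in_g & s$labels == 1L]
    gneg <- s$scores[in_g & s$labels == 0L]
    tibble::tibble(category = cc,
                   n_pos_in_group = length(gpos),
                   n_neg_global = nneg,
                   pairwise_fairness = unname(p$per_group[cc]),
                   group_auc = if (length(gneg)) auc_mw(gpos, gneg) else NA_real_)
  })
  structure(list(per_group = do.call(rbind, rows),
                 overall_auc = overall_auc(s),
                 pfd = p$pfd, excluded = p$excluded),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat("<fairness_report> overall AUC", sprintf("%.4f", x$overall_auc),
      " PFD", sprintf("%.4f", x$pfd), "\n")
  print(x$per_group)
  invisible(x)
}

#' Aggregate fairness reports over repeated runs
#'
#' Mean and sample standard deviation (denominator n - 1) of Pairwise
#' Fairness and group AUC per category, and of overall AUC and PFD, over
#' a list of reports from repeated splits.
#'
#' @param reports List of `fairness_report`s sharing the same
#'   categories.
#' @return List with `per_group` tibble (mean/sd columns), and
#'   mean/sd scalars for `overall_auc` and `pfd`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L, all(vapply(reports, inherits, logical(1), "fairness_report")))
  cats <- sort_c(unique(unlist(lapply(reports, function(r) r$per_group$category))))
  per_group <- do.call(rbind, lapply(cats, function(cc) {
    pf <- vapply(reports, function(r) {
      i <- match(cc, r$per_group$category)
      if (is.na(i)) NA_real_ else r$per_group$pairwise_fairness[i]
    }, numeric(1))
    ga <- vapply(reports, function(r) {
      i <- match(cc, r$per_group$category)
      if (is.na(i)) NA_real_ else r$per_group$group_auc[i]
    }, numeric(1))
    tibble::tibble(category = cc,
                   pf_mean = mean(pf, na.rm = TRUE), pf_sd = sd(pf, na.rm = TRUE),
                   group_auc_mean = mean(ga, na.rm = TRUE), group_auc_sd = sd(ga, na.rm = TRUE))
  }))
  aucs <- vapply(reports, function(r) r$overall_auc, numeric(1))
  pfds <- vapply(reports, function(r) r$pfd, numeric(1))
  list(per_group = per_group,
       overall_auc_mean = mean(aucs), overall_auc_sd = sd(aucs),
       pfd_mean = mean(pfds), pfd_sd = sd(pfds),
       n_repeats = length(reports))
}

#' Read a score file
#'
#' Delimited text with header `sample_id,score`.
#'
#' @param path File path.
#' @return Tibble with `sample_id`, `score`.
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "score") %in% names(df)))
    abort("score file needs columns sample_id,score", class = "fairdx_io_error")
  tibble::tibble(sample_id = as.character(df$sample_id), score = as.numeric(df$score))
}

#' Write a score file
#' @param s A [scored_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(s, path) {
  write.csv(data.frame(sample_id = s$sample_id, score = s$scores),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a fairness report as structured text (JSON) and read it back
#'
#' Round-trips exactly: numbers are serialised at full precision.
#'
#' @param report A `fairness_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- list(per_group = as.data.frame(report$per_group),
              overall_auc = report$overall_auc,
              pfd = report$pfd, excluded = report$excluded)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_group = tibble::as_tibble(obj$per_group),
                 overall_auc = obj$overall_auc, pfd = obj$pfd,
                 excluded = if (length(obj$excluded)) as.character(obj$excluded) else character(0)),
            class = "fairness_report")
}
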