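#' Configure a full comparison experiment
#'
#' Describes one end-to-end evaluation: a data source, the subgroup
#' definitions to audit, the repeated patient-level split plan, and the
#' training protocol applied under each loss mode. Within a repeat all
#' loss modes share the same split and the same initialisation seed, so
#' the comparison is paired.
#'
#' @param data Either a `bias_scenario` or a metadata file path.
#' @param groupings Named list of [grouping_spec()]s; at least one.
#' @param plan A [split_plan()].
#' @param train Template [train_config()] whose hyperparameters are
#'   reused for every mode (the seed is overridden per repeat).
#' @param modes Loss modes to compare; the first is the baseline for
#'   relative changes (default `c("bce", "proposed")`).
#' @param intersectional Also evaluate the cross of the two groupings
#'   with the largest baseline PFD (needs >= 2 groupings).
#' @param out_dir Optional directory: per-repeat reports, scores, the
#'   selection log, the comparison table and a run manifest are written
#'   there.
#' @param seed Base seed for generation and splitting.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(data, groupings, plan = split_plan(),
                              train = train_config("bce"),
                              modes = c("bce", "proposed"),
                              intersectional = FALSE,
                              out_dir = NULL, seed = 1L) {
  if (!length(groupings)) abort("need at least one grouping", class = "fairdx_spec_error")
  if (is.null(names(groupings)))
    names(groupings) <- vapply(groupings, function(g) g$name, character(1))
  stopifnot(all(vapply(groupings, inherits, logical(1), "grouping_spec")))
  if (length(modes) < 2L) abort("need >= 2 modes to compare", class = "fairdx_spec_error")
  structure(list(data = data, groupings = groupings, plan = plan, train = train,
                 modes = modes, intersectional = isTRUE(intersectional),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Pick the attribute pair for the intersectional audit
#'
#' Returns the two groupings with the largest baseline PFD; ties break
#' lexicographically by grouping name so reruns are deterministic.
#'
#' @param baseline_pfds Named numeric vector: grouping name -> baseline
#'   mean PFD, for at least two groupings.
#' @return Character vector of the two selected grouping names.
#' @export
intersectional_pick <- function(baseline_pfds) {
  if (length(baseline_pfds) < 2L)
    abort("intersectional pick needs >= 2 groupings", class = "fairdx_spec_error")
  nm <- names(baseline_pfds)
  ord <- order(-baseline_pfds, nm, method = "radix")
  nm[ord[1:2]]
}

#' Run the repeated-split comparison experiment
#'
#' For every repeat of the split plan: train one scorer per loss mode
#' on the identical training side (shared initialisation seed), score
#' the held-out test side, and compute a fairness report under every
#' grouping. Reports are aggregated as mean and sample standard
#' deviation over repeats, and relative changes between the baseline
#' (first mode) and each other mode are computed on the aggregated
#' means. When `intersectional = TRUE`, the two groupings with the
#' largest baseline PFD are crossed and the intersection is evaluated
#' from the same persisted per-repeat scores — no re-training.
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_result`: list with `comparison` (tibble, one
#'   row per grouping x non-baseline mode), `aggregates` (nested:
#'   grouping -> mode -> [aggregate_reports()] output), `reports`
#'   (nested per-repeat `fairness_report`s), `intersection` (grouping
#'   name or `NULL`), `records`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  records <- if (inherits(cfg$data, "bias_scenario"))
    generate_cohort(cfg$data, seed = cfg$seed) else read_metadata(cfg$data)
  assignments <- lapply(cfg$groupings, function(g) assign_groups(records, g))
  splits <- make_splits(records, cfg$plan)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # reports[[grouping]][[mode]][[repeat]]; scored[[mode]][[repeat]]
  scored <- lapply(cfg$modes, function(m) vector("list", length(splits)))
  names(scored) <- cfg$modes
  sel_logs <- list()
  for (r in seq_along(splits)) {
    tr <- records[records$sample_id %in% splits[[r]]$train, , drop = FALSE]
    te <- records[records$sample_id %in% splits[[r]]$test, , drop = FALSE]
    rep_seed <- cfg$plan$seeds[r]
    for (m in cfg$modes) {
      tc <- cfg$train
      tc$loss_mode <- m
      tc$seed <- rep_seed            # paired: same init and data order per repeat
      # the training-time grouping is the first configured grouping
      tr_assign <- assign_groups(tr, cfg$groupings[[1L]])
      fit <- train_scorer(tr, tr_assign, tc)
      s <- predict_scores(fit, te)
      scored[[m]][[r]] <- s
      if (m == "proposed" && nrow(fit$selection_log))
        sel_logs[[length(sel_logs) + 1L]] <-
          cbind(tibble::tibble(repeat_ = r), fit$selection_log)
      if (!is.null(out))
        write_scores(s, file.path(out, sprintf("scores_%s_rep%d.csv", m, r)))
    }
  }

  evaluate_grouping <- function(gname, assignment) {
    lapply(setNames(cfg$modes, cfg$modes), function(m) {
      lapply(seq_along(splits), function(r) {
        s <- scored[[m]][[r]]
        g <- unname(assignment$group_of[s$sample_id])
        rep_set <- scored_set(s$scores, s$labels, g, s$sample_id)
        rp <- fairness_report(rep_set)
        if (!is.null(out))
          write_report(rp, file.path(out, sprintf("report_%s_%s_rep%d.json",
                                                  gname, m, r)))
        rp
      })
    })
  }

  reports <- lapply(names(assignments), function(gn)
    evaluate_grouping(gn, assignments[[gn]]))
  names(reports) <- names(assignments)

  intersection <- NULL
  if (cfg$intersectional && length(assignments) >= 2L) {
    base_pfds <- vapply(reports, function(by_mode)
      mean(vapply(by_mode[[1L]], function(r) r$pfd, numeric(1))), numeric(1))
    pick <- intersectional_pick(base_pfds)
    cross_a <- cross_groups(assignments[[pick[1]]], assignments[[pick[2]]])
    intersection <- cross_a$spec$name
    reports[[intersection]] <- evaluate_grouping(intersection, cross_a)
  }

  aggregates <- lapply(reports, function(by_mode) lapply(by_mode, aggregate_reports))
  comparison <- build_comparison(aggregates, baseline = cfg$modes[1L])
  if (!is.null(out)) {
    write.csv(comparison, file.path(out, "comparison.csv"), row.names = FALSE)
    if (length(sel_logs))
      write.csv(do.call(rbind, sel_logs), file.path(out, "selection_log.csv"),
                row.names = FALSE)
    manifest <- list(seed = cfg$seed, modes = cfg$modes,
                     n_repeats = cfg$plan$n_repeats,
                     test_fraction = cfg$plan$test_fraction,
                     split_seeds = cfg$plan$seeds,
                     groupings = names(cfg$groupings),
                     intersection = intersection,
                     train = unclass(cfg$train))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(comparison = comparison, aggregates = aggregates,
                 reports = reports, intersection = intersection,
                 records = records),
            class = "experiment_result")
}

# one row per grouping x non-baseline mode; relative changes on means
build_comparison <- function(aggregates, baseline) {
  rows <- list()
  for (gn in names(aggregates)) {
    ag <- aggregates[[gn]]
    b <- ag[[baseline]]
    for (m in setdiff(names(ag), baseline)) {
      p <- ag[[m]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        grouping = gn, baseline = baseline, mode = m,
        baseline_auc_mean = b$overall_auc_mean, baseline_auc_sd = b$overall_auc_sd,
        mode_auc_mean = p$overall_auc_mean, mode_auc_sd = p$overall_auc_sd,
        auc_rel_change_pct = 100 * relative_change(b$overall_auc_mean, p$overall_auc_mean),
        baseline_pfd_mean = b$pfd_mean, baseline_pfd_sd = b$pfd_sd,
        mode_pfd_mean = p$pfd_mean, mode_pfd_sd = p$pfd_sd,
        pfd_rel_change_pct = 100 * relative_change(b$pfd_mean, p$pfd_mean))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$comparison)
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' Schema (all keys lowercase): `data` (either `scenario: paperlike`
#' with optional `divisor`/`modality`, or an explicit scenario with
#' `groups`, `n`, `prevalence`, `separability`, or `metadata: <path>`);
#' `groupings` (list of `name`, `attributes`, optional per-attribute
#' `bins` with `breaks`/`labels`, optional `category_map`); `split`
#' (`n_repeats`, `test_fraction`); `train` (any [train_config()]
#' field); `modes`; `intersectional`; `seed`; `out_dir`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  data <- if (!is.null(y$data$metadata)) {
    y$data$metadata
  } else if (identical(y$data$scenario, "paperlike")) {
    paperlike_scenario(divisor = y$data$divisor %||% 20,
                       modality = y$data$modality %||% "features")
  } else {
    sc <- y$data
    bias_scenario(sc$groups, unlist(sc$n), unlist(sc$prevalence),
                  unlist(sc$separability),
                  modality = sc$modality %||% "features")
  }
  groupings <- lapply(y$groupings, function(g) {
    bins <- lapply(g$bins, function(b)
      list(breaks = vapply(b$breaks, function(v)
             if (identical(v, ".inf") || identical(v, "inf")) Inf
             else if (identical(v, "-.inf") || identical(v, "-inf")) -Inf
             else as.numeric(v), numeric(1)),
           labels = as.character(b$labels)))
    grouping_spec(g$name, unlist(g$attributes), bins = bins,
                  category_map = g$category_map %||% list())
  })
  names(groupings) <- vapply(groupings, function(g) g$name, character(1))
  plan <- split_plan(n_repeats = y$split$n_repeats %||% 5L,
                     test_fraction = y$split$test_fraction %||% 0.2,
                     seed = seed)
  tr <- y$train %||% list()
  train <- train_config(loss_mode = tr$loss_mode %||% "bce",
                        margin = tr$margin %||% 0.1,
                        learning_rate = tr$learning_rate %||% 1e-4,
                        batch_size = tr$batch_size %||% 96L,
                        epochs = tr$epochs %||% 20L,
                        dev_fraction = tr$dev_fraction %||% 0.1,
                        seed = seed,
                        negative_buffer = tr$negative_buffer %||% 0L,
                        augment = tr$augment %||% FALSE)
  experiment_config(data, groupings, plan, train,
                    modes = unlist(y$modes %||% c("bce", "proposed")),
                    intersectional = y$intersectional %||% FALSE,
                    out_dir = y$out_dir, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
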