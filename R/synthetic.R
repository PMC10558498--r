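#' Describe a biased synthetic cohort
#'
#' A bias scenario captures the three mechanisms by which cohort
#' composition biases a trained classifier: per-group prevalence
#' imbalance, per-group sample-size imbalance, and per-group
#' class-separability disparity. Samples are grouped into patients
#' (1 + Poisson(1) images each); all images of a patient share the
#' patient's group, label and attributes, which makes patient-level
#' splitting consequential.
#'
#' @param groups Character vector of group category names.
#' @param n Per-group image counts.
#' @param prevalence Per-group disease prevalence, each in (0, 1).
#' @param separability Per-group mean shift `d` of the informative
#'   signal in units of the unit-variance noise; the best possible
#'   scorer then attains within-group AUC `pnorm(d / sqrt(2))`.
#' @param modality `"features"` (numeric feature vectors) or
#'   `"toy-images"` (32x32 grayscale discs written as PNG files).
#' @param n_noise Number of pure-noise feature dimensions.
#' @param marker_strength Strength of the group-marker channels: each
#'   group has an indicator feature equal to `marker_strength` for its
#'   members (0 otherwise), standing in for the group-correlated
#'   appearance cues real images carry. 0 removes group information
#'   from the payload entirely.
#' @param image_side Side length of toy images.
#' @param attribute Name of the grouping attribute carried in the
#'   metadata (default `"race"`, mirroring a race-like grouping).
#' @return A `bias_scenario` object.
#' @export
bias_scenario <- function(groups, n, prevalence, separability,
                          modality = c("features", "toy-images"),
                          n_noise = 8L, marker_strength = 1.0,
                          image_side = 32L, attribute = "race") {
  modality <- match.arg(modality)
  k <- length(groups)
  stopifnot(length(n) == k, length(prevalence) == k, length(separability) == k)
  if (any(n < 1L)) abort("group sizes must be >= 1", class = "fairdx_spec_error")
  if (any(prevalence <= 0 | prevalence >= 1))
    abort("prevalences must lie in (0,1)", class = "fairdx_spec_error")
  if (any(separability < 0)) abort("separability must be >= 0", class = "fairdx_spec_error")
  structure(list(groups = as.character(groups), n = as.integer(n),
                 prevalence = prevalence, separability = separability,
                 modality = modality, n_noise = as.integer(n_noise),
                 marker_strength = marker_strength,
                 image_side = as.integer(image_side), attribute = attribute),
            class = "bias_scenario")
}

#' The default "paperlike" benchmark scenario
#'
#' Three race-like groups whose sizes are proportional to
#' 38,457 : 30,239 : 9,191 (divided by `divisor`, default 20, for a
#' cohort of about 4,000 images), prevalences 0.37 / 0.70 / 0.40, and
#' separabilities 1.8 / 1.8 / 1.0 — the smallest group is also the
#' hardest. This reproduces, at desk scale, both imbalance mechanisms a
#' COVID-19 chest X-ray cohort exhibits across race groups: one group
#' far more prevalent-positive than the others, and one group much
#' smaller and less separable.
#'
#' @param divisor Scale divisor applied to the reference sizes.
#' @param modality Passed to [bias_scenario()].
#' @return A `bias_scenario`.
#' @export
paperlike_scenario <- function(divisor = 20, modality = "features") {
  bias_scenario(groups = c("Black", "Other races", "White"),
                n = round(c(30239, 9191, 38457) / divisor),
                prevalence = c(0.70, 0.40, 0.37),
                separability = c(1.8, 1.0, 1.8),
                modality = modality)
}

#' Generate a biased synthetic cohort
#'
#' Labels are Bernoulli(prevalence of the patient's group) at patient
#' level; each image of a positive patient carries informative signal
#' `d_g` on feature `f0` (a mean shift in unit Gaussian noise), so the
#' Bayes-optimal linear scorer reads `f0` and attains within-group AUC
#' `pnorm(d_g / sqrt(2))`. Noise features are pure N(0,1); group-marker
#' features are scaled indicators. In toy-image mode the signal is a
#' centred disc whose intensity is proportional to `d_g`, plus pixel
#' noise and a per-group corner marker; images are written under
#' `image_dir`.
#'
#' @param scenario A [bias_scenario()].
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param image_dir Directory for toy-image files (required for the
#'   toy-images modality).
#' @return A tibble of sample records: `sample_id`, `patient_id`,
#'   `label`, the grouping attribute, `sex`, `age`, and feature columns
#'   `f0..fk` or a `path` column.
#' @export
generate_cohort <- function(scenario, seed = 1L, image_dir = NULL) {
  stopifnot(inherits(scenario, "bias_scenario"))
  if (scenario$modality == "toy-images" && is.null(image_dir))
    abort("toy-images modality needs image_dir", class = "fairdx_spec_error")
  with_seed_(derive_seed(seed, 7L), {
    recs <- list()
    pid0 <- 0L
    for (gi in seq_along(scenario$groups)) {
      g <- scenario$groups[gi]
      n_img <- scenario$n[gi]
      # patients of 1 + Poisson(1) images until the group quota is filled
      sizes <- integer(0)
      while (sum(sizes) < n_img) sizes <- c(sizes, 1L + rpois(1L, 1))
      sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_img)
      sizes <- sizes[sizes > 0L]
      lab <- rbinom(length(sizes), 1L, scenario$prevalence[gi])
      age <- round(runif(length(sizes), 30, 90))
      sex <- sample(c("Male", "Female"), length(sizes), replace = TRUE)
      for (pi in seq_along(sizes)) {
        pid0 <- pid0 + 1L
        pid <- sprintf("P%05d", pid0)
        for (im in seq_len(sizes[pi])) {
          recs[[length(recs) + 1L]] <- list(
            patient_id = pid, label = lab[pi], group = g,
            sex = sex[pi], age = age[pi], d = scenario$separability[gi],
            gidx = gi)
        }
      }
    }
    df <- do.call(rbind, lapply(recs, as.data.frame))
    df$sample_id <- sprintf("S%05d", seq_len(nrow(df)))
    n <- nrow(df)
    if (scenario$modality == "features") {
      f0 <- df$d * df$label + rnorm(n)
      noise <- matrix(rnorm(n * scenario$n_noise), n)
      markers <- outer(df$gidx, seq_along(scenario$groups), `==`) * scenario$marker_strength
      feats <- cbind(f0, noise, markers)
      colnames(feats) <- paste0("f", seq_len(ncol(feats)) - 1L)
      out <- cbind(df[c("sample_id", "patient_id", "label")],
                   setNames(df["group"], scenario$attribute),
                   df[c("sex", "age")], as.data.frame(feats))
    } else {
      dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
      side <- scenario$image_side
      cx <- (side + 1) / 2
      disc <- outer(seq_len(side), seq_len(side),
                    function(i, j) (i - cx)^2 + (j - cx)^2 <= (side / 4)^2)
      paths <- character(n)
      for (i in seq_len(n)) {
        img <- matrix(rnorm(side * side), side)
        img <- img + disc * (df$d[i] * df$label[i])
        # corner marker: group-correlated appearance cue
        img[1:3, 1:3] <- img[1:3, 1:3] + df$gidx[i]
        img <- pmin(pmax((img + 4) / 10, 0), 1)   # map to [0,1] for PNG
        paths[i] <- file.path(image_dir, paste0(df$sample_id[i], ".png"))
        png::writePNG(img, paths[i])
      }
      out <- cbind(df[c("sample_id", "patient_id", "label")],
                   setNames(df["group"], scenario$attribute),
                   df[c("sex", "age")], data.frame(path = paths))
    }
    tibble::as_tibble(out)
  })
}

#' Plan repeated patient-level splits
#'
#' @param n_repeats Number of repeated holdout splits (default 5).
#' @param test_fraction Fraction of patients held out (default 0.2).
#' @param seed Base seed; each repeat uses a seed derived from it.
#' @return A `split_plan` object.
#' @export
split_plan <- function(n_repeats = 5L, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    abort("test_fraction must be in (0,1)", class = "fairdx_spec_error")
  structure(list(n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 seeds = vapply(seq_len(n_repeats), function(r) derive_seed(seed, 500L + r),
                                integer(1))),
            class = "split_plan")
}

#' Repeated patient-level train/test splits
#'
#' Each repeat holds out `round(test_fraction * #patients)` whole
#' patients, so no patient ever contributes images to both sides —
#' the split rule that prevents identity leakage in repeated-image
#' cohorts.
#'
#' @param records Records with a `patient_id` column.
#' @param plan A [split_plan()].
#' @return List of length `n_repeats`; each element a list with
#'   `train` and `test` sample-id character vectors.
#' @export
make_splits <- function(records, plan) {
  stopifnot(inherits(plan, "split_plan"))
  pats <- unique(records$patient_id)
  if (length(pats) < 2L)
    abort("patient-level splitting needs >= 2 patients", class = "fairdx_spec_error")
  n_test <- round(plan$test_fraction * length(pats))
  n_test <- min(max(n_test, 1L), length(pats) - 1L)
  lapply(plan$seeds, function(s) {
    test_pats <- with_seed_(s, sample(pats, n_test))
    in_test <- records$patient_id %in% test_pats
    list(train = records$sample_id[!in_test], test = records$sample_id[in_test])
  })
}
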