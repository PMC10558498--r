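#' Define a grouping over one or two protected attributes
#'
#' A grouping spec names the attribute(s) a fairness audit conditions on
#' and, for numeric attributes such as age, how values are binned. Bins
#' are half-open intervals `[lo, hi)` except the last, which is closed
#' above, so thresholds `c(-Inf, 65, 75, Inf)` give the categories
#' "<65", "[65,75)" and ">=75" and the value 75 falls in the upper bin.
#'
#' @param name Grouping name, e.g. `"age"` or `"race"`.
#' @param attributes Character vector of 1 or 2 attribute names found in
#'   the sample metadata.
#' @param bins For each numeric attribute, a named list entry giving
#'   `breaks` (increasing, covering the attribute's domain; use
#'   `-Inf`/`Inf` for open ends) and `labels` (one per bin). Categorical
#'   attributes need no entry: their observed values pass through.
#' @param category_map Optional named list per attribute collapsing raw
#'   categorical values into coarser categories (e.g. several race
#'   codes into "Other races"). Values absent from the map are an
#'   error, never silently pooled.
#' @return A `grouping_spec` object.
#' @examples
#' grouping_spec("age", "age",
#'   bins = list(age = list(breaks = c(-Inf, 75, Inf),
#'                          labels = c("<75 yrs", ">=75 yrs"))))
#' @export
grouping_spec <- function(name, attributes, bins = list(), category_map = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  attributes <- as.character(attributes)
  if (length(attributes) < 1L || length(attributes) > 2L)
    abort("a grouping uses 1 or 2 source attributes", class = "fairdx_spec_error")
  for (a in names(bins)) {
    b <- bins[[a]]
    if (is.null(b$breaks) || is.null(b$labels) ||
        length(b$labels) != length(b$breaks) - 1L || is.unsorted(b$breaks, strictly = TRUE))
      abort(sprintf("invalid bins for attribute '%s': need strictly increasing breaks and one label per bin", a),
            class = "fairdx_spec_error")
  }
  structure(list(name = name, attributes = attributes, bins = bins,
                 category_map = category_map),
            class = "grouping_spec")
}

#' @export
print.grouping_spec <- function(x, ...) {
  cat("<grouping_spec>", x$name, "on", paste(x$attributes, collapse = " x "), "\n")
  invisible(x)
}

bin_numeric <- function(x, breaks, labels, attr_name, sample_ids) {
  bad <- !is.finite(x)
  if (any(bad))
    abort(paste0("non-finite '", attr_name, "' for samples: ",
                 paste(sample_ids[bad], collapse = ", ")),
          class = "fairdx_attribute_error")
  # [lo, hi) bins, last bin closed above
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = FALSE)
  out <- idx < 1L | idx > length(labels)
  if (any(out))
    abort(paste0("'", attr_name, "' outside all bins for samples: ",
                 paste(sample_ids[out], collapse = ", ")),
          class = "fairdx_attribute_error")
  labels[idx]
}

categorize_one <- function(records, spec, attr_name) {
  if (!attr_name %in% names(records))
    abort(paste0("attribute '", attr_name, "' missing from records"),
          class = "fairdx_attribute_error")
  x <- records[[attr_name]]
  ids <- records$sample_id
  miss <- is.na(x)
  if (any(miss))
    abort(paste0("missing '", attr_name, "' for samples: ",
                 paste(ids[miss], collapse = ", ")),
          class = "fairdx_attribute_error")
  if (!is.null(spec$bins[[attr_name]])) {
    b <- spec$bins[[attr_name]]
    cat_vals <- bin_numeric(as.numeric(x), b$breaks, b$labels, attr_name, ids)
  } else {
    cat_vals <- as.character(x)
    cm <- spec$category_map[[attr_name]]
    if (!is.null(cm)) {
      unknown <- !cat_vals %in% names(cm)
      if (any(unknown))
        abort(paste0("values of '", attr_name, "' not in category map: ",
                     paste(unique(cat_vals[unknown]), collapse = ", ")),
              class = "fairdx_attribute_error")
      cat_vals <- unlist(cm)[cat_vals]
    }
  }
  unname(cat_vals)
}

#' Assign every sample to exactly one subgroup category
#'
#' Deterministically maps each record to a category under a grouping
#' spec. With two source attributes the category is the intersection
#' label `"catA x catB"`. Missing or out-of-range attribute values are
#' an error naming the offending sample ids: silently pooling unknowns
#' into a catch-all bin would corrupt a fairness audit.
#'
#' @param records Data frame of sample metadata with at least
#'   `sample_id` plus the spec's source attributes.
#' @param spec A [grouping_spec()].
#' @return A `group_assignment`: list with `spec`, `group_of` (named
#'   character vector, sample_id -> category) and `categories`
#'   (observed categories, sorted lexicographically in the C locale for
#'   stable downstream tie-breaking).
#' @export
assign_groups <- function(records, spec) {
  stopifnot(inherits(spec, "grouping_spec"), is.data.frame(records))
  if (anyDuplicated(records$sample_id))
    abort("duplicate sample_id in records", class = "fairdx_spec_error")
  parts <- lapply(spec$attributes, function(a) categorize_one(records, spec, a))
  cats <- if (length(parts) == 1L) parts[[1L]] else paste(parts[[1L]], parts[[2L]], sep = " x ")
  group_of <- setNames(cats, records$sample_id)
  structure(list(spec = spec, group_of = group_of,
                 categories = sort_c(unique(cats))),
            class = "group_assignment")
}

# lexicographic sort independent of the session locale
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x)
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment>", x$spec$name, "-", length(x$group_of), "samples,",
      length(x$categories), "categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Cross two group assignments into an intersectional assignment
#'
#' The category of each sample is `"catA x catB"`. Combinations that are
#' never observed do not appear in `categories`, so a 2 x 3 cross with
#' one empty cell yields 5 categories. Intersectional groups expose
#' biases that single-attribute audits mask.
#'
#' @param a,b `group_assignment`s over the same sample ids.
#' @return A `group_assignment` for the intersection grouping.
#' @export
cross_groups <- function(a, b) {
  stopifnot(inherits(a, "group_assignment"), inherits(b, "group_assignment"))
  ids_a <- names(a$group_of); ids_b <- names(b$group_of)
  if (length(ids_a) != length(ids_b) || !setequal(ids_a, ids_b))
    abort("assignments cover different sample sets", class = "fairdx_spec_error")
  gb <- b$group_of[ids_a]
  cats <- paste(a$group_of, gb, sep = " x ")
  spec <- grouping_spec(paste(a$spec$name, b$spec$name, sep = " x "),
                        unique(c(a$spec$attributes, b$spec$attributes))[1:2])
  structure(list(spec = spec, group_of = setNames(cats, ids_a),
                 categories = sort_c(unique(cats))),
            class = "group_assignment")
}

#' Summarize a cohort per subgroup
#'
#' One row per category with positive count, total count, and percent
#' positive (rounded half-up to 2 decimals), the shape of a standard
#' cohort-characteristics table.
#'
#' @param records Data frame with `sample_id` and binary `label`.
#' @param assignment A `group_assignment` over the same samples.
#' @return A tibble with columns `category`, `positive`, `total`,
#'   `percent`.
#' @export
summarize_cohort <- function(records, assignment) {
  stopifnot(inherits(assignment, "group_assignment"))
  lab <- records$label
  if (!all(lab %in% c(0L, 1L)))
    abort("labels must be 0/1", class = "fairdx_spec_error")
  g <- assignment$group_of[records$sample_id]
  cats <- assignment$categories
  pos <- vapply(cats, function(cc) sum(lab[g == cc]), numeric(1))
  tot <- vapply(cats, function(cc) sum(g == cc), numeric(1))
  tibble::tibble(category = cats, positive = as.integer(pos),
                 total = as.integer(tot),
                 percent = unname(round_half_up(100 * pos / tot, 2)))
}

#' Read a sample metadata table
#'
#' Comma-separated UTF-8 text with a header; required columns
#' `sample_id`, `patient_id`, `label` (0/1); any further columns are
#' attributes, an optional `path` column points at image files, and
#' `f0..fk` columns hold numeric features.
#'
#' @param path File path.
#' @return A tibble of sample records.
#' @export
read_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  need <- c("sample_id", "patient_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste("metadata missing required columns:", paste(miss, collapse = ", ")),
          class = "fairdx_io_error")
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  if (any(!nzchar(df$patient_id)))
    abort("empty patient_id", class = "fairdx_io_error")
  if (!all(df$label %in% c(0L, 1L)))
    abort("label column must be 0/1", class = "fairdx_io_error")
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample_id", class = "fairdx_io_error")
  tibble::as_tibble(df)
}

#' Write a sample metadata table
#'
#' Inverse of [read_metadata()]; writes UTF-8 CSV with header.
#'
#' @param records Data frame of sample records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# matrix of feature columns f0..fk, ordered by index
feature_matrix <- function(records) {
  fcols <- grep("^f[0-9]+$", names(records), value = TRUE)
  if (!length(fcols))
    abort("records carry no feature columns f0..fk", class = "fairdx_spec_error")
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  m <- as.matrix(records[, fcols, drop = FALSE])
  storage.mode(m) <- "double"
  if (!all(is.finite(m)))
    abort("non-finite feature values", class = "fairdx_spec_error")
  m
}
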