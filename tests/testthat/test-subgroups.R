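make_records <- function(age, sex = NULL, race = NULL, label = NULL) {
  n <- length(age)
  df <- tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)),
                       patient_id = sprintf("p%02d", seq_len(n)),
                       label = if (is.null(label)) rep(0L, n) else label,
                       age = age)
  if (!is.null(sex)) df$sex <- sex
  if (!is.null(race)) df$race <- race
  df
}

age2_spec <- grouping_spec("age", "age",
  bins = list(age = list(breaks = c(-Inf, 75, Inf),
                         labels = c("<75 yrs", ">=75 yrs"))))
age3_spec <- grouping_spec("age", "age",
  bins = list(age = list(breaks = c(-Inf, 65, 75, Inf),
                         labels = c("<65 yrs", "65-75 yrs", ">=75 yrs"))))

test_that("numeric age binning is half-open with the last bin closed above", {
  rec <- make_records(c(74, 75, 76))
  a <- assign_groups(rec, age2_spec)
  expect_equal(unname(a$group_of), c("<75 yrs", ">=75 yrs", ">=75 yrs"))

  rec2 <- make_records(c(64, 65, 70, 74.9, 75, 90))
  b <- assign_groups(rec2, age3_spec)
  expect_equal(unname(b$group_of),
               c("<65 yrs", "65-75 yrs", "65-75 yrs", "65-75 yrs",
                 ">=75 yrs", ">=75 yrs"))
  expect_equal(b$categories, c("65-75 yrs", "<65 yrs", ">=75 yrs")) # C-locale sort
})

test_that("missing or out-of-range attribute values raise errors naming samples", {
  rec <- make_records(c(50, NA, 70))
  expect_error(assign_groups(rec, age2_spec), "s02", class = "fairdx_attribute_error")
  expect_error(assign_groups(make_records(50), grouping_spec("sex", "sex")),
               class = "fairdx_attribute_error")
  bounded <- grouping_spec("age", "age",
    bins = list(age = list(breaks = c(40, 60, 80), labels = c("40-60", "60-80"))))
  expect_error(assign_groups(make_records(c(50, 85)), bounded),
               "s02", class = "fairdx_attribute_error")
  # category map refuses unknown values rather than pooling them
  race_spec <- grouping_spec("race", "race",
    category_map = list(race = list(White = "White", Black = "Black",
                                    Asian = "Other races")))
  rec2 <- make_records(c(50, 50), race = c("White", "Pacific"))
  expect_error(assign_groups(rec2, race_spec), "Pacific",
               class = "fairdx_attribute_error")
})

test_that("category maps collapse race codes per-dataset", {
  race_spec <- grouping_spec("race", "race",
    category_map = list(race = list(White = "Other races", Asian = "Other races",
                                    Black = "Black")))
  rec <- make_records(c(1, 2, 3), race = c("White", "Asian", "Black"))
  a <- assign_groups(rec, race_spec)
  expect_equal(unname(a$group_of), c("Other races", "Other races", "Black"))
  expect_equal(a$categories, c("Black", "Other races"))
})

test_that("crossing assignments forms the observed intersectional categories", {
  rec <- make_records(c(50, 50, 70, 70), sex = c("Male", "Female", "Male", "Female"))
  age2 <- grouping_spec("age", "age",
    bins = list(age = list(breaks = c(-Inf, 60, Inf), labels = c("<60", ">=60"))))
  a <- assign_groups(rec, age2)
  b <- assign_groups(rec, grouping_spec("sex", "sex"))
  cr <- cross_groups(a, b)
  expect_length(cr$categories, 4L)     # full 2x2 product observed

  # single-category partner: identical partition up to relabelling
  one <- assign_groups(make_records(c(50, 50, 70, 70), race = rep("X", 4)),
                       grouping_spec("race", "race"))
  cr1 <- cross_groups(a, one)
  expect_equal(length(cr1$categories), length(a$categories))
  expect_equal(split(names(cr1$group_of), cr1$group_of) |> unname() |> lapply(sort),
               split(names(a$group_of), a$group_of) |> unname() |> lapply(sort))

  # 2x3 with one unobserved combination -> 5 categories (6-sample fixture)
  rec6 <- make_records(c(50, 50, 50, 70, 70, 70),
                       race = c("W", "B", "O", "W", "B", "B"))
  a6 <- assign_groups(rec6, age2)
  b6 <- assign_groups(rec6, grouping_spec("race", "race"))
  cr6 <- cross_groups(a6, b6)
  expect_length(cr6$categories, 5L)    # ">=60 x O" never observed
  expect_false(">=60 x O" %in% cr6$categories)

  expect_error(cross_groups(a, b6), class = "fairdx_spec_error")
})

test_that("cross(a,b) and cross(b,a) induce identical partitions", {
  set.seed(42)
  rec <- make_records(sample(40:90, 30, TRUE), sex = sample(c("M", "F"), 30, TRUE))
  a <- assign_groups(rec, age2_spec)
  b <- assign_groups(rec, grouping_spec("sex", "sex"))
  p1 <- split(names(cross_groups(a, b)$group_of), cross_groups(a, b)$group_of)
  p2 <- split(names(cross_groups(b, a)$group_of), cross_groups(b, a)$group_of)
  norm <- function(p) unname(lapply(p, sort))[order(vapply(lapply(p, sort), paste, "", collapse = ","))]
  expect_equal(norm(p1), norm(p2))
})

test_that("assignment partitions the sample set (property over random fixtures)", {
  for (i in 1:20) {
    set.seed(i)
    n <- sample(5:40, 1)
    rec <- make_records(runif(n, 30, 95), sex = sample(c("M", "F"), n, TRUE))
    a <- assign_groups(rec, if (i %% 2) age2_spec else age3_spec)
    expect_setequal(names(a$group_of), rec$sample_id)
    expect_true(all(a$group_of %in% a$categories))
    expect_equal(sort(unique(unname(a$group_of))), a$categories)
  }
})

test_that("cohort summaries reproduce printed prevalence arithmetic", {
  # ocular-hypertension-cohort age<60 row: 420 positives of 16,254 -> 2.58%
  expect_equal(fairdx:::round_half_up(100 * 420 / 16254, 2), 2.58)
  set.seed(1)
  rec <- make_records(rep(50, 20), label = c(rep(1L, 3), rep(0L, 17)))
  s <- summarize_cohort(rec, assign_groups(rec, age2_spec))
  expect_equal(s$positive, 3L)
  expect_equal(s$total, 20L)
  expect_equal(s$percent, 15)

  # zero positives of 10 -> 0.00
  rec0 <- make_records(rep(50, 10))
  s0 <- summarize_cohort(rec0, assign_groups(rec0, age2_spec))
  expect_identical(s0$percent, 0)

  # percentages recompute exactly from stored counts
  recr <- make_records(runif(200, 30, 95), label = sample(0:1, 200, TRUE))
  sr <- summarize_cohort(recr, assign_groups(recr, age3_spec))
  expect_equal(sr$percent, fairdx:::round_half_up(100 * sr$positive / sr$total, 2))
  expect_equal(sum(sr$total), 200L)
})

test_that("metadata round-trips through CSV and validates its contract", {
  rec <- toy_records(15, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metadata(rec, path)
  back <- read_metadata(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  bad <- rec; names(bad)[1] <- "id"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_metadata(bad, path2)
  expect_error(read_metadata(path2), class = "fairdx_io_error")
})
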