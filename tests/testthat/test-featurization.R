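# Feature construction and the preprocessing stack.

test_that("per-category feature counts honor the 35/31/9/4/4/2/1 contract", {
  fc <- feature_counts()
  expect_identical(unname(fc[c("labs", "vitals")]), c(35L, 35L))
  expect_identical(unname(fc[["ventilator"]]), 31L)
  expect_identical(unname(fc[["medications"]]), 9L)
  expect_identical(unname(fc[c("cultures", "procedures")]), c(4L, 4L))
  expect_identical(unname(fc[["intake_output"]]), 2L)
  expect_identical(unname(fc[c("demographics", "diagnosis")]), c(1L, 1L))

  s <- data.frame(t = c(10, 50, 400), value = c(3, 9, 5))
  for (cat in c("labs", "vitals", "ventilator", "medications",
                "cultures", "procedures", "intake_output")) {
    expect_length(build_feature_group(s, cat, 2880), fc[[cat]])
  }
})

test_that("the named members of a lab group match their definitions", {
  s <- data.frame(t = c(100, 200, 300), value = c(100, 120, 110))
  g <- build_feature_group(s, "labs", 2880)
  expect_identical(unname(g[["first_value"]]), 100)
  expect_identical(unname(g[["last_value"]]), 110)
  expect_identical(unname(g[["max_value"]]), 120)
  expect_identical(unname(g[["min_value"]]), 100)
  expect_identical(unname(g[["diff_last_two"]]), -10)   # most recent minus previous
  expect_identical(unname(g[["ever_measured"]]), 1)
  expect_identical(unname(g[["n_measurements"]]), 3)
  expect_identical(unname(g[["time_since_last"]]), 2580)
})

test_that("degenerate series yield collapsed values and missing differences", {
  g <- build_feature_group(data.frame(t = 50, value = 7), "labs", 2880)
  expect_true(all(g[c("first_value", "last_value", "min_value",
                      "max_value")] == 7))
  expect_true(is.na(g[["diff_last_two"]]))
  expect_true(is.na(g[["sd_value"]]))
  expect_error(build_feature_group(data.frame(t = c(5, 1), value = 1:2),
                                   "labs", 2880), "nondecreasing")
})

test_that("an absent variable answers only the ever-measured question", {
  g <- build_feature_group(NULL, "labs", 2880)
  expect_identical(unname(g[["ever_measured"]]), 0)
  expect_identical(unname(g[["measured_last24h"]]), 0)
  expect_true(all(is.na(g[setdiff(names(g), c("ever_measured",
                                              "measured_last24h"))])))
})

test_that("matrix width equals the inventory arithmetic", {
  cfg <- sim_config(n_cases = 3L, seed = 4L, variable_counts = c(
    vitals = 0L, ventilator = 1L, labs = 2L, medications = 3L,
    procedures = 0L, cultures = 1L, intake_output = 1L,
    demographics = 6L, diagnosis = 1L))
  co <- generate_cohort(cfg)
  m <- assemble_matrix(co)
  expect_identical(ncol(m), 2L * 35L + 31L + 3L * 9L + 4L + 2L + 6L + 1L)
  sch <- attr(m, "schema")
  expect_identical(nrow(sch), ncol(m))
  expect_false(anyDuplicated(sch$feature) > 0)
  # every feature maps to exactly one variable group
  expect_true(all(table(sch$feature) == 1))
})

test_that("an empty cohort yields a zero-row matrix with the full-width schema", {
  cfg <- sim_config(n_cases = 0L, variable_counts = tiny_counts)
  m <- assemble_matrix(generate_cohort(cfg))
  expect_identical(nrow(m), 0L)
  expect_gt(ncol(m), 0)
})

test_that("constant columns are removed, and only those", {
  m <- make_fm(cbind(a = c(1, 1, 1), b = c(1, 1, 2), c = c(0, 0, 0),
                     d = c(NA, NA, NA), e = c(5, NA, 5)))
  out <- remove_constant_features(m)
  expect_identical(colnames(out), "b")
  expect_setequal(attr(out, "removed_features"), c("a", "c", "d", "e"))
})

test_that("removing k constant columns shrinks the width by exactly k", {
  set.seed(21)
  vals <- matrix(rnorm(10 * 12), 10)
  k <- 4
  vals[, sample(12, k)] <- 3.14
  m <- make_fm(vals)
  expect_identical(ncol(remove_constant_features(m)), 12L - 4L)
})

test_that("duplicate columns collapse to the canonically first survivor", {
  m <- make_fm(cbind(x1 = c(1, 0, 1, 0), x2 = c(0, 1, 1, 0),
                     x3 = c(1, 0, 1, 0), x4 = c(1, 0, 1, 0),
                     x5 = c(2, 3, 4, 5)))
  out <- deduplicate_features(m)
  expect_identical(colnames(out), c("x1", "x2", "x5"))
  expect_identical(attr(out, "duplicate_classes")$x1, c("x1", "x3", "x4"))
  # brute-force pairwise check: no identical pair remains
  for (i in seq_len(ncol(out) - 1)) for (j in (i + 1):ncol(out)) {
    expect_false(identical(out[, i], out[, j]))
  }
  # no duplicates: identity
  m2 <- make_fm(cbind(u = 1:4, v = 4:1))
  expect_identical(colnames(deduplicate_features(m2)), c("u", "v"))
})

test_that("median/mode imputation fills exactly the missing cells", {
  m <- make_fm(cbind(num = c(1, NA, 3), nom = c(1, 1, NA), full = c(7, 8, 9)),
               types = c("numeric", "nominal", "numeric"))
  out <- impute_median_mode(m)
  expect_identical(unname(out[2, "num"]), 2)
  expect_identical(unname(out[3, "nom"]), 1)
  expect_identical(out[, "full"], m[, "full"])
  expect_false(anyNA(out))
  # mode ties resolve to the smallest code
  m2 <- make_fm(cbind(nom = c(1, 1, 2, 2, NA)), types = "nominal")
  expect_identical(unname(impute_median_mode(m2)[5, "nom"]), 1)
  # fully observed: identity on values
  m3 <- make_fm(cbind(a = 1:5, b = 5:1))
  expect_identical(unclass(impute_median_mode(m3))[, ], unclass(m3)[, ])
})

test_that("regression imputation recovers an exact linear relation", {
  set.seed(31)
  x <- rnorm(30)
  y <- 2 * x
  y[7] <- NA
  m <- make_fm(cbind(x = x, y = y, z = rnorm(30)))
  out <- impute_regression(m)
  expect_equal(unname(out[7, "y"]), 2 * x[7], tolerance = 1e-8)
  expect_identical(out[-7, "y"], m[-7, "y"])   # observed cells untouched
  expect_false(anyNA(out))
})

test_that("regression imputation falls back gracefully", {
  m <- make_fm(cbind(a = c(NA, NA, NA, NA), b = c(1, 2, 3, 4)))
  out <- impute_regression(m)
  expect_true(all(out[, "a"] == 0))
  expect_true("a" %in% attr(out, "imputation")$fallbacks)
  # fully observed: identity
  m2 <- make_fm(cbind(a = 1:4, b = 4:1))
  expect_identical(unclass(impute_regression(m2))[, ], unclass(m2)[, ])
})

test_that("the full preprocessing stack is ordered, idempotent, and aligned", {
  cfg <- sim_config(n_cases = 25L, seed = 17L, variable_counts = tiny_counts)
  m <- assemble_matrix(generate_cohort(cfg))
  prep <- preprocess_features(m)
  expect_identical(dim(prep$median), dim(prep$regression))
  expect_identical(colnames(prep$median), colnames(prep$regression))
  expect_false(anyNA(prep$median))
  expect_false(anyNA(prep$regression))
  # both imputations leave observed cells bit-identical
  keep <- colnames(prep$median)
  obs <- !is.na(unclass(m)[, keep])
  expect_identical(unclass(prep$median)[, keep][obs], unclass(m)[, keep][obs])
  expect_identical(unclass(prep$regression)[, keep][obs], unclass(m)[, keep][obs])
  # constants and dedup are idempotent
  m1 <- remove_constant_features(m)
  expect_identical(unclass(remove_constant_features(m1))[, ], unclass(m1)[, ])
  m2 <- deduplicate_features(m1)
  expect_identical(unclass(deduplicate_features(m2))[, ], unclass(m2)[, ])
})

test_that("feature matrices round-trip through CSV with schema sidecar", {
  cfg <- sim_config(n_cases = 4L, seed = 9L, variable_counts = tiny_counts)
  m <- assemble_matrix(generate_cohort(cfg))
  tf <- tempfile(fileext = ".csv")
  write_matrix_csv(m, tf)
  back <- read_matrix_csv(tf)
  expect_equal(unclass(back)[, ], unclass(m)[, ], tolerance = 1e-12)
  expect_identical(attr(back, "schema")$feature, attr(m, "schema")$feature)
  unlink(c(tf, paste0(tf, ".schema.json")))
})
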