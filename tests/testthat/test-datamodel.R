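test_that("feature tables parse, round-trip, and reject bad cells", {
  d <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcgA\tcgB",
               "S1\t0.1\t0.2", "S2\t0.9\t0.8", "S3\t0.5\t0.7"), d)
  blk <- load_feature_table(d, "methylation")
  expect_equal(dim(blk$values), c(3, 2))
  expect_equal(blk$values["S2", "cgA"], 0.9)

  # beta out of range, named by cell
  writeLines(c("sample_id\tcgA", "S1\t1.2"), d)
  expect_error(load_feature_table(d, "methylation"), "cgA")

  # non-numeric cell named
  writeLines(c("sample_id\tcgA", "S1\toops"), d)
  expect_error(load_feature_table(d, "methylation"), "oops")

  # duplicate ids rejected
  writeLines(c("sample_id\tcgA\tcgA", "S1\t0.1\t0.2"), d)
  expect_error(load_feature_table(d, "methylation"), "duplicate feature")
  writeLines(c("sample_id\tcgA", "S1\t0.1", "S1\t0.2"), d)
  expect_error(load_feature_table(d, "methylation"), "duplicate sample")
})

test_that("write-then-load is the identity on a generated 50x200 table", {
  set.seed(7)
  m <- matrix(runif(50 * 200), 50, 200,
              dimnames = list(sprintf("S%02d", 1:50), sprintf("cg%03d", 1:200)))
  f <- tempfile(fileext = ".tsv")
  write_feature_table(m, f)
  back <- load_feature_table(f, "methylation")
  expect_identical(back$values, m)
})

test_that("zero-variance filtering removes exactly the constant columns", {
  ds <- tiny_dataset()
  ds$values[, 2] <- 0.5
  ds$values[, 5] <- 0.123
  ds$values[, 7] <- 3
  kept <- drop_zero_variance(ds)
  expect_equal(ncol(kept$values), ncol(ds$values) - 3)
  expect_false(any(colnames(ds$values)[c(2, 5, 7)] %in% colnames(kept$values)))
  # order of survivors preserved
  expect_identical(colnames(kept$values),
                   setdiff(colnames(ds$values), colnames(ds$values)[c(2, 5, 7)]))

  # larger planted case: 100x500 with 17 known constant columns
  set.seed(99)
  m <- matrix(runif(100 * 500), 100, 500,
              dimnames = list(sprintf("S%03d", 1:100), sprintf("F%03d", 1:500)))
  const_cols <- sample(500, 17)
  m[, const_cols] <- rep(runif(17), each = 100)
  ds2 <- omics_dataset(m, rep("methylation", 500),
                       survival_days = sample(1000, 100, TRUE))
  kept2 <- drop_zero_variance(ds2)
  expect_equal(setdiff(colnames(m), colnames(kept2$values)),
               colnames(m)[sort(const_cols)])

  ds$values[] <- 1
  ds$feature_kind[] <- "expression"
  expect_error(drop_zero_variance(ds), "zero variance")
})

test_that("class assignment follows the day threshold exactly", {
  mk <- function(days) {
    m <- matrix(runif(length(days)), ncol = 1,
                dimnames = list(paste0("S", seq_along(days)), "cgA"))
    omics_dataset(m, "methylation", survival_days = days)
  }
  ds <- suppressMessages(assign_classes(mk(c(400, 401, 7, 4084)), class_rule(400)))
  expect_equal(as.character(ds$class_label), c("SHORT", "LONG", "SHORT", "LONG"))

  # threshold 0: everyone survives past it
  ds0 <- suppressMessages(assign_classes(mk(c(1, 5, 9)), class_rule(0)))
  expect_true(all(ds0$class_label == "LONG"))

  # censored samples are not admissible
  dsc <- mk(c(100, 600))
  dsc$event <- c(1L, 0L)
  expect_error(assign_classes(dsc, class_rule(400)), "deceased")

  # partition property: |SHORT| + |LONG| = n at every threshold
  ds2 <- mk(sample(1:1000, 30, TRUE))
  for (thr in c(0, 100, 400, 999)) {
    d <- suppressMessages(assign_classes(ds2, class_rule(thr)))
    expect_equal(sum(table(d$class_label)), 30)
  }
})

test_that("assembly intersects samples, applies the NA policy, and bundles round-trip", {
  set.seed(3)
  meth <- matrix(runif(12), 4, 3,
                 dimnames = list(paste0("S", 1:4), paste0("cg", 1:3)))
  expr <- matrix(rexp(9), 3, 3,
                 dimnames = list(paste0("S", c(1, 2, 5)), paste0("G", 1:3)))
  clin <- data.frame(sample_id = paste0("S", 1:5),
                     days_to_death = c(100, 500, 300, 800, 50),
                     vital_status = "deceased", age = 50:54,
                     gender = "f", grade = "IV")
  blocks <- list(list(values = meth, kind = "methylation"),
                 list(values = expr, kind = "expression"))
  expect_warning(ds <- assemble_dataset(blocks, clin), "dropped")
  expect_equal(rownames(ds$values), c("S1", "S2"))
  expect_equal(ncol(ds$values), 6)

  # features with NA dropped under the default policy
  meth2 <- meth; meth2[2, 1] <- NA
  blocks2 <- list(list(values = meth2[1:3, ], kind = "methylation"))
  clin3 <- clin[1:3, ]
  expect_message(ds2 <- assemble_dataset(blocks2, clin3), "dropped")
  expect_false("cg1" %in% colnames(ds2$values))
  # ... or median-imputed under the switch
  ds3 <- assemble_dataset(blocks2, clin3, na_action = "impute")
  expect_equal(ds3$values[2, "cg1"], median(meth2[c(1, 3), 1]))

  # bundle round-trip preserves values, ids and survival
  ds <- suppressMessages(assign_classes(ds, class_rule(400)))
  dir <- tempfile()
  write_dataset_bundle(ds, dir)
  expect_true(file.exists(file.path(dir, "MANIFEST.tsv")))
  back <- suppressWarnings(suppressMessages(read_dataset_bundle(dir)))
  expect_equal(back$values[, colnames(ds$values)], ds$values)
  expect_equal(unname(back$survival_days), unname(ds$survival_days))
})

test_that("dataset invariants are enforced at construction", {
  m <- matrix(c(0.5, 1.5), 2, 1, dimnames = list(c("a", "b"), "cgX"))
  expect_error(omics_dataset(m, "methylation", survival_days = c(1, 2)),
               "beta-value")
  m2 <- matrix(c(1, -3), 2, 1, dimnames = list(c("a", "b"), "gX"))
  expect_error(omics_dataset(m2, "expression", survival_days = c(1, 2)),
               "negative expression")
  m3 <- matrix(c(0.2, NA), 2, 1, dimnames = list(c("a", "b"), "cgX"))
  expect_error(omics_dataset(m3, "methylation", survival_days = c(1, 2)),
               "missing")
})
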