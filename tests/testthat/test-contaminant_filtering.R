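test_that("depth filter applies a strict less-than boundary", {
  m <- matrix(0L, nrow = 3, ncol = 2,
              dimnames = list(c("A", "B", "C"), c("O1", "O2")))
  m["A", ] <- c(5000L, 5000L)    # exactly 10,000 -> kept
  m["B", ] <- c(5000L, 4999L)    # 9,999 -> removed
  m["C", ] <- c(50000L, 4652L)   # 54,652 -> kept
  kept <- filter_samples_by_depth(count_table(m), 10000)
  expect_setequal(rownames(kept), c("A", "C"))
  expect_equal(ncol(kept), 2)

  expect_identical(rownames(filter_samples_by_depth(count_table(m), 100)),
                   c("A", "B", "C"))
  expect_error(filter_samples_by_depth(count_table(m), 1e6), "step \\(a\\)")
})

test_that("relative abundances sum to one and preserve zeros", {
  m <- count_table(matrix(c(2L, 2L, 4L,
                            7L, 0L, 0L), nrow = 2, byrow = TRUE,
                          dimnames = list(c("A", "B"), c("O1", "O2", "O3"))))
  rel <- to_relative(m)
  expect_equal(rel["A", ], c(O1 = 0.25, O2 = 0.25, O3 = 0.5))
  expect_equal(rel["B", ], c(O1 = 1, O2 = 0, O3 = 0))
  expect_true(all(abs(rowSums(rel) - 1) < 1e-12))

  z <- count_table(matrix(c(1L, 0L, 0L, 0L), nrow = 2,
                          dimnames = list(c("A", "B"), c("O1", "O2"))))
  expect_error(to_relative(z), "zero-total")
})

test_that("relative luminosity normalises by the brightest band", {
  w <- relative_luminosity(c(A = 200, B = 100, C = 50))
  expect_equal(w, c(A = 1, B = 0.5, C = 0.25))
  expect_equal(relative_luminosity(c(A = 3, B = 3)), c(A = 1, B = 1))
  expect_equal(relative_luminosity(c(A = 100, B = 0)), c(A = 1, B = 0))
  expect_error(relative_luminosity(c(A = 0, B = 0)), "zero")
  # literal complementary variant: brightest band -> 0
  expect_equal(relative_luminosity(c(A = 200, B = 50), mode = "literal"),
               c(A = 0, B = 0.75))
})

test_that("luminosity weighting is an element-wise product per sample", {
  rel <- matrix(c(0.5, 0.5, 0.3, 0.7), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("O1", "O2")))
  w <- c(A = 0.5, B = 1)
  wt <- weight_by_luminosity(rel, w)
  expect_equal(wt["A", ], c(O1 = 0.25, O2 = 0.25))
  expect_equal(wt["B", ], rel["B", ])
  wt0 <- weight_by_luminosity(rel, c(A = 0, B = 1))
  expect_equal(unname(wt0["A", ]), c(0, 0))
  expect_error(weight_by_luminosity(rel, c(A = 0.5)), "missing luminosity")
})

test_that("sample-type means average within each type with zeros included", {
  exp <- tiny_experiment()
  rel <- to_relative(exp$counts)
  means <- sample_type_means(rel, exp$metadata)
  expect_equal(dim(means), c(3L, 3L))
  expect_equal(means["OTU1", "subject"],
               mean(rel[c("S1_T1", "S1_T2", "S2_T1", "S2_T2"), "OTU1"]))
  expect_equal(means["OTU2", "blank_control"], rel["BLK1", "OTU2"])

  two_subj <- matrix(c(0.2, 0.4), nrow = 2,
                     dimnames = list(c("S1_T1", "S2_T1"), "OTU1"))
  expect_error(sample_type_means(two_subj, exp$metadata), "step \\(d\\)")
})

test_that("rare-OTU removal uses a strict less-than share threshold", {
  means <- c(O1 = 0.5, O2 = 0.5 * 1e-7)
  # O2's share = 1e-7 / (1 + 1e-7) < 1e-6 -> removed
  expect_identical(remove_rare_otus(means, 1e-6), "O1")

  equal <- c(O1 = 0.2, O2 = 0.2, O3 = 0.2)
  expect_identical(remove_rare_otus(equal, 1e-6), c("O1", "O2", "O3"))

  # boundary share exactly equal to the threshold is retained
  boundary <- c(O1 = 1 - 1e-6, O2 = 1e-6)
  expect_identical(remove_rare_otus(boundary, 1e-6), c("O1", "O2"))

  expect_error(remove_rare_otus(c(O1 = 0, O2 = 0)), "step \\(e\\)")
})

test_that("a perfect control fit has slope 1, intercept 0, zero residual SE", {
  means <- c(O1 = 1e-3, O2 = 1e-2, O3 = 1e-1, O4 = 1)
  fit <- fit_control_regression(means, means, names(means))
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$residual_se, 0, tolerance = 1e-9)
  expect_equal(fit$n_points, 4)
  # no OTU strictly exceeds its own prediction -> nothing retained
  expect_length(regression_retain(fit, means, means, names(means), 5), 0)
})

test_that("regression matches the closed-form normal-equations oracle", {
  subject <- c(O1 = 0.1, O2 = 0.2, O3 = 0.3, O4 = 4.0)
  control <- c(O1 = 0.1, O2 = 0.2, O3 = 0.3, O4 = 0.4)
  fit <- fit_control_regression(subject, control, names(subject))
  eps <- min(c(subject, control)) / 2
  oracle <- ols_oracle(log(control + eps), log(subject + eps))
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$residual_se, oracle$residual_se, tolerance = 1e-10)

  kept <- regression_retain(fit, subject, control, names(subject), 1)
  expect_identical(kept,
                   retain_oracle(subject, control, names(subject), 1))
})

test_that("fit and retention agree with the oracle on 100 random instances", {
  set.seed(2024)
  for (i in 1:100) {
    inst <- random_mean_instance(sample(5:50, 1))
    pooled <- c(inst$subject, inst$control)
    eps <- min(pooled[pooled > 0]) / 2
    fit <- fit_control_regression(inst$subject, inst$control, inst$otu_set)
    oracle <- ols_oracle(log(inst$control + eps), log(inst$subject + eps))
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$residual_se, oracle$residual_se, tolerance = 1e-10)
    m <- sample(c(0.5, 1, 2, 5), 1)
    expect_identical(
      sort(regression_retain(fit, inst$subject, inst$control,
                             inst$otu_set, m)),
      sort(retain_oracle(inst$subject, inst$control, inst$otu_set, m)))
  }
})

test_that("regression preconditions are enforced", {
  s <- c(O1 = 0.1, O2 = 0.2)
  expect_error(fit_control_regression(s, s, names(s)), "at least 3")
  s3 <- c(O1 = 0.1, O2 = 0.2, O3 = 0.3)
  same <- c(O1 = 0.5, O2 = 0.5, O3 = 0.5)
  expect_error(fit_control_regression(s3, same, names(s3)),
               "regression undefined")
})

test_that("retention shrinks to nothing as the multiplier grows", {
  set.seed(31)
  inst <- random_mean_instance(30)
  fit <- fit_control_regression(inst$subject, inst$control, inst$otu_set)
  sizes <- vapply(c(0.5, 1, 2, 5, 50, 1e6), function(m) {
    length(regression_retain(fit, inst$subject, inst$control,
                             inst$otu_set, m))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0)
})

test_that("pipeline recovers truth in a contaminant-dominated pool", {
  # regime the filter is built for: true OTUs are a small minority of the
  # pool entering the regression (fraction well below 1/(1 + 5^2))
  sens <- spec <- numeric(3)
  for (i in 1:3) {
    b <- generate_experiment(dominated_config(seed = i))
    res <- run_contaminant_pipeline(b$counts, b$metadata, b$luminosity)
    cf <- truth_confusion(res$retained_otus, b$truth)
    sens[i] <- cf$sensitivity
    spec[i] <- cf$specificity
  }
  expect_true(all(sens >= 0.9))
  expect_true(all(spec >= 0.95))
})

test_that("pipeline report attrition is monotone and complete", {
  b <- small_bundle()
  res <- run_contaminant_pipeline(b$counts, b$metadata, b$luminosity)
  expect_identical(res$report$step, c("a", "b", "c", "d", "e", "f", "g",
                                      "h", "i"))
  expect_true(all(diff(res$report$n_otus_retained) <= 0))
  expect_equal(res$report$n_otus_retained[nrow(res$report)],
               length(res$retained_otus))
  if (length(res$retained_otus) > 0) {
    expect_identical(colnames(res$filtered_counts),
                     res$retained_otus)
  }
})

test_that("pipeline output is invariant to input row/column ordering", {
  b <- generate_experiment(dominated_config(seed = 4))
  res1 <- run_contaminant_pipeline(b$counts, b$metadata, b$luminosity)

  set.seed(1)
  perm_s <- sample(nrow(b$counts))
  perm_o <- sample(ncol(b$counts))
  counts2 <- count_table(unclass(b$counts)[perm_s, perm_o])
  meta2 <- b$metadata[sample(nrow(b$metadata)), ]
  lum2 <- b$luminosity[sample(length(b$luminosity))]
  class(lum2) <- c("luminosity_table", "numeric")
  res2 <- run_contaminant_pipeline(counts2, meta2, lum2)

  expect_identical(res1$retained_otus, res2$retained_otus)
})

test_that("rescaling all luminosities leaves the retained set unchanged", {
  b <- generate_experiment(dominated_config(seed = 2))
  res1 <- run_contaminant_pipeline(b$counts, b$metadata, b$luminosity)
  lum_scaled <- luminosity_table(stats::setNames(
    as.numeric(b$luminosity) * 37.5, names(b$luminosity)))
  res2 <- run_contaminant_pipeline(b$counts, b$metadata, lum_scaled)
  expect_identical(res1$retained_otus, res2$retained_otus)
})

test_that("retained set shrinks with stricter thresholds on a fixed bundle", {
  b <- generate_experiment(dominated_config(seed = 3))
  sizes_m <- vapply(c(3, 5, 8, 12), function(m) {
    length(run_contaminant_pipeline(
      b$counts, b$metadata, b$luminosity,
      filter_config(se_multiplier = m))$retained_otus)
  }, numeric(1))
  expect_true(all(diff(sizes_m) <= 0))

  sizes_r <- vapply(c(1e-7, 1e-6, 1e-4, 1e-3), function(rf) {
    length(run_contaminant_pipeline(
      b$counts, b$metadata, b$luminosity,
      filter_config(rare_fraction = rf))$retained_otus)
  }, numeric(1))
  expect_true(all(diff(sizes_r) <= 0))
})

test_that("survivor wiring runs and reports like the default wiring", {
  b <- small_bundle()
  res <- run_contaminant_pipeline(b$counts, b$metadata, b$luminosity,
                                  filter_config(pass_mode = "survivor"))
  expect_identical(res$report$step, c("a", "b", "c", "d", "e", "f", "g",
                                      "h", "i"))
  expect_true(all(diff(res$report$n_otus_retained) <= 0))
  expect_equal(res$report$n_otus_retained[nrow(res$report)],
               length(res$retained_otus))
})

test_that("pipeline errors are annotated with their step letter", {
  exp <- tiny_experiment()
  expect_error(
    run_contaminant_pipeline(exp$counts, exp$metadata, exp$luminosity,
                             filter_config(min_depth = 1e6)),
    "step \\(a\\)")
})

test_that("filter results round-trip to a directory of TSVs", {
  b <- generate_experiment(dominated_config(seed = 1))
  res <- run_contaminant_pipeline(b$counts, b$metadata, b$luminosity)
  dir <- withr::local_tempdir()
  write_filter_result(res, dir)
  retained <- read.table(file.path(dir, "retained_otus.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  expect_identical(retained$otu_id, res$retained_otus)
  filt <- read_count_table(file.path(dir, "filtered_counts.tsv"),
                           "samples_rows")
  expect_identical(unclass(filt), unclass(res$filtered_counts))
  rep_back <- read.table(file.path(dir, "filter_report.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(rep_back), 9)
})
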