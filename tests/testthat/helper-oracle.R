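# Independent oracles and shared fixtures.
#
# The OLS oracle solves the normal equations in closed form; the retention
# oracle enumerates residuals directly. Both are deliberately independent of
# the package's lm-based implementation path.

ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- sy / n - slope * sx / n
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept,
       residual_se = sqrt(rss / (n - 2)))
}

retain_oracle <- function(subject_means, control_means, otu_set,
                          se_multiplier) {
  s <- subject_means[otu_set]
  c_ <- control_means[otu_set]
  pooled <- c(s, c_)
  eps <- min(pooled[pooled > 0]) / 2
  x <- log(c_ + eps)
  y <- log(s + eps)
  fit <- ols_oracle(x, y)
  kept <- character()
  for (i in seq_along(otu_set)) {
    resid <- y[i] - (fit$intercept + fit$slope * x[i])
    if (resid > se_multiplier * fit$residual_se) {
      kept <- c(kept, otu_set[i])
    }
  }
  kept
}

# random small regression instance: named subject/control mean vectors
random_mean_instance <- function(n_otus) {
  ids <- sprintf("O%03d", seq_len(n_otus))
  control <- stats::rlnorm(n_otus, meanlog = -6, sdlog = 2)
  subject <- exp(log(control) * runif(1, 0.5, 1.5) +
                 stats::rnorm(n_otus, sd = runif(1, 0.2, 2)))
  # sprinkle structural zeros on both axes
  control[runif(n_otus) < 0.15] <- 0
  subject[runif(n_otus) < 0.05] <- 0
  list(subject = stats::setNames(subject, ids),
       control = stats::setNames(control, ids),
       otu_set = ids)
}

# tiny 3-sample x 2-OTU count fixture
tiny_counts <- function() {
  count_table(matrix(c(5L, 3L, 0L,
                       2L, 8L, 4L), nrow = 3,
                     dimnames = list(c("A", "B", "C"), c("OTU1", "OTU2"))))
}

# minimal consistent experiment: 2 subjects x 2 times + both control types
tiny_experiment <- function() {
  samples <- c("S1_T1", "S1_T2", "S2_T1", "S2_T2", "BLK1", "WAT1")
  counts <- count_table(matrix(
    as.integer(c(40, 30, 35, 25, 5, 4,
                 10, 15, 12, 18, 20, 25,
                 50, 55, 53, 57, 25, 21)),
    nrow = 6,
    dimnames = list(samples, c("OTU1", "OTU2", "OTU3"))))
  metadata <- sample_metadata(data.frame(
    sample_id = samples,
    sample_type = c(rep("subject", 4), "blank_control", "water_control"),
    subject_id = c("S1", "S1", "S2", "S2", "", ""),
    time_point = c("baseline", "month1", "baseline", "month1", "", ""),
    stringsAsFactors = FALSE), time_points = c("baseline", "month1"))
  luminosity <- luminosity_table(stats::setNames(
    c(200, 180, 220, 190, 15, 10), samples))
  list(counts = counts, metadata = metadata, luminosity = luminosity)
}

# simulation config for the contaminant-dominated regime the filter is
# designed for (true fraction well below 1/(1 + se_multiplier^2))
dominated_config <- function(seed) {
  simulation_config(n_subjects = 20, n_true_otus = 15,
                    n_contaminant_otus = 600, core_size_per_subject = 8,
                    seed = seed)
}

# small but structurally complete bundle for fast pipeline tests
small_bundle <- function(seed = 11) {
  generate_experiment(simulation_config(
    n_subjects = 6, n_times = 3, n_blank_controls = 4, n_water_controls = 2,
    n_true_otus = 10, n_contaminant_otus = 80, core_size_per_subject = 5,
    depth_mean = 20000, depth_sd = 5000, seed = seed))
}

# boolean presence grid used by the core-microbiome enumeration tests:
# 5 taxa x 3 subjects x 3 times covering all-present, one-cell-absent,
# 2-of-3-subjects, never-present and missing-cell cases
enumeration_grid <- function() {
  arr <- array(TRUE, dim = c(5, 3, 3),
               dimnames = list(taxon = paste0("tax", 1:5),
                               subject = paste0("S", 1:3),
                               time = c("t1", "t2", "t3")))
  arr["tax2", "S1", "t2"] <- FALSE              # one cell absent
  arr["tax3", "S3", ] <- FALSE                  # 2/3 subjects at all times
  arr["tax4", , ] <- FALSE                      # never present
  arr["tax5", "S2", "t3"] <- FALSE
  arr["tax5", "S3", "t1"] <- FALSE
  structure(arr, detection_threshold = 1,
            class = c("presence_table", "array"))
}
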