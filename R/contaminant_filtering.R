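# Nine-step contaminant-removal model for low-biomass OTU tables:
#   (a) drop samples with < min_depth reads
#   (b) convert counts to within-sample relative abundances
#   (c) weight by relative PCR band luminosity (biomass surrogate)
#   (d) per-OTU mean weighted relative abundance per sample type
#   (e) drop OTUs below a rare-abundance share of the subject total
#   (f,g) OLS of log subject means on log blank-control means; OTUs more than
#         exp(se_multiplier * SE) above their prediction are flagged as truly
#         present
#   (h) regression repeated on the remaining pool (blank controls)
#   (i) regression repeated with water-control means as predictor
# The final retained set contains the OTUs whose subject abundance the
# negative controls failed to predict.

#' Configuration of the contaminant filter
#'
#' Defaults are the published thresholds: samples with fewer than 10,000
#' reads are removed; OTUs below 0.0001% (1e-6) of the summed subject-sample
#' mean abundance are removed; regression outliers are retained when their
#' subject abundance exceeds the control-based prediction by more than a
#' factor of `exp(se_multiplier * SE)` with `se_multiplier = 5`.
#'
#' @param min_depth Minimum per-sample read count (step a); samples with
#'   strictly fewer reads are removed.
#' @param rare_fraction Minimum share of the summed subject-sample mean
#'   weighted relative abundance (step e); OTUs strictly below it are
#'   removed. 1e-6 corresponds to the printed 0.0001%.
#' @param se_multiplier Multiplier of the regression residual standard error
#'   defining the outlier threshold (steps g-i).
#' @param luminosity_mode `"proportional"` (default): weight = L / L_max, so
#'   the brightest band (highest biomass) keeps weight 1. `"literal"`:
#'   weight = (L_max - L) / L_max, the complementary form in which the
#'   brightest band receives weight 0; provided for comparison only (see the
#'   methods vignette).
#' @param pass_mode `"accumulate"` (default): each regression pass extracts
#'   its positive outliers as truly present, sets them aside, and the next
#'   pass re-fits on the remaining pool; the final retained set is the union
#'   of extracted outliers. `"survivor"`: each pass re-fits on the previously
#'   retained outliers themselves and keeps only their outliers. See the
#'   methods vignette for why "accumulate" is the default.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10000,
                          rare_fraction = 1e-6,
                          se_multiplier = 5,
                          luminosity_mode = c("proportional", "literal"),
                          pass_mode = c("accumulate", "survivor")) {
  luminosity_mode <- match.arg(luminosity_mode)
  pass_mode <- match.arg(pass_mode)
  if (!is.numeric(min_depth) || min_depth < 1) stop("min_depth must be >= 1")
  if (!is.numeric(rare_fraction) || rare_fraction <= 0 || rare_fraction >= 1) {
    stop("rare_fraction must lie in (0, 1)")
  }
  if (!is.numeric(se_multiplier) || se_multiplier <= 0) {
    stop("se_multiplier must be > 0")
  }
  structure(list(min_depth = min_depth, rare_fraction = rare_fraction,
                 se_multiplier = se_multiplier,
                 luminosity_mode = luminosity_mode, pass_mode = pass_mode),
            class = "filter_config")
}

step_stop <- function(step, ...) {
  stop(sprintf("step (%s): %s", step, paste0(...)), call. = FALSE)
}

#' Step (a): remove samples with insufficient sequencing depth
#'
#' Retains exactly the samples whose total read count is at least
#' `min_depth` (the boundary sample with exactly `min_depth` reads is kept:
#' removal applies to strictly "less than"). The OTU set is unchanged.
#'
#' @param counts A [count_table()].
#' @param min_depth Read-count threshold.
#' @return A [count_table()] with the retained samples.
#' @export
filter_samples_by_depth <- function(counts, min_depth = 10000) {
  depths <- rowSums(unclass_matrix(counts))
  keep <- depths >= min_depth
  if (!any(keep)) {
    step_stop("a", "all samples fall below the depth threshold of ",
              min_depth, " reads")
  }
  count_table(unclass_matrix(counts)[keep, , drop = FALSE])
}

#' Step (b): convert counts to within-sample relative abundances
#'
#' @param counts A [count_table()].
#' @return A numeric matrix (samples x OTUs) whose rows each sum to 1.
#' @export
to_relative <- function(counts) {
  m <- unclass_matrix(counts)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    step_stop("b", "zero-total sample(s): ",
              paste(rownames(m)[totals == 0], collapse = ", "))
  }
  sweep(m, 1L, totals, "/")
}

#' Step (c): relative PCR band luminosity weights
#'
#' Scales every band luminosity by the brightest band. In the default
#' `"proportional"` mode the weight is `L / L_max`, so the brightest
#' (highest-biomass) sample keeps weight 1 and faint control bands are
#' down-weighted in proportion to their target DNA content. The `"literal"`
#' mode computes the complement `(L_max - L) / L_max`.
#'
#' @param luminosity A [luminosity_table()] (or named non-negative vector).
#' @param mode `"proportional"` or `"literal"` (see [filter_config()]).
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
relative_luminosity <- function(luminosity,
                                mode = c("proportional", "literal")) {
  mode <- match.arg(mode)
  l <- as.numeric(luminosity)
  names(l) <- names(luminosity)
  if (any(l < 0)) step_stop("c", "negative luminosity")
  l_max <- max(l)
  if (l_max <= 0) step_stop("c", "all luminosities are zero")
  if (mode == "proportional") l / l_max else (l_max - l) / l_max
}

#' Step (c): weight relative abundances by luminosity
#'
#' Element-wise product of each sample's relative abundances with its
#' luminosity weight. A sample with weight 0 becomes an all-zero row but is
#' retained (and flagged downstream in the report).
#'
#' @param rel Relative-abundance matrix from [to_relative()].
#' @param weights Named weight vector from [relative_luminosity()].
#' @return The weighted relative-abundance matrix.
#' @export
weight_by_luminosity <- function(rel, weights) {
  missing_w <- setdiff(rownames(rel), names(weights))
  if (length(missing_w) > 0) {
    step_stop("c", "missing luminosity weight for sample(s): ",
              paste(missing_w, collapse = ", "))
  }
  rel * weights[rownames(rel)]
}

#' Step (d): per-OTU mean weighted abundance for each sample type
#'
#' Arithmetic mean of the (weighted) relative abundances over the samples of
#' each of the three types, zeros included.
#'
#' @param weighted Weighted relative-abundance matrix (samples x OTUs).
#' @param metadata A [sample_metadata()] covering the rows of `weighted`.
#' @return A numeric matrix (OTUs x 3) with columns `subject`,
#'   `blank_control`, `water_control`.
#' @export
sample_type_means <- function(weighted, metadata) {
  meta <- metadata[match(rownames(weighted), metadata$sample_id), ]
  if (anyNA(meta$sample_type)) {
    step_stop("d", "sample(s) without metadata: ",
              paste(rownames(weighted)[is.na(meta$sample_type)], collapse = ", "))
  }
  out <- sapply(SAMPLE_TYPES, function(tp) {
    rows <- meta$sample_type == tp
    if (!any(rows)) {
      step_stop("d", "no remaining samples of type '", tp, "'")
    }
    colMeans(weighted[rows, , drop = FALSE])
  })
  colnames(out) <- SAMPLE_TYPES
  out
}

#' Step (e): remove rare OTUs
#'
#' An OTU's share is its subject-sample mean weighted relative abundance
#' divided by the sum of that quantity over all OTUs. OTUs whose share is
#' strictly below `rare_fraction` are removed (a boundary share exactly equal
#' to the threshold is kept). The share basis is subject samples only, so
#' control-driven abundance cannot rescue an OTU.
#'
#' @param subject_means Named vector of per-OTU subject-sample means.
#' @param rare_fraction Minimum retained share (default 1e-6 = 0.0001%).
#' @return Character vector of retained OTU ids.
#' @export
remove_rare_otus <- function(subject_means, rare_fraction = 1e-6) {
  total <- sum(subject_means)
  if (total <= 0) {
    step_stop("e", "subject-sample means sum to zero; no abundance signal")
  }
  share <- subject_means / total
  retained <- names(subject_means)[share >= rare_fraction]
  if (length(retained) == 0) {
    step_stop("e", "no OTU reaches the rare-abundance threshold")
  }
  retained
}

#' Step (f): regression of subject abundances on control abundances
#'
#' Ordinary least squares of `log(subject mean + eps)` on
#' `log(control mean + eps)` over the OTUs in `otu_set`, where the
#' pseudocount `eps` is half the smallest non-zero value among the means
#' entering the regression (both axes pooled). The fit is the model of what
#' reagent contamination alone would produce: an OTU whose subject abundance
#' greatly exceeds its prediction is not explained by contamination.
#'
#' @param subject_means,control_means Named per-OTU mean vectors (from
#'   [sample_type_means()]).
#' @param otu_set OTUs to regress (at least 3).
#' @param predictor_label Which control type the predictor means come from
#'   (recorded in the fit).
#' @return A list of class `regression_fit` with `slope`, `intercept`,
#'   `residual_se` (`sqrt(RSS / (n - 2))`), `n_points`, `pseudocount`,
#'   `predictor_label`, and the log-scale data (`x`, `y`).
#' @export
fit_control_regression <- function(subject_means, control_means, otu_set,
                                   predictor_label = "blank_control") {
  if (length(otu_set) < 3) {
    stop("regression needs at least 3 OTUs, got ", length(otu_set))
  }
  s <- subject_means[otu_set]
  c_ <- control_means[otu_set]
  if (anyNA(s) || anyNA(c_)) stop("otu_set contains OTUs without means")
  pooled <- c(s, c_)
  nz <- pooled[pooled > 0]
  if (length(nz) == 0) {
    stop("all means are zero; regression undefined")
  }
  eps <- min(nz) / 2
  x <- log(c_ + eps)
  y <- log(s + eps)
  if (stats::var(x) == 0) {
    stop("zero predictor variance (all control means identical); ",
         "regression undefined")
  }
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  n <- length(otu_set)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residual_se = sqrt(sum(res^2) / (n - 2)),
    n_points = n,
    pseudocount = eps,
    predictor_label = predictor_label,
    x = x, y = y
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(paste0("<regression_fit> y = %.4f + %.4f x on %d OTUs ",
                     "(predictor: %s), residual SE %.4f, ",
                     "retention factor exp(5*SE) = %.2f\n"),
              x$intercept, x$slope, x$n_points, x$predictor_label,
              x$residual_se, exp(5 * x$residual_se)))
  invisible(x)
}

#' Step (g): retain positive regression outliers
#'
#' Retains OTU `o` iff `log(subject_mean_o + eps) - [intercept + slope *
#' log(control_mean_o + eps)] > se_multiplier * residual_se` (strict
#' inequality), i.e. iff the subject abundance exceeds the contamination
#' prediction by more than a factor of `exp(se_multiplier * residual_se)`.
#' The pseudocount is the one stored in the fit.
#'
#' @param fit A `regression_fit` from [fit_control_regression()].
#' @param subject_means,control_means Named per-OTU mean vectors.
#' @param otu_set OTUs to test (normally the set the fit was computed on).
#' @param se_multiplier Threshold multiplier (default 5).
#' @return Character vector of retained (outlier) OTU ids.
#' @export
regression_retain <- function(fit, subject_means, control_means, otu_set,
                              se_multiplier = 5) {
  eps <- fit$pseudocount
  x <- log(control_means[otu_set] + eps)
  y <- log(subject_means[otu_set] + eps)
  residual <- y - (fit$intercept + fit$slope * x)
  otu_set[residual > se_multiplier * fit$residual_se]
}

#' Run the full contaminant-filtering pipeline (steps a-i)
#'
#' Executes depth filtering, relative-abundance standardisation, luminosity
#' weighting, per-type means, rare-OTU removal, two blank-swab regression
#' passes and one water-control regression pass, and assembles a per-step
#' attrition report.
#'
#' In the default `"accumulate"` mode each regression pass extracts its
#' positive outliers (OTUs the controls fail to predict) as truly present and
#' re-fits the contamination model on the remaining pool, so outliers masked
#' by an inflated residual SE in an earlier pass can surface later; the final
#' retained set is everything extracted over the three passes. In
#' `"survivor"` mode each pass re-fits on the previously retained outliers
#' themselves. A pass whose pool has fewer than 3 OTUs, or whose control
#' means carry no signal (all zero or all identical), is recorded as skipped.
#'
#' @param counts A [count_table()].
#' @param metadata A [sample_metadata()].
#' @param luminosity A [luminosity_table()].
#' @param config A [filter_config()].
#' @return A list of class `filter_result` with elements `retained_otus`
#'   (sorted character vector), `report` (per-step data.frame), `fits`
#'   (list of `regression_fit` per regression pass), `filtered_counts`
#'   (the depth-filtered count table restricted to retained OTUs) and
#'   `weights` (the luminosity weights used).
#' @export
run_contaminant_pipeline <- function(counts, metadata, luminosity,
                                     config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  validate_experiment(counts, metadata, luminosity)

  report <- list()
  fits <- list()
  n_samples_in <- nrow(counts)
  n_otus_in <- ncol(counts)
  add_row <- function(step, action, n_samples, n_otus, removed, note = "") {
    report[[length(report) + 1L]] <<- data.frame(
      step = step, action = action, n_samples = n_samples,
      n_otus_retained = n_otus, n_removed = removed, note = note,
      stringsAsFactors = FALSE)
  }

  # (a) depth filter
  kept <- filter_samples_by_depth(counts, config$min_depth)
  add_row("a", sprintf("remove samples with < %d reads", config$min_depth),
          nrow(kept), ncol(kept), n_samples_in - nrow(kept))

  # (b) relative abundances
  rel <- to_relative(kept)
  add_row("b", "convert counts to relative abundances", nrow(kept),
          ncol(kept), 0L)

  # (c) luminosity weighting
  weights <- relative_luminosity(luminosity, mode = config$luminosity_mode)
  weighted <- weight_by_luminosity(rel, weights)
  zero_w <- sum(weights[rownames(weighted)] == 0)
  add_row("c", sprintf("weight by relative band luminosity (%s)",
                       config$luminosity_mode),
          nrow(kept), ncol(kept), 0L,
          if (zero_w > 0) sprintf("%d sample(s) with weight 0", zero_w) else "")

  # (d) sample-type means
  means <- sample_type_means(weighted, metadata)
  add_row("d", "per-OTU mean weighted abundance per sample type",
          nrow(kept), ncol(kept), 0L)
  subject_means <- means[, "subject"]
  blank_means <- means[, "blank_control"]
  water_means <- means[, "water_control"]

  # (e) rare-OTU removal
  pool <- remove_rare_otus(subject_means, config$rare_fraction)
  add_row("e", sprintf("remove OTUs below %g of summed subject abundance",
                       config$rare_fraction),
          nrow(kept), length(pool), ncol(kept) - length(pool))

  extracted <- character()
  run_pass <- function(step, pool, control_means, label) {
    # returns list(outliers, fit or NULL, note)
    if (length(pool) < 3) {
      return(list(outliers = character(), fit = NULL,
                  note = sprintf("skipped: only %d OTU(s) in pool",
                                 length(pool))))
    }
    ctrl <- control_means[pool]
    if (all(ctrl == 0)) {
      return(list(outliers = character(), fit = NULL,
                  note = "skipped: no control signal for remaining OTUs"))
    }
    subj <- subject_means[pool]
    eps_pool <- c(subj, ctrl)
    x_chk <- log(ctrl + min(eps_pool[eps_pool > 0]) / 2)
    if (stats::var(x_chk) == 0) {
      return(list(outliers = character(), fit = NULL,
                  note = "skipped: zero predictor variance"))
    }
    fit <- tryCatch(
      fit_control_regression(subject_means, control_means, pool,
                             predictor_label = label),
      error = function(e) step_stop(step, conditionMessage(e)))
    out <- regression_retain(fit, subject_means, control_means, pool,
                             config$se_multiplier)
    list(outliers = out, fit = fit, note = "")
  }

  if (config$pass_mode == "accumulate") {
    # pass 1 (f,g): blank controls on the full pool
    p1 <- run_pass("f", pool, blank_means, "blank_control")
    fits$pass1_blank <- p1$fit
    add_row("f", "fit blank-control regression (pass 1)", nrow(kept),
            length(pool), 0L, p1$note)
    extracted <- union(extracted, p1$outliers)
    pool <- setdiff(pool, p1$outliers)
    add_row("g", "extract positive outliers as truly present", nrow(kept),
            length(pool) + length(extracted), 0L,
            sprintf("%d OTU(s) extracted", length(p1$outliers)))

    # pass 2 (h): blank controls on the remaining pool
    p2 <- run_pass("h", pool, blank_means, "blank_control")
    fits$pass2_blank <- p2$fit
    extracted <- union(extracted, p2$outliers)
    pool <- setdiff(pool, p2$outliers)
    add_row("h", "repeat blank-control regression on remaining pool",
            nrow(kept), length(pool) + length(extracted), 0L,
            trim_note(sprintf("%d OTU(s) extracted; %s",
                              length(p2$outliers), p2$note)))

    # pass 3 (i): water controls on the remaining pool; the unextracted pool
    # is then discarded as contamination
    p3 <- run_pass("i", pool, water_means, "water_control")
    fits$pass3_water <- p3$fit
    extracted <- union(extracted, p3$outliers)
    discarded <- setdiff(pool, p3$outliers)
    retained <- extracted
    add_row("i", "water-control regression; discard unextracted pool",
            nrow(kept), length(retained), length(discarded),
            trim_note(sprintf("%d OTU(s) extracted; %s",
                              length(p3$outliers), p3$note)))
  } else {
    # survivor wiring: each pass re-fits on the previously retained outliers
    p1 <- run_pass("f", pool, blank_means, "blank_control")
    fits$pass1_blank <- p1$fit
    add_row("f", "fit blank-control regression (pass 1)", nrow(kept),
            length(pool), 0L, p1$note)
    retained <- if (is.null(p1$fit)) character() else p1$outliers
    add_row("g", "retain positive outliers", nrow(kept), length(retained),
            length(pool) - length(retained))

    p2 <- run_pass("h", retained, blank_means, "blank_control")
    fits$pass2_blank <- p2$fit
    prev <- length(retained)
    if (!is.null(p2$fit)) retained <- p2$outliers
    add_row("h", "repeat blank-control regression on retained set",
            nrow(kept), length(retained), prev - length(retained), p2$note)

    p3 <- run_pass("i", retained, water_means, "water_control")
    fits$pass3_water <- p3$fit
    prev <- length(retained)
    if (!is.null(p3$fit)) retained <- p3$outliers
    add_row("i", "water-control regression on retained set",
            nrow(kept), length(retained), prev - length(retained), p3$note)
  }

  retained <- sort(retained)
  report <- do.call(rbind, report)
  structure(list(
    retained_otus = retained,
    report = report,
    fits = fits,
    filtered_counts = if (length(retained) > 0) {
      count_table(unclass_matrix(kept)[, retained, drop = FALSE])
    } else NULL,
    weights = weights,
    config = config
  ), class = "filter_result")
}

trim_note <- function(x) sub("; $", "", x)

#' @export
print.filter_result <- function(x, ...) {
  cat("Contaminant filtering report:\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("Final retained OTUs: %d\n", length(x$retained_otus)))
  invisible(x)
}

#' Write the outputs of a filter run to a directory
#'
#' Writes the retained OTU list (`retained_otus.tsv`), the filtered count
#' table (`filtered_counts.tsv`, depth-passing samples x retained OTUs) and
#' the per-step attrition report (`filter_report.tsv`).
#'
#' @param result A `filter_result` from [run_contaminant_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_filter_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(otu_id = result$retained_otus, stringsAsFactors = FALSE),
    file.path(dir, "retained_otus.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$filtered_counts)) {
    write_count_table(result$filtered_counts,
                      file.path(dir, "filtered_counts.tsv"))
  }
  utils::write.table(result$report, file.path(dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
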