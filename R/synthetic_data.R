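# Synthetic low-biomass amplicon experiments with known contamination
# structure. The generative model mirrors the assumption under which the
# negative-control regression filter is coherent: reagent contaminants enter
# every library as a fixed absolute spike per OTU, independent of specimen
# biomass, so their relative abundance is inversely related to sample biomass
# and their control abundance predicts their subject abundance.

GENERA_POOL <- data.frame(
  genus  = c("Corynebacterium", "Sphingomonas", "Streptococcus",
             "Acinetobacter", "Pseudomonas", "Staphylococcus",
             "Massilia", "Rothia", "Anaerococcus", "Micrococcus",
             "unclassified"),
  family = c("Corynebacteriaceae", "Sphingomonadaceae", "Streptococcaceae",
             "Moraxellaceae", "Pseudomonadaceae", "Staphylococcaceae",
             "Oxalobacteraceae", "Micrococcaceae", "Peptoniphilaceae",
             "Micrococcaceae", "unclassified"),
  order  = c("Corynebacteriales", "Sphingomonadales", "Lactobacillales",
             "Pseudomonadales", "Pseudomonadales", "Bacillales",
             "Burkholderiales", "Micrococcales", "Tissierellales",
             "Micrococcales", "unclassified"),
  class  = c("Actinomycetia", "Alphaproteobacteria", "Bacilli",
             "Gammaproteobacteria", "Gammaproteobacteria", "Bacilli",
             "Betaproteobacteria", "Actinomycetia", "Tissierellia",
             "Actinomycetia", "unclassified"),
  phylum = c("Actinobacteria", "Proteobacteria", "Firmicutes",
             "Proteobacteria", "Proteobacteria", "Firmicutes",
             "Proteobacteria", "Actinobacteria", "Firmicutes",
             "Actinobacteria", "unclassified"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic experiment generator
#'
#' Defaults emulate a three-visit longitudinal ocular-surface cohort:
#' 45 subjects sampled at baseline, one month and three months, 9 blank-swab
#' and 3 water negative controls, sequencing depths of 54,652 +/- 28,912
#' reads (truncated at 1,000), and a per-sample true community of roughly
#' 10-40 OTUs (a stable per-subject core plus sporadically present OTUs).
#'
#' @param n_subjects Number of enrolled subjects.
#' @param n_times Number of sampling time points (max 3 under the default
#'   time-point labels).
#' @param n_blank_controls Number of blank-swab negative controls.
#' @param n_water_controls Number of nuclease-free water controls.
#' @param n_true_otus Number of OTUs genuinely resident on the sampled
#'   surface.
#' @param n_contaminant_otus Number of reagent-contaminant OTUs.
#' @param core_size_per_subject Number of true OTUs stably present in each
#'   subject at every time point.
#' @param sporadic_prob Per-sample presence probability of each non-core true
#'   OTU.
#' @param subject_biomass_log_mean,subject_biomass_log_sd Parameters (log
#'   scale) of the per-sample target biomass, in arbitrary absolute units.
#' @param control_biomass_fraction Ratio of control (handling/cross-over)
#'   biomass to mean subject biomass; must be in (0, 1) and is much less
#'   than 1 for the contaminant-dominated controls the filter assumes.
#' @param contaminant_concentration_log_mean,contaminant_concentration_log_sd
#'   Parameters (log scale) of the per-OTU reagent contaminant concentration,
#'   on the same absolute scale as biomass.
#' @param depth_mean,depth_sd Sequencing depth distribution (normal,
#'   truncated at `depth_min`).
#' @param depth_min Minimum sequencing depth (truncation point).
#' @param luminosity_noise_sd Standard deviation of multiplicative
#'   (log-normal) noise on band luminosity.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output bundles.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 45,
                              n_times = 3,
                              n_blank_controls = 9,
                              n_water_controls = 3,
                              n_true_otus = 40,
                              n_contaminant_otus = 150,
                              core_size_per_subject = 10,
                              sporadic_prob = 0.3,
                              subject_biomass_log_mean = log(2e4),
                              subject_biomass_log_sd = 0.8,
                              control_biomass_fraction = 0.01,
                              contaminant_concentration_log_mean = log(3),
                              contaminant_concentration_log_sd = 1.5,
                              depth_mean = 54652,
                              depth_sd = 28912,
                              depth_min = 1000,
                              luminosity_noise_sd = 0.2,
                              seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_times = n_times,
              n_blank_controls = n_blank_controls,
              n_water_controls = n_water_controls,
              n_true_otus = n_true_otus,
              n_contaminant_otus = n_contaminant_otus,
              core_size_per_subject = core_size_per_subject,
              sporadic_prob = sporadic_prob,
              subject_biomass_log_mean = subject_biomass_log_mean,
              subject_biomass_log_sd = subject_biomass_log_sd,
              control_biomass_fraction = control_biomass_fraction,
              contaminant_concentration_log_mean = contaminant_concentration_log_mean,
              contaminant_concentration_log_sd = contaminant_concentration_log_sd,
              depth_mean = depth_mean, depth_sd = depth_sd,
              depth_min = depth_min,
              luminosity_noise_sd = luminosity_noise_sd,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  pos_int <- c("n_subjects", "n_times", "n_blank_controls", "n_water_controls",
               "n_true_otus", "n_contaminant_otus", "core_size_per_subject")
  for (f in pos_int) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop(sprintf("config field '%s' must be a positive integer", f))
    }
  }
  if (cfg$core_size_per_subject > cfg$n_true_otus) {
    stop("core_size_per_subject must not exceed n_true_otus")
  }
  if (cfg$n_times > length(DEFAULT_TIME_POINTS)) {
    stop(sprintf("n_times must be <= %d", length(DEFAULT_TIME_POINTS)))
  }
  if (!is.numeric(cfg$control_biomass_fraction) ||
      cfg$control_biomass_fraction <= 0 || cfg$control_biomass_fraction >= 1) {
    stop("control_biomass_fraction must lie in (0, 1)")
  }
  if (cfg$sporadic_prob < 0 || cfg$sporadic_prob > 1) {
    stop("sporadic_prob must lie in [0, 1]")
  }
  for (f in c("subject_biomass_log_sd", "contaminant_concentration_log_sd",
              "depth_sd", "luminosity_noise_sd")) {
    if (cfg[[f]] < 0) stop(sprintf("config field '%s' must be >= 0", f))
  }
  if (cfg$depth_min < 1 || cfg$depth_mean <= 0) {
    stop("depth_min must be >= 1 and depth_mean positive")
  }
  if (!is.finite(cfg$seed)) stop("seed must be a finite integer")
  invisible(cfg)
}

#' Generate a complete synthetic low-biomass amplicon experiment
#'
#' Per-sample generative model: each subject carries an individual-specific
#' community profile over the true OTU pool (a fixed core present at every
#' visit plus sporadically present non-core OTUs); absolute true abundances
#' are the profile scaled by a log-normal per-sample biomass. Controls carry
#' a small background community over the same pool (handling/cross-over,
#' `control_biomass_fraction` of mean subject biomass). Every library
#' additionally receives the same absolute reagent-contaminant spike (one
#' log-normal concentration per contaminant OTU), independent of biomass, so
#' contaminants dominate the low-biomass controls. Observed counts are a
#' multinomial draw of the combined relative abundances at a truncated-normal
#' sequencing depth; luminosity equals the sample's true (target) biomass
#' with multiplicative log-normal noise.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_bundle` with elements `counts`
#'   ([count_table()]), `metadata` ([sample_metadata()]), `taxonomy`
#'   ([taxonomy_map()]), `luminosity` ([luminosity_table()]) and `truth`
#'   (list with `true_otu_ids`, `contaminant_otu_ids` and per-subject
#'   `core_membership`).
#' @export
generate_experiment <- function(config = simulation_config()) {
  validate_simulation_config(config)
  cfg <- config
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  n_otus <- cfg$n_true_otus + cfg$n_contaminant_otus
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  true_ids <- otu_ids[seq_len(cfg$n_true_otus)]
  cont_ids <- setdiff(otu_ids, true_ids)

  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  times <- DEFAULT_TIME_POINTS[seq_len(cfg$n_times)]
  subj_samples <- as.vector(t(outer(subjects, seq_along(times),
                                    function(s, i) paste0(s, "_T", i))))
  blanks <- sprintf("BLANK%02d", seq_len(cfg$n_blank_controls))
  waters <- sprintf("WATER%02d", seq_len(cfg$n_water_controls))
  samples <- c(subj_samples, blanks, waters)

  metadata <- sample_metadata(data.frame(
    sample_id = samples,
    sample_type = c(rep("subject", length(subj_samples)),
                    rep("blank_control", length(blanks)),
                    rep("water_control", length(waters))),
    subject_id = c(rep(subjects, each = length(times)),
                   rep("", length(blanks) + length(waters))),
    time_point = c(rep(times, times = length(subjects)),
                   rep("", length(blanks) + length(waters))),
    stringsAsFactors = FALSE
  ), time_points = times)

  # per-OTU base abundance weights and per-subject OTU affinity: individual
  # specific but temporally stable profiles
  base_w <- stats::rlnorm(cfg$n_true_otus, meanlog = 0, sdlog = 1)
  names(base_w) <- true_ids
  subj_effect <- matrix(stats::rnorm(cfg$n_subjects * cfg$n_true_otus,
                                     sd = 0.7),
                        nrow = cfg$n_subjects,
                        dimnames = list(subjects, true_ids))
  core_membership <- lapply(subjects, function(s) {
    sort(sample(true_ids, cfg$core_size_per_subject))
  })
  names(core_membership) <- subjects

  contaminant_conc <- stats::rlnorm(
    cfg$n_contaminant_otus,
    meanlog = cfg$contaminant_concentration_log_mean,
    sdlog = cfg$contaminant_concentration_log_sd)
  names(contaminant_conc) <- cont_ids

  mean_subject_biomass <- exp(cfg$subject_biomass_log_mean +
                              cfg$subject_biomass_log_sd^2 / 2)
  control_biomass <- cfg$control_biomass_fraction * mean_subject_biomass

  counts <- matrix(0L, nrow = length(samples), ncol = n_otus,
                   dimnames = list(samples, otu_ids))
  true_biomass <- stats::setNames(numeric(length(samples)), samples)

  draw_depth <- function() {
    repeat {
      d <- round(stats::rnorm(1, cfg$depth_mean, cfg$depth_sd))
      if (d >= cfg$depth_min) return(d)
    }
  }

  for (s in subjects) {
    core <- core_membership[[s]]
    for (ti in seq_along(times)) {
      id <- paste0(s, "_T", ti)
      present <- union(core, true_ids[stats::runif(cfg$n_true_otus) <
                                        cfg$sporadic_prob])
      w <- base_w[present] * exp(subj_effect[s, present] +
                                 stats::rnorm(length(present), sd = 0.5))
      biomass <- stats::rlnorm(1, cfg$subject_biomass_log_mean,
                               cfg$subject_biomass_log_sd)
      abs_true <- stats::setNames(numeric(n_otus), otu_ids)
      abs_true[present] <- biomass * w / sum(w)
      abs_all <- abs_true
      abs_all[cont_ids] <- abs_all[cont_ids] + contaminant_conc
      counts[id, ] <- as.integer(stats::rmultinom(1, draw_depth(),
                                                  abs_all / sum(abs_all)))
      true_biomass[id] <- biomass
    }
  }

  for (id in c(blanks, waters)) {
    # background (handling / cross-over) community over the true pool
    present <- true_ids[stats::runif(cfg$n_true_otus) < cfg$sporadic_prob]
    abs_true <- stats::setNames(numeric(n_otus), otu_ids)
    if (length(present) > 0) {
      w <- base_w[present] * exp(stats::rnorm(length(present), sd = 0.5))
      abs_true[present] <- control_biomass * w / sum(w)
    }
    abs_all <- abs_true
    abs_all[cont_ids] <- abs_all[cont_ids] + contaminant_conc
    counts[id, ] <- as.integer(stats::rmultinom(1, draw_depth(),
                                                abs_all / sum(abs_all)))
    true_biomass[id] <- sum(abs_true)
  }

  lum <- true_biomass * exp(stats::rnorm(length(true_biomass),
                                         sd = cfg$luminosity_noise_sd))
  # a zero-biomass sample yields a zero-luminosity band
  lum[true_biomass == 0] <- 0

  taxonomy <- taxonomy_map(data.frame(
    otu_id = otu_ids,
    phylum = GENERA_POOL$phylum[(seq_len(n_otus) - 1L) %% nrow(GENERA_POOL) + 1L],
    class  = GENERA_POOL$class[(seq_len(n_otus) - 1L) %% nrow(GENERA_POOL) + 1L],
    order  = GENERA_POOL$order[(seq_len(n_otus) - 1L) %% nrow(GENERA_POOL) + 1L],
    family = GENERA_POOL$family[(seq_len(n_otus) - 1L) %% nrow(GENERA_POOL) + 1L],
    genus  = GENERA_POOL$genus[(seq_len(n_otus) - 1L) %% nrow(GENERA_POOL) + 1L],
    stringsAsFactors = FALSE
  ))

  bundle <- list(
    counts = count_table(counts),
    metadata = metadata,
    taxonomy = taxonomy,
    luminosity = luminosity_table(lum),
    truth = list(true_otu_ids = true_ids,
                 contaminant_otu_ids = cont_ids,
                 core_membership = core_membership),
    config = cfg
  )
  class(bundle) <- "synthetic_bundle"
  bundle
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_bundle> %d samples x %d OTUs ",
                     "(%d true, %d contaminant), seed %d\n"),
              nrow(x$counts), ncol(x$counts),
              length(x$truth$true_otu_ids),
              length(x$truth$contaminant_otu_ids), x$config$seed))
  invisible(x)
}

#' Confusion summary of a retained OTU set against ground truth
#'
#' Treats "retained by the filter" as a positive call for true residency.
#' Sensitivity is the fraction of truly resident OTUs retained; specificity
#' is the fraction of contaminant OTUs removed.
#'
#' @param retained_otus Character vector of retained OTU ids.
#' @param truth Truth list from [generate_experiment()] (elements
#'   `true_otu_ids`, `contaminant_otu_ids`).
#' @return A list with `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`.
#' @export
truth_confusion <- function(retained_otus, truth) {
  all_ids <- c(truth$true_otu_ids, truth$contaminant_otu_ids)
  unknown <- setdiff(retained_otus, all_ids)
  if (length(unknown) > 0) {
    stop("retained OTU id(s) unknown to truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  tp <- length(intersect(retained_otus, truth$true_otu_ids))
  fp <- length(intersect(retained_otus, truth$contaminant_otu_ids))
  fn <- length(truth$true_otu_ids) - tp
  tn <- length(truth$contaminant_otu_ids) - fp
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Write a synthetic bundle to a directory of TSV files
#'
#' Writes `counts.tsv`, `metadata.tsv`, `taxonomy.tsv`, `luminosity.tsv` in
#' the package TSV dialect plus `truth.tsv` (one row per OTU with its
#' true/contaminant label). Re-reading with [read_bundle()] reproduces the
#' tables.
#'
#' @param bundle A `synthetic_bundle` from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing bundle files? Default `FALSE`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, force = FALSE) {
  files <- file.path(dir, c("counts.tsv", "metadata.tsv", "taxonomy.tsv",
                            "luminosity.tsv", "truth.tsv"))
  if (!force && any(file.exists(files))) {
    stop("bundle files already exist in ", dir, " (use force = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(bundle$counts, files[1])
  write_metadata(bundle$metadata, files[2])
  write_taxonomy(bundle$taxonomy, files[3])
  write_luminosity(bundle$luminosity, files[4])
  truth_df <- data.frame(
    otu_id = c(bundle$truth$true_otu_ids, bundle$truth$contaminant_otu_ids),
    label = c(rep("true", length(bundle$truth$true_otu_ids)),
              rep("contaminant", length(bundle$truth$contaminant_otu_ids))),
    stringsAsFactors = FALSE)
  truth_df <- truth_df[order(truth_df$otu_id), ]
  utils::write.table(truth_df, files[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Read the TSV tables of a written bundle back
#'
#' @param dir Directory previously written by [write_bundle()].
#' @return A list with `counts`, `metadata`, `taxonomy`, `luminosity` and
#'   `truth` (the latter without per-subject core membership, which is not
#'   serialised).
#' @export
read_bundle <- function(dir) {
  truth_df <- read_tsv_checked(file.path(dir, "truth.tsv"))
  list(
    counts = read_count_table(file.path(dir, "counts.tsv"), "samples_rows"),
    metadata = read_metadata(file.path(dir, "metadata.tsv")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    luminosity = read_luminosity(file.path(dir, "luminosity.tsv")),
    truth = list(
      true_otu_ids = truth_df$otu_id[truth_df$label == "true"],
      contaminant_otu_ids = truth_df$otu_id[truth_df$label == "contaminant"])
  )
}
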