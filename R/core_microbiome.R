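# Presence/absence and prevalence analysis across subjects and time points.
# The core microbiome is defined as the taxa present in all subjects at all
# time points; prevalence summaries relax that to fractions of subjects and
# any-time presence.

#' Collapse an OTU count table to a higher taxonomic rank
#'
#' Counts are summed over OTUs sharing the rank label; OTUs unclassified at
#' that rank are pooled into a single `"unclassified"` taxon. Total counts
#' are conserved at every rank.
#'
#' @param counts A [count_table()].
#' @param taxonomy A [taxonomy_map()] covering the table's OTUs.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return A [count_table()] whose columns are taxa at the requested rank.
#' @export
collapse_taxonomy <- function(counts, taxonomy, rank) {
  if (!rank %in% TAXONOMY_RANKS) {
    stop("unknown rank '", rank, "'; expected one of ",
         paste(TAXONOMY_RANKS, collapse = ", "))
  }
  m <- unclass_matrix(counts)
  labels <- taxonomy[[rank]][match(colnames(m), taxonomy$otu_id)]
  if (anyNA(labels)) {
    stop("OTU(s) missing from taxonomy: ",
         paste(utils::head(colnames(m)[is.na(labels)], 5), collapse = ", "))
  }
  collapsed <- t(rowsum(t(m), group = labels))
  count_table(collapsed)
}

#' Boolean presence table over (taxon, subject, time point)
#'
#' Presence is `count >= detection_threshold` in the subject's sample at that
#' time point; duplicate samples for the same (subject, time) cell are
#' OR-combined. A (subject, time) cell with no underlying sample is `NA`
#' (missing), never `FALSE`: absence of evidence is kept distinct from
#' evidence of absence.
#'
#' @param counts A [count_table()] (any rank).
#' @param metadata A [sample_metadata()] covering the table's samples.
#' @param detection_threshold Minimum count declaring a taxon present
#'   (default 1 read).
#' @return A logical 3-d array of class `presence_table` with dimensions
#'   taxon x subject x time and a `detection_threshold` attribute.
#' @export
presence_table <- function(counts, metadata, detection_threshold = 1) {
  if (detection_threshold < 1) stop("detection_threshold must be >= 1")
  m <- unclass_matrix(counts)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  subj_rows <- which(meta$sample_type == "subject")
  if (length(subj_rows) == 0) stop("no subject samples in the count table")
  m <- m[subj_rows, , drop = FALSE]
  meta <- meta[subj_rows, , drop = FALSE]
  subjects <- sort(unique(meta$subject_id))
  times <- levels(meta$time_point)
  arr <- array(NA, dim = c(ncol(m), length(subjects), length(times)),
               dimnames = list(taxon = colnames(m), subject = subjects,
                               time = times))
  for (i in seq_len(nrow(m))) {
    s <- meta$subject_id[i]
    tp <- as.character(meta$time_point[i])
    present <- m[i, ] >= detection_threshold
    prev <- arr[, s, tp]
    arr[, s, tp] <- ifelse(is.na(prev), present, prev | present)
  }
  structure(arr, detection_threshold = detection_threshold,
            class = c("presence_table", "array"))
}

complete_subjects <- function(presence) {
  # subjects with a sample at every time point (no missing cells)
  has_cell <- apply(!is.na(presence), c(2, 3), all)
  names(which(apply(has_cell, 1, all)))
}

#' Core taxa across subjects and time points
#'
#' With `subject_fraction = 1` and `require_all_times = TRUE` this is the
#' strict core-microbiome definition: taxa present in all subjects at all
#' time points. Subjects with incomplete sampling (any missing time point)
#' are excluded from the denominator, so a discontinued subject does not
#' veto the core.
#'
#' @param presence A [presence_table()].
#' @param subject_fraction Minimum fraction of (complete) subjects in which
#'   the taxon must qualify, in (0, 1].
#' @param require_all_times If `TRUE` a subject only counts when the taxon is
#'   present at every time point; if `FALSE`, presence at any time point
#'   suffices.
#' @return Character vector of core taxa.
#' @export
core_taxa <- function(presence, subject_fraction = 1,
                      require_all_times = TRUE) {
  if (subject_fraction <= 0 || subject_fraction > 1) {
    stop("subject_fraction must lie in (0, 1]")
  }
  subj <- complete_subjects(presence)
  if (length(subj) == 0) return(character())
  p <- presence[, subj, , drop = FALSE]
  per_subject <- if (require_all_times) {
    apply(p, c(1, 2), all)
  } else {
    apply(p, c(1, 2), any)
  }
  frac <- rowMeans(per_subject)
  names(frac)[frac >= subject_fraction]
}

#' Per-taxon prevalence summary
#'
#' For each taxon, counts and fractions of complete subjects in which it is
#' present at all time points and at any time point, plus (as an attribute
#' and in the print) the number of taxa with all-times presence in at least
#' one subject.
#'
#' @param presence A [presence_table()].
#' @return A data.frame of class `core_summary` with one row per taxon:
#'   `taxon`, `n_subjects_all_times`, `n_subjects_any_time`,
#'   `frac_subjects_all_times`, `frac_subjects_any_time`; attributes
#'   `n_complete_subjects` and `n_taxa_all_times_ge1_subject`.
#' @export
prevalence_summary <- function(presence) {
  subj <- complete_subjects(presence)
  n_subj <- length(subj)
  taxa <- dimnames(presence)$taxon
  if (n_subj == 0) {
    all_t <- any_t <- stats::setNames(integer(length(taxa)), taxa)
  } else {
    p <- presence[, subj, , drop = FALSE]
    all_t <- apply(p, 1, function(g) sum(apply(g, 1, all)))
    any_t <- apply(p, 1, function(g) sum(apply(g, 1, any)))
  }
  out <- data.frame(
    taxon = taxa,
    n_subjects_all_times = as.integer(all_t),
    n_subjects_any_time = as.integer(any_t),
    frac_subjects_all_times = if (n_subj > 0) all_t / n_subj else NA_real_,
    frac_subjects_any_time = if (n_subj > 0) any_t / n_subj else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            n_complete_subjects = n_subj,
            n_taxa_all_times_ge1_subject = sum(out$n_subjects_all_times >= 1),
            class = c("core_summary", "data.frame"))
}

#' Isolation proportions from culture presence data
#'
#' Culture results enter as an ordinary presence table: a logical matrix of
#' samples x taxa (`TRUE` when the taxon was isolated from that sample),
#' with an optional per-sample time-point label. Returns the proportion of
#' samples positive for each taxon, overall and per time point.
#'
#' @param isolated Logical matrix, samples in rows, taxa in columns.
#' @param time_point Optional character/factor vector of per-sample time
#'   points (same length as `nrow(isolated)`).
#' @return A data.frame with one row per taxon: `taxon`, `n_samples`,
#'   `n_positive`, `proportion`, plus one `prop_<time>` column per time
#'   point when `time_point` is given.
#' @export
culture_presence_summary <- function(isolated, time_point = NULL) {
  if (!is.matrix(isolated) || !is.logical(isolated)) {
    stop("`isolated` must be a logical matrix (samples x taxa)")
  }
  out <- data.frame(
    taxon = colnames(isolated),
    n_samples = nrow(isolated),
    n_positive = as.integer(colSums(isolated)),
    proportion = colMeans(isolated),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(time_point)) {
    if (length(time_point) != nrow(isolated)) {
      stop("time_point must have one entry per sample")
    }
    for (tp in unique(as.character(time_point))) {
      rows <- as.character(time_point) == tp
      out[[paste0("prop_", tp)]] <- colMeans(isolated[rows, , drop = FALSE])
    }
  }
  out
}
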