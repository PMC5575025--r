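# Canonical orientation everywhere in the package: samples in rows, OTUs in
# columns. TSV dialect: tab-delimited, UTF-8, first row is a header, no
# quoting of identifiers.

TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus")
UNCLASSIFIED <- "unclassified"
SAMPLE_TYPES <- c("subject", "blank_control", "water_control")
DEFAULT_TIME_POINTS <- c("baseline", "month1", "month3")

#' Construct a validated OTU count table
#'
#' A count table is an integer matrix of sequence read counts with samples in
#' rows and OTUs in columns. All counts must be non-negative integers and the
#' row (sample) and column (OTU) identifiers must be unique and non-empty.
#'
#' @param counts A numeric matrix of read counts. Row names are sample
#'   identifiers, column names are OTU identifiers.
#' @return An integer matrix of class `count_table`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("count table must contain at least one sample and one OTU")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table must carry sample (row) and OTU (column) identifiers")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU identifiers")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral read counts")
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d OTUs, total %s reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

drop_ct_class <- function(x) {
  class(x) <- setdiff(class(x), "count_table")
  x
}

#' Read an OTU count table from TSV
#'
#' The file orientation must be declared explicitly: `"samples_rows"` means
#' rows are samples and columns OTUs; `"otus_rows"` the transpose. The
#' returned table is always in canonical samples x OTUs orientation, so
#' reading a transposed file with the flipped flag yields an identical table.
#'
#' @param path Path to a tab-delimited file with a header row and row
#'   identifiers in the first column.
#' @param orientation Either `"samples_rows"` or `"otus_rows"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, orientation = c("samples_rows", "otus_rows")) {
  orientation <- match.arg(orientation)
  df <- read_tsv_checked(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric count in column '%s' of %s",
                 names(df)[bad + 1L], path))
  }
  rownames(m) <- as.character(df[[1]])
  if (orientation == "otus_rows") m <- t(m)
  count_table(m)
}

#' Write an OTU count table to TSV
#'
#' @param counts A [count_table()] (or bare counts matrix).
#' @param path Output file path.
#' @param orientation Orientation to write (see [read_count_table()]).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path,
                              orientation = c("samples_rows", "otus_rows")) {
  orientation <- match.arg(orientation)
  counts <- count_table(unclass_matrix(counts))
  m <- drop_ct_class(counts)
  id_col <- "sample_id"
  if (orientation == "otus_rows") {
    m <- t(m)
    id_col <- "otu_id"
  }
  write_tsv_matrix(m, path, id_col)
}

#' Construct validated per-sample metadata
#'
#' Each sample is one of three types: `subject` (an ocular-surface specimen
#' from an enrolled subject at a named time point), `blank_control` (an
#' unused swab processed identically, capturing swab/reagent/handling
#' contamination) or `water_control` (nuclease-free water through
#' PCR/sequencing, capturing reagent-only contamination). Subject samples
#' must carry `subject_id` and `time_point`; control samples must carry
#' neither.
#'
#' @param df A data.frame with columns `sample_id`, `sample_type`,
#'   `subject_id`, `time_point` (empty string or NA where not applicable).
#' @param time_points Ordered character vector of admissible time points.
#' @return A data.frame of class `sample_metadata`; `time_point` is a factor
#'   with levels in study order.
#' @export
sample_metadata <- function(df, time_points = DEFAULT_TIME_POINTS) {
  req <- c("sample_id", "sample_type", "subject_id", "time_point")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  df[is.na(df)] <- ""
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad_type <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "))
  }
  subj <- df$sample_type == "subject"
  if (any(subj & df$subject_id == "")) {
    stop("subject sample(s) missing subject_id: ",
         paste(df$sample_id[subj & df$subject_id == ""], collapse = ", "))
  }
  if (any(subj & df$time_point == "")) {
    stop("subject sample(s) missing time_point: ",
         paste(df$sample_id[subj & df$time_point == ""], collapse = ", "))
  }
  bad_tp <- setdiff(unique(df$time_point[subj]), time_points)
  if (length(bad_tp) > 0) {
    stop("unknown time_point label: ", paste(bad_tp, collapse = ", "))
  }
  if (any(!subj & (df$subject_id != "" | df$time_point != ""))) {
    stop("control samples must not carry subject_id or time_point")
  }
  df$time_point <- factor(df$time_point, levels = time_points)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @inheritParams sample_metadata
#' @param path Path to a tab-delimited file with columns `sample_id`,
#'   `sample_type`, `subject_id`, `time_point`.
#' @return A [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path, time_points = DEFAULT_TIME_POINTS) {
  df <- read_tsv_checked(path)
  sample_metadata(df, time_points = time_points)
}

#' Write sample metadata to TSV
#' @param metadata A [sample_metadata()] data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- as.data.frame(metadata)
  out$time_point <- as.character(out$time_point)
  out$time_point[is.na(out$time_point)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated taxonomy map
#'
#' Maps each OTU to a fixed-rank lineage (phylum, class, order, family,
#' genus). Unclassified ranks are represented by the explicit sentinel
#' `"unclassified"`, never by absence.
#'
#' @param df A data.frame with column `otu_id` plus the five rank columns.
#' @return A data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(df) {
  req <- c("otu_id", TAXONOMY_RANKS)
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("taxonomy lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy")
  for (col in TAXONOMY_RANKS) {
    blank <- is.na(df[[col]]) | df[[col]] == ""
    df[[col]][blank] <- UNCLASSIFIED
  }
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read a taxonomy table from TSV
#'
#' Expects two columns: `otu_id` and a semicolon-delimited lineage string in
#' mothur/QIIME style (`Bacteria;Phylum;Class;Order;Family;Genus` or without
#' the leading domain). Bootstrap annotations like `(100)` are stripped.
#' Missing trailing ranks are filled with the `"unclassified"` sentinel.
#'
#' @param path Path to the TSV file.
#' @return A [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("taxonomy TSV needs otu_id and lineage columns")
  otu_id <- as.character(df[[1]])
  lineage <- as.character(df[[2]])
  parsed <- lapply(lineage, parse_lineage)
  tax <- as.data.frame(do.call(rbind, parsed), stringsAsFactors = FALSE)
  names(tax) <- TAXONOMY_RANKS
  taxonomy_map(cbind(data.frame(otu_id = otu_id, stringsAsFactors = FALSE), tax))
}

parse_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- gsub("\\([0-9.]+\\)", "", parts)   # strip bootstrap values
  parts <- trimws(parts)
  parts <- parts[parts != ""]
  # tolerate a leading domain rank (Bacteria/Archaea/...), which is above
  # phylum and not part of the stored lineage
  if (length(parts) > 0 &&
      tolower(parts[1]) %in% c("bacteria", "archaea", "eukaryota", "root", "k__bacteria")) {
    parts <- parts[-1]
  }
  if (length(parts) > length(TAXONOMY_RANKS)) {
    parts <- parts[seq_along(TAXONOMY_RANKS)]
  }
  out <- rep(UNCLASSIFIED, length(TAXONOMY_RANKS))
  if (length(parts) > 0) out[seq_along(parts)] <- parts
  out[out == ""] <- UNCLASSIFIED
  out
}

#' Write a taxonomy map to TSV (semicolon-delimited lineage)
#' @param taxonomy A [taxonomy_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  taxonomy <- taxonomy_map(taxonomy)
  lineage <- apply(as.data.frame(taxonomy)[TAXONOMY_RANKS], 1L,
                   paste, collapse = ";")
  out <- data.frame(otu_id = taxonomy$otu_id, lineage = lineage,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated PCR band luminosity table
#'
#' Band luminosity of the amplicon gel band acts as a surrogate for
#' per-sample target DNA concentration (microbial biomass), which is the
#' quantity the contaminant filter weights relative abundances by.
#' Luminosities are non-negative, in arbitrary units, and at least one sample
#' must have a positive value.
#'
#' @param x Either a named numeric vector (names are sample ids) or a
#'   data.frame with columns `sample_id` and `luminosity`.
#' @return A named numeric vector of class `luminosity_table`.
#' @export
luminosity_table <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "luminosity") %in% names(x))) {
      stop("luminosity data.frame needs columns sample_id and luminosity")
    }
    v <- as.numeric(x$luminosity)
    names(v) <- as.character(x$sample_id)
    x <- v
  }
  if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "")) {
    stop("luminosity must be a named numeric vector")
  }
  if (anyDuplicated(names(x))) stop("duplicate sample_id in luminosity table")
  if (any(!is.finite(x))) stop("luminosity must be finite")
  if (any(x < 0)) stop("luminosity must be non-negative")
  if (all(x == 0)) stop("all luminosities are zero; at least one must be positive")
  class(x) <- c("luminosity_table", "numeric")
  x
}

#' Read a PCR band luminosity table from TSV
#' @param path Path to a TSV with columns `sample_id` and `luminosity`.
#' @return A [luminosity_table()].
#' @export
read_luminosity <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("sample_id", "luminosity") %in% names(df))) {
    stop("luminosity TSV needs columns sample_id and luminosity")
  }
  if (!is.numeric(df$luminosity)) stop("non-numeric luminosity value in ", path)
  luminosity_table(df)
}

#' Write a luminosity table to TSV
#' @param luminosity A [luminosity_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_luminosity <- function(luminosity, path) {
  out <- data.frame(sample_id = names(luminosity),
                    luminosity = as.numeric(luminosity),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check cross-table consistency of an experiment before analysis
#'
#' Confirms that every sample in the count table has metadata; that every
#' subject sample has a luminosity entry; that both control types are
#' present (the regression filter needs blank-swab controls for its first two
#' passes and water controls for its final pass). Samples present in metadata
#' but absent from the count table are reported as warnings, not errors,
#' since longitudinal studies routinely lose samples (discontinued subjects,
#' failed libraries).
#'
#' @param counts A [count_table()].
#' @param metadata A [sample_metadata()] data.frame.
#' @param luminosity A [luminosity_table()].
#' @return Invisibly, a list with elements `errors` and `warnings`
#'   (character vectors); called primarily for its side effect of stopping
#'   on inconsistency.
#' @export
validate_experiment <- function(counts, metadata, luminosity) {
  errors <- character()
  warnings <- character()
  samples <- rownames(counts)
  missing_meta <- setdiff(samples, metadata$sample_id)
  if (length(missing_meta) > 0) {
    errors <- c(errors, paste0("count-table sample(s) absent from metadata: ",
                               paste(missing_meta, collapse = ", ")))
  }
  extra_meta <- setdiff(metadata$sample_id, samples)
  if (length(extra_meta) > 0) {
    warnings <- c(warnings,
                  paste0("metadata sample(s) absent from count table ",
                         "(will be ignored): ",
                         paste(extra_meta, collapse = ", ")))
  }
  meta_here <- metadata[metadata$sample_id %in% samples, , drop = FALSE]
  subj <- meta_here$sample_id[meta_here$sample_type == "subject"]
  no_lum <- setdiff(subj, names(luminosity))
  if (length(no_lum) > 0) {
    errors <- c(errors, paste0("subject sample(s) without luminosity entry: ",
                               paste(no_lum, collapse = ", ")))
  }
  ctrl_no_lum <- setdiff(setdiff(meta_here$sample_id, subj), names(luminosity))
  if (length(ctrl_no_lum) > 0) {
    warnings <- c(warnings,
                  paste0("control sample(s) without luminosity entry ",
                         "(required before step (c) weighting): ",
                         paste(ctrl_no_lum, collapse = ", ")))
  }
  if (!any(meta_here$sample_type == "blank_control")) {
    errors <- c(errors, paste0("no blank_control samples: pipeline cannot ",
                               "run steps f-h (blank-swab regression)"))
  }
  if (!any(meta_here$sample_type == "water_control")) {
    errors <- c(errors, paste0("no water_control samples: pipeline cannot ",
                               "run step (i) (water-control regression)"))
  }
  if (!any(meta_here$sample_type == "subject")) {
    errors <- c(errors, "no subject samples in the count table")
  }
  for (w in warnings) warning(w, call. = FALSE)
  if (length(errors) > 0) {
    stop(paste(errors, collapse = "\n  "), call. = FALSE)
  }
  invisible(list(errors = errors, warnings = warnings))
}

#' Read a count table from a BIOM (JSON, format 1.0) file
#'
#' Convenience wrapper around the biomformat package for tables exported by
#' QIIME-era tooling. The returned table is in canonical samples x OTUs
#' orientation (BIOM stores observations x samples).
#'
#' @param path Path to a JSON BIOM file.
#' @return A [count_table()].
#' @export
read_biom_counts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  count_table(t(m))
}

# ---- internal TSV helpers --------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 2) stop("malformed TSV (no data rows): ", path)
  # count separators directly: trailing empty fields must still count
  nfield <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  bad <- which(nfield != nfield[1])
  if (length(bad) > 0) {
    stop(sprintf("malformed TSV %s: line %d has %d fields, expected %d",
                 path, bad[1], nfield[bad[1]], nfield[1]))
  }
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

unclass_matrix <- function(x) {
  if (inherits(x, "count_table")) x <- drop_ct_class(x)
  x
}
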