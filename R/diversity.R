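# Alpha diversity (richness, Shannon), Bray-Curtis dissimilarity,
# rarefaction curves and temporal coefficient-of-variation summaries.
# Shannon and Bray-Curtis are delegated to vegan; rarefaction here is the
# Monte-Carlo subsampling estimator (vegan::rarefy's hypergeometric closed
# form serves as its cross-check in the tests).

#' Observed richness of a sample
#'
#' @param x Numeric count vector (one sample), or a counts matrix
#'   (samples x OTUs) for per-sample richness.
#' @return Number of OTUs with count >= 1 (vector in, scalar out; matrix in,
#'   named vector out).
#' @export
richness <- function(x) {
  if (is.matrix(x) || inherits(x, "count_table")) {
    return(rowSums(unclass_matrix(x) >= 1))
  }
  sum(x >= 1)
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over OTUs with positive relative abundance
#' `p_i`. Computed in nats by default; `base` rescales.
#'
#' @param x Numeric count (or relative-abundance) vector, or a matrix
#'   (samples x OTUs).
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (scalar for a vector, named vector for a matrix).
#' @export
shannon <- function(x, base = exp(1)) {
  if (is.matrix(x) || inherits(x, "count_table")) {
    m <- unclass_matrix(x)
    if (any(rowSums(m) == 0)) {
      stop("zero-total sample(s): ",
           paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
    }
    return(vegan::diversity(m, index = "shannon", base = base))
  }
  if (sum(x) == 0) stop("zero-total sample")
  unname(vegan::diversity(rbind(x), index = "shannon", base = base)[1])
}

#' Bray-Curtis dissimilarity
#'
#' `BC = sum|p_i - q_i| / sum(p_i + q_i)` computed on within-sample relative
#' abundances (not raw counts), so sequencing depth differences do not
#' masquerade as community differences. For a matrix input the full
#' symmetric labelled dissimilarity matrix is returned.
#'
#' @param a A counts matrix (samples x OTUs), or a single sample count
#'   vector when `b` is given.
#' @param b Optional second sample vector (pairwise mode).
#' @return A symmetric matrix of dissimilarities, or a scalar in pairwise
#'   mode; values in `[0, 1]`.
#' @export
bray_curtis <- function(a, b = NULL) {
  if (!is.null(b)) {
    if (sum(a) == 0 || sum(b) == 0) stop("zero-total sample")
    m <- rbind(a / sum(a), b / sum(b))
    return(as.numeric(vegan::vegdist(m, method = "bray")))
  }
  m <- unclass_matrix(a)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(m)[totals == 0], collapse = ", "))
  }
  rel <- sweep(m, 1L, totals, "/")
  as.matrix(vegan::vegdist(rel, method = "bray"))
}

#' Monte-Carlo rarefaction curve for one sample
#'
#' Expected richness under random subsampling of reads without replacement:
#' at each depth, the sample's reads are subsampled `n_reps` times and the
#' mean number of OTUs observed is reported. At the sample's full depth the
#' curve equals the observed richness exactly.
#'
#' @param x Integer count vector (one sample).
#' @param depths Integer vector of subsampling depths, each <= `sum(x)`.
#' @param n_reps Number of Monte-Carlo replicates per depth.
#' @param seed Integer seed for reproducibility.
#' @return A data.frame with columns `depth`, `mean_richness`, `sd_richness`.
#' @export
rarefaction_curve <- function(x, depths, n_reps = 100, seed = 1L) {
  total <- sum(x)
  if (total == 0) stop("zero-total sample")
  if (any(depths < 1) || any(depths > total)) {
    stop("depths must lie in [1, ", total, "]")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  reads <- rep.int(seq_along(x), x)
  res <- lapply(depths, function(d) {
    if (d == total) {
      rich <- rep(sum(x >= 1), n_reps)
    } else {
      rich <- vapply(seq_len(n_reps), function(i) {
        length(unique(sample(reads, d)))
      }, numeric(1))
    }
    data.frame(depth = d, mean_richness = mean(rich),
               sd_richness = stats::sd(rich))
  })
  do.call(rbind, res)
}

#' Per-taxon temporal coefficient of variation
#'
#' CV = sample standard deviation (n - 1 denominator) divided by the mean,
#' over a taxon's per-time mean relative abundances. A taxon with zero mean
#' is reported as `NA` (undefined); a constant taxon has CV 0. The CV is
#' scale-invariant, so it can be compared across taxa of very different
#' abundance.
#'
#' @param profile Numeric matrix, taxa in rows, time points in columns
#'   (e.g. from [time_profile()]); or a single taxon's numeric vector.
#' @return Named numeric vector of CVs (or a scalar for vector input).
#' @export
temporal_cv <- function(profile) {
  cv1 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    stats::sd(v) / m
  }
  if (is.matrix(profile)) {
    return(apply(profile, 1, cv1))
  }
  cv1(profile)
}

#' Per-time mean relative abundance profile
#'
#' For each taxon, the mean of its within-sample relative abundance over the
#' subject samples of each time point — the per-time summary that temporal
#' stability (CV) is computed on.
#'
#' @param counts A [count_table()] (any rank).
#' @param metadata A [sample_metadata()] covering the table's samples.
#' @return Numeric matrix, taxa x time points.
#' @export
time_profile <- function(counts, metadata) {
  m <- unclass_matrix(counts)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  rows <- which(meta$sample_type == "subject")
  if (length(rows) == 0) stop("no subject samples in the count table")
  rel <- to_relative(count_table(m[rows, , drop = FALSE]))
  tp <- droplevels(meta$time_point[rows])
  out <- sapply(levels(tp), function(t) {
    colMeans(rel[tp == t, , drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = 1,
                                       dimnames = list(colnames(m), levels(tp)))
  out
}

#' Per-sample alpha-diversity table
#'
#' @param counts A [count_table()].
#' @return A data.frame with columns `sample_id`, `depth`, `richness`,
#'   `shannon`.
#' @export
alpha_diversity <- function(counts) {
  m <- unclass_matrix(counts)
  data.frame(sample_id = rownames(m),
             depth = rowSums(m),
             richness = as.numeric(richness(m)),
             shannon = as.numeric(shannon(m)),
             stringsAsFactors = FALSE, row.names = NULL)
}
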