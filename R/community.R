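#' Transcripts-per-million normalisation
#'
#' Length-normalised abundance: each feature's read count is divided by
#' its length in kilobases, and the resulting rates are scaled to sum to
#' one million per sample, so values are comparable across samples with
#' different sequencing depth.
#'
#' @param counts numeric vector (one sample) or matrix (features x
#'   samples) of read counts.
#' @param lengths feature lengths in bp, parallel to rows.
#' @return object of the same shape with TPM values; columns of all-zero
#'   counts stay zero and are named in the `zero_samples` attribute.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  one <- function(x) {
    rate <- x / (lengths / 1000)
    s <- sum(rate)
    if (s == 0) rate else 1e6 * rate / s
  }
  if (is.matrix(counts)) {
    if (nrow(counts) != length(lengths))
      stop("lengths must match rows of counts", call. = FALSE)
    out <- apply(counts, 2L, one)
    dimnames(out) <- dimnames(counts)
    zero <- colSums(counts) == 0
    if (any(zero)) attr(out, "zero_samples") <- colnames(counts)[zero]
    out
  } else {
    if (length(counts) != length(lengths))
      stop("lengths must match counts", call. = FALSE)
    out <- one(counts)
    if (sum(counts) == 0) attr(out, "zero_samples") <- TRUE
    out
  }
}

#' Two-group comparison of feature abundances
#'
#' Per-feature two-sided Wilcoxon rank-sum test between two sample
#' groups (exact where no ties and small samples, normal approximation
#' with midranks otherwise), reporting the raw p-value with a
#' significance flag at p < 0.05 and the Benjamini-Hochberg FDR
#' alongside.
#'
#' @param table numeric matrix, features x samples (e.g. TPM), with
#'   sample names as column names.
#' @param group_a,group_b character vectors of sample names (at least 2
#'   each).
#' @return data.frame with `feature_id`, `median_a`, `median_b`,
#'   `p_value`, `bh_fdr`, `significant_raw`.
#' @export
compare_groups <- function(table, group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  missing_smp <- setdiff(c(group_a, group_b), colnames(table))
  if (length(missing_smp))
    stop("sample not in table: ", missing_smp[1L], call. = FALSE)
  a <- table[, group_a, drop = FALSE]
  b <- table[, group_b, drop = FALSE]
  p <- vapply(seq_len(nrow(table)), function(i)
    suppressWarnings(wilcox.test(a[i, ], b[i, ])$p.value), numeric(1))
  p[is.na(p)] <- 1  # constant features: no evidence of difference
  data.frame(
    feature_id = if (!is.null(rownames(table))) rownames(table)
                 else as.character(seq_len(nrow(table))),
    median_a = apply(a, 1L, median), median_b = apply(b, 1L, median),
    p_value = p, bh_fdr = p.adjust(p, "BH"),
    significant_raw = p < 0.05, row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Diversity indices for one sample's taxon abundances
#'
#' Richness S (taxa with positive abundance), Shannon H, Simpson's index
#' in Gini form \eqn{1 - \sum p_i^2} (inverse Simpson available via
#' `simpson = "inverse"`), and Pielou evenness \eqn{J = H / \ln S}.
#' J is `NaN`-flagged when S <= 1.
#'
#' @param abundances nonnegative numeric vector of per-taxon abundances;
#'   at least one must be positive.
#' @param sample_id,rank bookkeeping columns carried into the result.
#' @param simpson `"gini"` (default) or `"inverse"`.
#' @return one-row data.frame with `sample_id`, `rank`, `S`, `H`, `D`,
#'   `J`.
#' @export
diversity_report <- function(abundances, sample_id = NA_character_,
                             rank = NA_character_,
                             simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  if (any(abundances < 0)) stop("negative abundance", call. = FALSE)
  if (sum(abundances) == 0)
    stop("all-zero abundance vector", call. = FALSE)
  S <- sum(abundances > 0)
  H <- as.numeric(vegan::diversity(abundances, index = "shannon"))
  D <- as.numeric(vegan::diversity(
    abundances, index = if (simpson == "gini") "simpson" else "invsimpson"))
  J <- if (S > 1L) H / log(S) else NaN
  data.frame(sample_id = sample_id, rank = rank, S = S, H = H, D = D,
             J = J, stringsAsFactors = FALSE)
}

#' Compare diversity indices between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test for each index over per-sample
#' diversity reports.
#'
#' @param reports data.frame of rows from [diversity_report()].
#' @param groups named character vector mapping sample ids to group
#'   labels (exactly two distinct labels).
#' @return data.frame with `index` and `p_value`.
#' @export
compare_diversity <- function(reports, groups) {
  g <- groups[reports$sample_id]
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2L)
    stop("exactly two groups required", call. = FALSE)
  if (sum(g == lev[1L], na.rm = TRUE) < 2L ||
      sum(g == lev[2L], na.rm = TRUE) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  idx <- c("S", "H", "D", "J")
  p <- vapply(idx, function(m) {
    x <- reports[[m]][g == lev[1L]]
    y <- reports[[m]][g == lev[2L]]
    x <- x[!is.nan(x)]; y <- y[!is.nan(y)]
    suppressWarnings(wilcox.test(x, y)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  data.frame(index = idx, p_value = unname(p), stringsAsFactors = FALSE)
}
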