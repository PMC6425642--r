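#' Count annotated genes on a contig
#'
#' Number of distinct genes on one contig with at least one hit to the
#' given database at `evalue <= evalue_max`. A gene with several
#' qualifying hits counts once.
#'
#' @param genes gene calls for the contig (data.frame with `gene_id`).
#' @param hits annotation hits (data.frame with `gene_id`, `database`,
#'   `evalue`); hits whose gene is absent from the gene table raise an
#'   error.
#' @param database_tag database to count, one of
#'   `r paste(ANNOTATION_DATABASES, collapse = ", ")`.
#' @param evalue_max inclusive e-value cutoff, default `1e-5`.
#' @return integer count.
#' @export
count_annotated_genes <- function(genes, hits, database_tag,
                                  evalue_max = 1e-5) {
  if (!database_tag %in% ANNOTATION_DATABASES)
    stop("unknown annotation database tag: ", database_tag, call. = FALSE)
  h <- hits[hits$database == database_tag & hits$evalue <= evalue_max, ,
            drop = FALSE]
  unknown <- setdiff(h$gene_id, genes$gene_id)
  if (length(unknown))
    stop("annotation hit refers to unknown gene: ", unknown[1L],
         call. = FALSE)
  length(intersect(unique(h$gene_id), genes$gene_id))
}

#' Extract per-contig predictor vectors
#'
#' Builds the 10 predictors used by the phage-contig classifier for every
#' contig longer than `min_length` bp:
#' \enumerate{
#'   \item average depth (mapped reads / contig length);
#'   \item number of predicted genes;
#'   \item number of genes with phage-orthologous-group (uPOG) hits;
#'   \item number of genes with viral-protein-family hits;
#'   \item fraction of genes with viral-protein-family hits;
#'   \item number of genes with KO hits;
#'   \item fraction of genes with KO hits;
#'   \item number of genes with Pfam hits;
#'   \item fraction of genes with Pfam hits;
#'   \item number of genes with viral-hallmark hits.
#' }
#' Fractions are stored in \[0, 1\] and are 0 for contigs with no genes
#' (such contigs are retained: depth is still informative). Annotation
#' hits are filtered at `evalue <= 1e-5`.
#'
#' @param contigs data.frame with `id`, `sample_id`, `length`.
#' @param genes gene calls (data.frame from [read_gene_table()]).
#' @param hits annotation hits for all databases, row-bound.
#' @param mapping mapping summaries (see [read_mapping_summary()]); one
#'   row per contig is required.
#' @param min_length contigs with `length <= min_length` are skipped;
#'   default 5000 (the "> 5 kb" rule). Lower cutoffs (1 kb, 3 kb) change
#'   which contigs appear but never a feature value.
#' @param evalue_max inclusive annotation e-value cutoff.
#' @return data.frame with `contig_id`, `sample_id` and feature columns
#'   `f1_avg_depth` .. `f10_n_hallmark`.
#' @export
extract_features <- function(contigs, genes, hits, mapping,
                             min_length = 5000L, evalue_max = 1e-5) {
  keep <- contigs$length > min_length
  ctg <- contigs[keep, , drop = FALSE]
  if (nrow(ctg) == 0L)
    return(.empty_feature_df())
  mi <- match(ctg$id, mapping$contig_id)
  if (anyNA(mi))
    stop("missing mapping summary for contig: ", ctg$id[is.na(mi)][1L],
         call. = FALSE)
  unknown <- setdiff(hits$gene_id, genes$gene_id)
  if (length(unknown))
    stop("annotation hit refers to unknown gene: ", unknown[1L],
         call. = FALSE)

  # qualifying hits once, then distinct annotated genes per (db, contig)
  h <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  h$contig_id <- genes$contig_id[match(h$gene_id, genes$gene_id)]
  n_genes <- table(factor(genes$contig_id, levels = ctg$id))
  db_count <- function(db) {
    sub <- h[h$database == db, c("gene_id", "contig_id")]
    sub <- unique(sub)
    as.integer(table(factor(sub$contig_id, levels = ctg$id)))
  }
  f2 <- as.integer(n_genes)
  f3 <- db_count("uPOG"); f4 <- db_count("viral_family")
  f6 <- db_count("KO"); f8 <- db_count("Pfam"); f10 <- db_count("hallmark")
  frac <- function(x) ifelse(f2 > 0L, x / f2, 0)
  data.frame(contig_id = ctg$id, sample_id = ctg$sample_id,
             f1_avg_depth = mapping$depth[mi],
             f2_n_genes = f2, f3_n_upog = f3,
             f4_n_viral_family = f4, f5_pct_viral_family = frac(f4),
             f6_n_ko = f6, f7_pct_ko = frac(f6),
             f8_n_pfam = f8, f9_pct_pfam = frac(f8),
             f10_n_hallmark = f10, stringsAsFactors = FALSE)
}

.feature_columns <- function() {
  c("f1_avg_depth", "f2_n_genes", "f3_n_upog", "f4_n_viral_family",
    "f5_pct_viral_family", "f6_n_ko", "f7_pct_ko", "f8_n_pfam",
    "f9_pct_pfam", "f10_n_hallmark")
}

.empty_feature_df <- function() {
  out <- data.frame(contig_id = character(), sample_id = character(),
                    stringsAsFactors = FALSE)
  for (cn in .feature_columns()) out[[cn]] <- numeric()
  out
}
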