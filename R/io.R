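#' phageminer: mining phage signals from metagenomic assemblies
#'
#' Tools for identifying bacteriophage contigs in mixed metagenomic
#' assemblies and analysing the recovered phage community: ground-truth
#' labelling against paired phageome assemblies, annotation-based feature
#' extraction, a random-forest phage classifier with abundance-weighted
#' evaluation, virus-quotient statistics for phage orthologous groups,
#' CRISPR-spacer host prediction, naive-Bayes 8-mer taxonomy with
#' bootstrap confidence, TPM quantification with two-group comparison,
#' and a seeded study simulator.
#'
#' All tabular readers use 1-based inclusive coordinates and skip blank
#' lines and lines starting with `#`.
#'
#' @importFrom stats aggregate cor median p.adjust quantile predict
#'   rlnorm rnorm runif rpois rgamma sd setNames wilcox.test rmultinom
#' @importFrom utils read.table write.table head
#' @keywords internal
"_PACKAGE"

ANNOTATION_DATABASES <- c("KO", "Pfam", "uPOG", "viral_family", "hallmark")

# Read a whitespace table, skipping '#' comments and blank lines.
# Returns character matrix rows so callers control type conversion and can
# report the original line number in errors.
.read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.split_fields <- function(line) strsplit(line, "\t| +")[[1]]

#' Read contigs from a FASTA file
#'
#' Sequences are upper-cased; `N` is allowed. Record ids are taken as the
#' first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @param sample_id optional sample identifier stored with every contig.
#' @return a data.frame with columns `id`, `sample_id`, `length` (bp) and
#'   `sequence`.
#' @export
read_fasta <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate contig id in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record ", ids[bad][1L], call. = FALSE)
  data.frame(id = ids, sample_id = sample_id, length = nchar(seqs),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write contigs to a FASTA file
#'
#' @param contigs data.frame with `id` and `sequence` columns.
#' @param path output path.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(contigs$sequence)
  names(set) <- contigs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a 12-column tabular alignment file
#'
#' Parses the standard 12-column tabular alignment layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). Query coordinates are
#' normalised so `q_start <= q_end`; subject strand is inferred from subject
#' coordinate order and subject coordinates are stored forward.
#'
#' @param path path to the table.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `identity_pct`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`, `s_strand`.
#' @export
read_alignment_table <- function(path) {
  tab <- .read_table_lines(path)
  n <- length(tab$lines)
  if (n == 0L)
    return(.empty_alignment_df())
  fields <- strsplit(tab$lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop("alignment table ", path, " line ", tab$lineno[i], ": expected 12 ",
         "columns, found ", nf[i], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  df <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    identity_pct = as.numeric(m[, 3L]), aln_length = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gap_opens = as.integer(m[, 6L]),
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    s_start = as.integer(m[, 9L]), s_end = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bit_score = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  if (anyNA(df$identity_pct) || anyNA(df$evalue) || anyNA(df$q_start))
    stop("alignment table ", path, ": non-numeric value in numeric column",
         call. = FALSE)
  if (any(df$evalue < 0))
    stop("alignment table ", path, ": negative e-value", call. = FALSE)
  if (any(df$identity_pct < 0 | df$identity_pct > 100))
    stop("alignment table ", path, ": identity outside [0,100]", call. = FALSE)
  # normalise query forward; subject order carries the strand
  qrev <- df$q_start > df$q_end
  tmpq <- df$q_start[qrev]; df$q_start[qrev] <- df$q_end[qrev]
  df$q_end[qrev] <- tmpq
  srev <- xor(df$s_start > df$s_end, qrev)
  df$s_strand <- ifelse(srev, "-", "+")
  sswap <- df$s_start > df$s_end
  tmps <- df$s_start[sswap]; df$s_start[sswap] <- df$s_end[sswap]
  df$s_end[sswap] <- tmps
  df
}

.empty_alignment_df <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), aln_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bit_score = numeric(),
             s_strand = character(), stringsAsFactors = FALSE)
}

#' Write a 12-column tabular alignment file
#'
#' Inverse of [read_alignment_table()]; minus-strand records are written
#' with subject coordinates reversed, so a write/read round trip preserves
#' the parsed records.
#'
#' @param aln data.frame as returned by [read_alignment_table()].
#' @param path output path.
#' @export
write_alignment_table <- function(aln, path) {
  s1 <- ifelse(aln$s_strand == "-", aln$s_end, aln$s_start)
  s2 <- ifelse(aln$s_strand == "-", aln$s_start, aln$s_end)
  out <- data.frame(aln$query_id, aln$subject_id, aln$identity_pct,
                    aln$aln_length, aln$mismatches, aln$gap_opens,
                    aln$q_start, aln$q_end, s1, s2, aln$evalue,
                    aln$bit_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Five tab-separated columns: gene id, contig id, start, end, strand.
#' Coordinates are 1-based inclusive; rows with `start > end`, `start < 1`
#' or a duplicated gene id are rejected.
#'
#' @param path path to the gene table.
#' @return data.frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_table <- function(path) {
  tab <- .read_table_lines(path)
  if (length(tab$lines) == 0L)
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  fields <- strsplit(tab$lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    i <- which(nf != 5L)[1L]
    stop("gene table ", path, " line ", tab$lineno[i],
         ": expected 5 columns, found ", nf[i], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  df <- data.frame(gene_id = m[, 1L], contig_id = m[, 2L],
                   start = as.integer(m[, 3L]), end = as.integer(m[, 4L]),
                   strand = m[, 5L], stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    stop("gene table ", path, ": non-integer coordinate", call. = FALSE)
  bad <- df$start < 1L | df$start > df$end
  if (any(bad))
    stop("gene table ", path, " line ", tab$lineno[bad][1L],
         ": invalid coordinates (1-based, start <= end required)",
         call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("gene table ", path, ": strand must be + or -", call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("gene table ", path, ": duplicate gene_id ",
         df$gene_id[duplicated(df$gene_id)][1L], call. = FALSE)
  df
}

#' @rdname read_gene_table
#' @param genes data.frame of gene calls.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "contig_id", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read annotation hits for one database
#'
#' Reads a tabular alignment file of gene-vs-database hits and tags every
#' record with `database_tag`. No e-value filtering happens here; the
#' feature extractor applies its own cutoff.
#'
#' @param path path to the hit table (12-column tabular alignment layout;
#'   query is the gene id, subject the database entry).
#' @param database_tag one of `"KO"`, `"Pfam"`, `"uPOG"`, `"viral_family"`,
#'   `"hallmark"`.
#' @return data.frame with columns `gene_id`, `database`, `subject_id`,
#'   `evalue`, `bit_score`, `identity_pct`, `aln_length`.
#' @export
read_annotation_hits <- function(path, database_tag) {
  if (!is.character(database_tag) || length(database_tag) != 1L ||
      !database_tag %in% ANNOTATION_DATABASES)
    stop("unknown annotation database tag: ", database_tag,
         " (expected one of ", paste(ANNOTATION_DATABASES, collapse = ", "),
         ")", call. = FALSE)
  aln <- read_alignment_table(path)
  data.frame(gene_id = aln$query_id, database = database_tag,
             subject_id = aln$subject_id, evalue = aln$evalue,
             bit_score = aln$bit_score, identity_pct = aln$identity_pct,
             aln_length = aln$aln_length, stringsAsFactors = FALSE)
}

#' Read a per-contig read-mapping summary
#'
#' Three tab-separated columns: contig id, sample id, mapped read count.
#' Relative abundance (mapped reads / total reads in the sample) and depth
#' (mapped reads / contig length) are computed on read. Identity filtering
#' of the read alignments is a property of the upstream counting step;
#' counts are taken as given.
#'
#' @param path path to the mapping summary table.
#' @param totals named numeric vector of total read counts per sample id.
#' @param contigs data.frame with `id` and `length` columns; every contig
#'   id in the table must appear here.
#' @return data.frame with columns `contig_id`, `sample_id`,
#'   `mapped_reads`, `total_reads_in_sample`, `relative_abundance`,
#'   `depth`.
#' @export
read_mapping_summary <- function(path, totals, contigs) {
  tab <- .read_table_lines(path)
  if (length(tab$lines) == 0L) stop("empty mapping summary: ", path,
                                    call. = FALSE)
  fields <- strsplit(tab$lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    i <- which(nf != 3L)[1L]
    stop("mapping summary ", path, " line ", tab$lineno[i],
         ": expected 3 columns, found ", nf[i], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  df <- data.frame(contig_id = m[, 1L], sample_id = m[, 2L],
                   mapped_reads = as.numeric(m[, 3L]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$mapped_reads) || any(df$mapped_reads < 0))
    stop("mapping summary ", path, ": mapped_reads must be >= 0",
         call. = FALSE)
  compute_mapping_summary(df, totals, contigs)
}

#' Compute relative abundance and depth for mapped-read counts
#'
#' @param counts data.frame with `contig_id`, `sample_id`, `mapped_reads`.
#' @inheritParams read_mapping_summary
#' @return see [read_mapping_summary()].
#' @export
compute_mapping_summary <- function(counts, totals, contigs) {
  unknown <- setdiff(counts$contig_id, contigs$id)
  if (length(unknown))
    stop("mapping summary refers to unknown contig id: ", unknown[1L],
         call. = FALSE)
  missing_tot <- setdiff(counts$sample_id, names(totals))
  if (length(missing_tot))
    stop("no total read count for sample: ", missing_tot[1L], call. = FALSE)
  tot <- as.numeric(totals[counts$sample_id])
  if (any(tot <= 0))
    stop("total_reads_in_sample must be > 0", call. = FALSE)
  len <- contigs$length[match(counts$contig_id, contigs$id)]
  data.frame(contig_id = counts$contig_id, sample_id = counts$sample_id,
             mapped_reads = counts$mapped_reads,
             total_reads_in_sample = tot,
             relative_abundance = counts$mapped_reads / tot,
             depth = counts$mapped_reads / len,
             stringsAsFactors = FALSE)
}

#' @rdname read_mapping_summary
#' @param mapping data.frame of mapping summaries.
#' @export
write_mapping_summary <- function(mapping, path) {
  write.table(mapping[, c("contig_id", "sample_id", "mapped_reads")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
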