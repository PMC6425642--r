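#' Filter metagenome-vs-phageome alignments
#'
#' Retains alignments passing the megablast screening thresholds used when
#' pairing metagenomic contigs with phageome contigs: e-value strictly
#' below `evalue_max` and percent identity strictly above `identity_min`.
#'
#' @param aln alignment data.frame from [read_alignment_table()].
#' @param evalue_max e-value upper bound, exclusive (default `1e-5`).
#' @param identity_min percent-identity lower bound, exclusive
#'   (default `98`).
#' @return the subset of `aln` passing both filters.
#' @export
filter_phageome_alignments <- function(aln, evalue_max = 1e-5,
                                       identity_min = 98) {
  aln[aln$evalue < evalue_max & aln$identity_pct > identity_min, ,
      drop = FALSE]
}

# Total length of the union of 1-based inclusive intervals.
.interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L; cur_s <- starts[1L]; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e + 1L) {
      if (ends[i] > cur_e) cur_e <- ends[i]
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Merge alignment evidence for one metagenome/phageome contig pair
#'
#' Collapses all local alignments (HSPs) between one metagenomic contig
#' and one phageome contig into a single evidence record. The aligned
#' length is the length of the union of query-side intervals, so
#' overlapping HSPs are not double-counted; coverage is that length
#' divided by the length of the shorter of the two contigs.
#'
#' @param aln alignment records sharing one (query, subject) pair.
#' @param meta_length length of the metagenomic (query) contig in bp.
#' @param phage_length length of the phageome (subject) contig in bp.
#' @return one-row data.frame with `meta_contig_id`, `phage_contig_id`,
#'   `merged_aligned_length` and `coverage`.
#' @export
merge_pair_evidence <- function(aln, meta_length, phage_length) {
  if (is.na(meta_length) || is.na(phage_length))
    stop("contig length missing for evidence pair", call. = FALSE)
  if (nrow(aln) == 0L)
    return(data.frame(meta_contig_id = NA_character_,
                      phage_contig_id = NA_character_,
                      merged_aligned_length = 0L, coverage = 0,
                      stringsAsFactors = FALSE))
  if (length(unique(aln$query_id)) > 1L ||
      length(unique(aln$subject_id)) > 1L)
    stop("merge_pair_evidence expects records for a single contig pair",
         call. = FALSE)
  merged <- .interval_union_length(aln$q_start, aln$q_end)
  shorter <- min(meta_length, phage_length)
  merged <- min(merged, shorter)  # clamp: union cannot exceed the shorter contig
  data.frame(meta_contig_id = aln$query_id[1L],
             phage_contig_id = aln$subject_id[1L],
             merged_aligned_length = merged,
             coverage = merged / shorter, stringsAsFactors = FALSE)
}

#' Label metagenomic contigs from paired-phageome evidence
#'
#' Assigns each metagenomic contig one of three categories from its
#' merged alignment evidence against the same sample's phageome contigs:
#' \describe{
#'   \item{phage}{some phageome contig pair has coverage > 0.80 of the
#'     shorter contig, or merged aligned length > 10 kb;}
#'   \item{ambiguous}{otherwise, some pair has coverage in \[0.40, 0.80\]
#'     or merged aligned length in \[4 kb, 10 kb\];}
#'   \item{non_phage}{no pair qualifies.}
#' }
#' A single pair may satisfy a criterion; evidence is never summed across
#' different phageome contigs. Coverage exactly 0.80 (or length exactly
#' 10 kb) falls in the ambiguous band, mirroring the strict "> 80%" /
#' "40--80%" reading of the rules.
#'
#' @param evidence data.frame of merged pair evidence
#'   (see [merge_pair_evidence()]) for any number of metagenomic contigs.
#' @param contig_ids character vector of all metagenomic contig ids to
#'   label; contigs without evidence become `non_phage`.
#' @param cov_phage,len_phage phage thresholds (exclusive): coverage 0.80,
#'   aligned length 10000 bp.
#' @param cov_ambig,len_ambig lower bounds (inclusive) of the ambiguous
#'   band: coverage 0.40, aligned length 4000 bp.
#' @return data.frame with `contig_id`, `label`, `best_coverage`,
#'   `best_aligned_length`, `best_phage_contig`.
#' @export
assign_labels <- function(evidence, contig_ids,
                          cov_phage = 0.80, len_phage = 10000L,
                          cov_ambig = 0.40, len_ambig = 4000L) {
  stopifnot(is.character(contig_ids))
  out <- data.frame(contig_id = contig_ids, label = "non_phage",
                    best_coverage = 0, best_aligned_length = 0L,
                    best_phage_contig = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.null(evidence) || !nrow(evidence)) return(out)
  ev <- evidence[!is.na(evidence$meta_contig_id) &
                   evidence$meta_contig_id %in% contig_ids, , drop = FALSE]
  if (!nrow(ev)) return(out)
  cov <- ev$coverage; len <- ev$merged_aligned_length
  # per-pair verdict; a contig's label is the best verdict of any pair
  pair_rank <- ifelse(cov > cov_phage | len > len_phage, 2L,
               ifelse((cov >= cov_ambig & cov <= cov_phage) |
                      (len >= len_ambig & len <= len_phage), 1L, 0L))
  for (i in order(pair_rank, cov, len)) {  # ascending: last write wins
    j <- match(ev$meta_contig_id[i], out$contig_id)
    out$label[j] <- c("non_phage", "ambiguous", "phage")[pair_rank[i] + 1L]
  }
  # best evidence = pair maximising (coverage, then aligned length)
  for (i in order(cov, len)) {
    j <- match(ev$meta_contig_id[i], out$contig_id)
    out$best_coverage[j] <- cov[i]
    out$best_aligned_length[j] <- len[i]
    out$best_phage_contig[j] <- ev$phage_contig_id[i]
  }
  out
}

#' Full labelling pipeline from raw alignments
#'
#' Convenience wrapper: filters raw metagenome-vs-phageome alignments,
#' merges HSPs per contig pair, and assigns the three-category labels.
#'
#' @param aln raw alignment data.frame (query = metagenomic contig,
#'   subject = phageome contig).
#' @param meta_contigs,phage_contigs data.frames with `id` and `length`.
#' @param ... passed to [filter_phageome_alignments()] and
#'   [assign_labels()].
#' @return see [assign_labels()].
#' @export
label_contigs <- function(aln, meta_contigs, phage_contigs, ...) {
  dots <- list(...)
  filt_args <- dots[names(dots) %in% c("evalue_max", "identity_min")]
  lab_args <- dots[names(dots) %in%
                     c("cov_phage", "len_phage", "cov_ambig", "len_ambig")]
  aln <- do.call(filter_phageome_alignments, c(list(aln), filt_args))
  ev <- merge_all_pairs(aln, meta_contigs, phage_contigs)
  do.call(assign_labels, c(list(ev, meta_contigs$id), lab_args))
}

#' Merge evidence for every (metagenome, phageome) contig pair present
#'
#' @inheritParams label_contigs
#' @return data.frame of merged pair evidence, one row per pair.
#' @export
merge_all_pairs <- function(aln, meta_contigs, phage_contigs) {
  if (nrow(aln) == 0L)
    return(data.frame(meta_contig_id = character(),
                      phage_contig_id = character(),
                      merged_aligned_length = integer(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  key <- paste(aln$query_id, aln$subject_id, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(aln)), key), function(idx) {
    sub <- aln[idx, , drop = FALSE]
    ml <- meta_contigs$length[match(sub$query_id[1L], meta_contigs$id)]
    pl <- phage_contigs$length[match(sub$subject_id[1L], phage_contigs$id)]
    merge_pair_evidence(sub, ml, pl)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
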