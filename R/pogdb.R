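#' Filter POG-vs-genome matches
#'
#' Retains protein matches passing the profile-search thresholds used for
#' virus-quotient computation: `evalue <= 0.001`, `bit_score > 40` and an
#' aligned (homologous) region of at least 40 amino acids.
#'
#' @param matches data.frame with columns `pog_id`, `genome_id`,
#'   `genome_type` (`"viral"`/`"prokaryotic"`), `evalue`, `bit_score`,
#'   `aln_length` (aa); extra columns pass through.
#' @param evalue_max inclusive e-value bound (default 0.001).
#' @param bit_min exclusive bit-score bound (default 40).
#' @param aln_min inclusive aligned-length bound in aa (default 40).
#' @return the qualifying subset.
#' @export
filter_pog_matches <- function(matches, evalue_max = 0.001, bit_min = 40,
                               aln_min = 40) {
  matches[matches$evalue <= evalue_max & matches$bit_score > bit_min &
            matches$aln_length >= aln_min, , drop = FALSE]
}

#' Virus quotient of a phage orthologous group
#'
#' VQ = (number of distinct viral genomes matched) /
#' (viral + prokaryotic genomes matched), with prokaryotic genomes on the
#' exclusion list (e.g. genomes carrying detected prophage regions)
#' removed before counting. Genomes are counted once regardless of hit
#' multiplicity. A group is virus-specific when VQ > 0.85 (strict).
#'
#' @param viral_genomes character vector (or set) of viral genome ids
#'   matched by the group.
#' @param prokaryotic_genomes character vector of prokaryotic genome ids
#'   matched.
#' @param excluded_genomes prokaryotic genome ids excluded from the
#'   calculation.
#' @return numeric VQ in \[0, 1\].
#' @export
compute_vq <- function(viral_genomes, prokaryotic_genomes,
                       excluded_genomes = character()) {
  v <- unique(viral_genomes)
  p <- setdiff(unique(prokaryotic_genomes), excluded_genomes)
  if (length(v) + length(p) == 0L)
    stop("VQ undefined: no qualifying genome matches", call. = FALSE)
  length(v) / (length(v) + length(p))
}

#' @rdname compute_vq
#' @param vq a virus quotient.
#' @param threshold strict virus-specific threshold (default 0.85).
#' @export
is_virus_specific <- function(vq, threshold = 0.85) vq > threshold

#' Summarise POG records from a qualifying match table
#'
#' Per group: distinct viral and (post-exclusion) prokaryotic genome
#' matches, VQ and the virus-specific verdict.
#'
#' @inheritParams filter_pog_matches
#' @param excluded_genomes prokaryotic genomes excluded from VQ.
#' @return data.frame with one row per `pog_id`: `n_viral`,
#'   `n_prokaryotic`, `vq`, `virus_specific`.
#' @export
pog_records <- function(matches, excluded_genomes = character()) {
  split_idx <- split(seq_len(nrow(matches)), matches$pog_id)
  rows <- lapply(names(split_idx), function(pid) {
    sub <- matches[split_idx[[pid]], , drop = FALSE]
    v <- unique(sub$genome_id[sub$genome_type == "viral"])
    p <- setdiff(unique(sub$genome_id[sub$genome_type == "prokaryotic"]),
                 excluded_genomes)
    vq <- if (length(v) + length(p) == 0L) NaN
          else length(v) / (length(v) + length(p))
    data.frame(pog_id = pid, n_viral = length(v),
               n_prokaryotic = length(p), vq = vq,
               virus_specific = !is.nan(vq) && is_virus_specific(vq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Taxon-signature verdict for a phage orthologous group
#'
#' A group is a signature marker for a taxon when it occurs in every
#' genome it matches only within that taxon (precision exactly 1), in
#' more than 85% of the taxon's genomes (recall, strict), with VQ > 0.85
#' (strict), and in a single copy per containing genome. Precision is a
#' set-membership test, not a float comparison.
#'
#' @param copies_per_genome named integer vector: copy number of the
#'   group in each genome that contains it (names are genome ids).
#' @param genome_taxa named character vector mapping every genome id to
#'   its taxon.
#' @param taxon the candidate taxon.
#' @param vq the group's virus quotient.
#' @param recall_min,vq_min strict thresholds, both 0.85.
#' @return one-row data.frame with `taxon`, `precision`, `recall`,
#'   `single_copy`, `vq`, `is_signature`.
#' @export
taxon_signature <- function(copies_per_genome, genome_taxa, taxon, vq,
                            recall_min = 0.85, vq_min = 0.85) {
  containing <- names(copies_per_genome)[copies_per_genome > 0L]
  unknown <- setdiff(containing, names(genome_taxa))
  if (length(unknown))
    stop("genome without taxonomy assignment: ", unknown[1L],
         call. = FALSE)
  taxon_genomes <- names(genome_taxa)[genome_taxa == taxon]
  if (length(taxon_genomes) == 0L)
    stop("taxon has no genomes: ", taxon, call. = FALSE)
  in_taxon <- containing[genome_taxa[containing] == taxon]
  precision_exact <- length(containing) > 0L &&
    all(genome_taxa[containing] == taxon)
  precision <- if (length(containing)) length(in_taxon) / length(containing)
               else NaN
  recall <- length(in_taxon) / length(taxon_genomes)
  single_copy <- length(containing) > 0L &&
    all(copies_per_genome[containing] == 1L)
  data.frame(taxon = taxon, precision = precision, recall = recall,
             single_copy = single_copy, vq = vq,
             is_signature = precision_exact && recall > recall_min &&
               vq > vq_min && single_copy,
             stringsAsFactors = FALSE)
}
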