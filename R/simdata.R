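#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: a longitudinal cohort of subjects with
#' several samples each, a mixed community in which about 2% of contigs
#' are phage, lognormal read-count abundances, class-dependent
#' annotation-hit rates, and a paired phageome assembly that echoes a
#' configurable fraction of the true phage contigs.
#'
#' The `preset` controls how cleanly phage and bacterial contigs
#' separate: `"easy"` uses well-separated annotation rates and a perfect
#' phageome echo; `"medium"` and `"hard"` shrink the rate gaps, lower
#' the echo recovery and add coverage noise plus spurious partial
#' echoes of bacterial contigs (which creates ambiguous labels).
#'
#' @param n_subjects number of subjects (default 10).
#' @param n_samples_per_subject longitudinal samples per subject
#'   (default 6).
#' @param n_contigs_per_sample contigs per sample (default 150).
#' @param phage_fraction probability a contig is phage (default 0.02).
#' @param length_meanlog,length_sdlog lognormal contig-length parameters
#'   (bp).
#' @param min_contig_length,max_contig_length clamp bounds for lengths.
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of the
#'   per-contig abundance weights.
#' @param total_reads_per_sample reads distributed over a sample's
#'   contigs.
#' @param equal_abundance give every contig the same read count (useful
#'   to check that count- and abundance-weighted metrics coincide).
#' @param preset `"easy"`, `"medium"` or `"hard"`.
#' @param rng_seed master seed; the whole study is a deterministic
#'   function of the configuration.
#' @return a list of class `sim_config`, including derived fields
#'   `annotation_rates` (per class per database), `phageome_recovery`,
#'   `coverage_noise_sd` and `spurious_echo_rate`.
#' @export
sim_config <- function(n_subjects = 10L, n_samples_per_subject = 6L,
                       n_contigs_per_sample = 150L,
                       phage_fraction = 0.02,
                       length_meanlog = log(9000), length_sdlog = 0.25,
                       min_contig_length = 5200L,
                       max_contig_length = 60000L,
                       abundance_meanlog = 0, abundance_sdlog = 1.5,
                       total_reads_per_sample = 2e6,
                       equal_abundance = FALSE,
                       preset = c("easy", "medium", "hard"),
                       rng_seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(phage_fraction > 0, phage_fraction < 1, n_subjects >= 1L,
            n_samples_per_subject >= 1L, n_contigs_per_sample >= 1L)
  n_total <- n_subjects * n_samples_per_subject * n_contigs_per_sample
  if (phage_fraction * n_total < 1)
    stop("infeasible configuration: expected phage contig count below 1",
         call. = FALSE)
  # class-conditional annotation rates; presets shrink the phage rates
  # toward the bacterial ones
  bact <- c(uPOG = 0.05, viral_family = 0.02, hallmark = 0.005,
            KO = 0.70, Pfam = 0.75)
  phage_easy <- c(uPOG = 0.60, viral_family = 0.55, hallmark = 0.30,
                  KO = 0.10, Pfam = 0.20)
  w <- switch(preset, easy = 1, medium = 0.6, hard = 0.35)
  phage <- bact + w * (phage_easy - bact)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_samples_per_subject = as.integer(n_samples_per_subject),
    n_contigs_per_sample = as.integer(n_contigs_per_sample),
    phage_fraction = phage_fraction,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_contig_length = as.integer(min_contig_length),
    max_contig_length = as.integer(max_contig_length),
    abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog,
    total_reads_per_sample = total_reads_per_sample,
    equal_abundance = isTRUE(equal_abundance),
    preset = preset,
    annotation_rates = list(phage = phage, bacterial = bact),
    phageome_recovery = switch(preset, easy = 1.0, medium = 0.9,
                               hard = 0.75),
    coverage_noise_sd = switch(preset, easy = 0, medium = 0.08,
                               hard = 0.15),
    spurious_echo_rate = switch(preset, easy = 0, medium = 0.02,
                                hard = 0.04),
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

#' Generate a complete synthetic paired metagenome/phageome study
#'
#' Emits, deterministically under the configuration seed, every input
#' the pipeline consumes: metagenomic contigs (lengths; sequences are
#' added by [write_study()] when requested), gene calls, annotation hits
#' for all five databases (including a small fraction of hits above the
#' e-value cutoff, which the feature extractor must ignore), per-contig
#' mapped-read counts, phageome contigs with metagenome-vs-phageome
#' alignment records, and a truth table with the simulated class of
#' every contig.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_study` with elements `contigs`, `genes`,
#'   `hits`, `mapping`, `totals`, `phageome_contigs`, `phageome_aln`,
#'   `truth`, `config`.
#' @export
generate_study <- function(config = sim_config()) {
  .with_seed(config$rng_seed, .generate_study_impl(config))
}

.generate_study_impl <- function(config) {
  contigs <- genes <- hits <- counts <- pctg <- paln <- truth <- list()
  gene_no <- 0L
  for (i in seq_len(config$n_subjects)) {
    subject_id <- sprintf("subj%02d", i)
    for (j in seq_len(config$n_samples_per_subject)) {
      sample_id <- sprintf("S%02dT%d", i, j)
      n <- config$n_contigs_per_sample
      ids <- sprintf("%s_c%04d", sample_id, seq_len(n))
      is_phage <- runif(n) < config$phage_fraction
      len <- pmin(pmax(round(rlnorm(n, config$length_meanlog,
                                    config$length_sdlog)),
                       config$min_contig_length), config$max_contig_length)
      contigs[[sample_id]] <- data.frame(
        id = ids, sample_id = sample_id, length = len,
        stringsAsFactors = FALSE)
      truth[[sample_id]] <- data.frame(
        contig_id = ids, sample_id = sample_id, subject_id = subject_id,
        true_class = ifelse(is_phage, "phage", "bacterial"),
        stringsAsFactors = FALSE)

      # gene calls: roughly one gene per kb, tiled across the contig
      gtab <- lapply(seq_len(n), function(k) {
        ng <- max(1L, rpois(1L, len[k] / 1100))
        step <- len[k] %/% ng
        start <- (seq_len(ng) - 1L) * step + 1L
        end <- pmin(start + max(90L, step - 60L), len[k])
        gene_ids <- sprintf("%s_g%03d", ids[k], seq_len(ng))
        data.frame(gene_id = gene_ids, contig_id = ids[k],
                   start = start, end = end,
                   strand = sample(c("+", "-"), ng, replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      gtab <- do.call(rbind, gtab)
      genes[[sample_id]] <- gtab

      hits[[sample_id]] <- .simulate_hits(gtab, is_phage, config)

      # lognormal abundance weights -> multinomial read counts
      wts <- if (config$equal_abundance) rep(1, n)
             else rlnorm(n, config$abundance_meanlog,
                         config$abundance_sdlog)
      counts[[sample_id]] <- data.frame(
        contig_id = ids, sample_id = sample_id,
        mapped_reads = as.vector(
          rmultinom(1L, config$total_reads_per_sample, wts)),
        stringsAsFactors = FALSE)

      echo <- .simulate_phageome(ids, len, is_phage, sample_id, config)
      pctg[[sample_id]] <- echo$contigs
      paln[[sample_id]] <- echo$aln
    }
  }
  bind <- function(x) { out <- do.call(rbind, x); rownames(out) <- NULL; out }
  contigs <- bind(contigs)
  mapping <- compute_mapping_summary(
    bind(counts),
    setNames(rep(config$total_reads_per_sample,
                 length(unique(contigs$sample_id))),
             unique(contigs$sample_id)),
    contigs)
  structure(list(contigs = contigs, genes = bind(genes),
                 hits = bind(hits), mapping = mapping,
                 totals = setNames(rep(config$total_reads_per_sample,
                                       length(unique(contigs$sample_id))),
                                   unique(contigs$sample_id)),
                 phageome_contigs = bind(pctg), phageome_aln = bind(paln),
                 truth = bind(truth), config = config),
            class = "sim_study")
}

# annotation hits per gene per database at class-conditional rates;
# a few extra hits land above the 1e-5 cutoff and must be filtered out
.simulate_hits <- function(gtab, is_phage, config) {
  class_of <- ifelse(is_phage, "phage", "bacterial")
  names(class_of) <- unique(gtab$contig_id)
  out <- list()
  for (db in ANNOTATION_DATABASES) {
    rate <- vapply(config$annotation_rates[class_of[gtab$contig_id]],
                   `[[`, numeric(1), db)
    hit <- runif(nrow(gtab)) < rate
    junk <- runif(nrow(gtab)) < 0.03  # above-cutoff noise hits
    if (any(hit))
      out[[paste0(db, "_real")]] <- data.frame(
        gene_id = gtab$gene_id[hit], database = db,
        subject_id = sprintf("%s%05d", db, sample.int(99999L, sum(hit),
                                                      replace = TRUE)),
        evalue = 10^-runif(sum(hit), 6, 50),
        bit_score = runif(sum(hit), 60, 400),
        identity_pct = runif(sum(hit), 40, 99),
        aln_length = sample(60:300, sum(hit), replace = TRUE),
        stringsAsFactors = FALSE)
    if (any(junk))
      out[[paste0(db, "_junk")]] <- data.frame(
        gene_id = gtab$gene_id[junk], database = db,
        subject_id = sprintf("%s%05d", db, sample.int(99999L, sum(junk),
                                                      replace = TRUE)),
        evalue = 10^-runif(sum(junk), 1, 4.9),
        bit_score = runif(sum(junk), 25, 50),
        identity_pct = runif(sum(junk), 25, 50),
        aln_length = sample(30:80, sum(junk), replace = TRUE),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), database = character(),
                      subject_id = character(), evalue = numeric(),
                      bit_score = numeric(), identity_pct = numeric(),
                      aln_length = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# phageome echo: each true phage contig is recovered with probability
# phageome_recovery at coverage 1 minus half-normal noise; at the noisy
# presets some bacterial contigs get a partial (ambiguous-band) echo
.simulate_phageome <- function(ids, len, is_phage, sample_id, config) {
  ctg <- list(); aln <- list()
  rec <- which(is_phage & runif(length(ids)) < config$phageome_recovery)
  spur <- which(!is_phage & runif(length(ids)) < config$spurious_echo_rate)
  mk_aln <- function(qid, pid, alen) {
    data.frame(query_id = qid, subject_id = pid,
               identity_pct = round(runif(1, 98.5, 100), 2),
               aln_length = alen, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
               evalue = 0, bit_score = 2 * alen, s_strand = "+",
               stringsAsFactors = FALSE)
  }
  for (k in rec) {
    pid <- sub("_c", "_p", ids[k])
    cov <- if (config$coverage_noise_sd > 0)
      max(0.3, 1 - abs(rnorm(1, 0, config$coverage_noise_sd))) else 1
    alen <- max(1L, round(cov * len[k]))
    ctg[[pid]] <- data.frame(id = pid, sample_id = sample_id,
                             length = len[k], stringsAsFactors = FALSE)
    aln[[pid]] <- mk_aln(ids[k], pid, alen)
  }
  for (k in spur) {
    pid <- sub("_c", "_sp", ids[k])
    alen <- min(len[k] - 1L, round(runif(1, 4000, 9000)))
    ctg[[pid]] <- data.frame(id = pid, sample_id = sample_id,
                             length = len[k], stringsAsFactors = FALSE)
    aln[[pid]] <- mk_aln(ids[k], pid, alen)
  }
  empty_ctg <- data.frame(id = character(), sample_id = character(),
                          length = integer(), stringsAsFactors = FALSE)
  list(contigs = if (length(ctg)) do.call(rbind, ctg) else empty_ctg,
       aln = if (length(aln)) do.call(rbind, aln)
             else .empty_alignment_df())
}

#' Label the contigs of a simulated study
#'
#' Runs the three-category labelling pipeline on a study's
#' metagenome-vs-phageome alignment records.
#'
#' @param study a `sim_study` from [generate_study()].
#' @param ... passed to [label_contigs()].
#' @return see [assign_labels()].
#' @export
study_labels <- function(study, ...) {
  label_contigs(study$phageome_aln, study$contigs,
                study$phageome_contigs, ...)
}

#' Write a simulated study to disk
#'
#' Writes every table in the core file formats: `contigs.fa` and
#' `phageome_contigs.fa` (random sequences of the recorded lengths,
#' generated when `sequences = TRUE`), `genes.tsv`, one
#' `hits_<database>.tsv` per database (12-column tabular alignment
#' layout), `mapping.tsv`, `totals.tsv`, `meta_vs_phageome.tsv` and
#' `truth.tsv`.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @param sequences also write FASTA files with synthetic sequences.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, sequences = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (sequences) {
    ctg <- study$contigs
    ctg$sequence <- vapply(ctg$length, .random_dna, "")
    write_fasta(ctg, p("contigs.fa"))
    pc <- study$phageome_contigs
    if (nrow(pc)) {
      pc$sequence <- vapply(pc$length, .random_dna, "")
      write_fasta(pc, p("phageome_contigs.fa"))
    }
  }
  write_gene_table(study$genes, p("genes.tsv"))
  for (db in unique(study$hits$database)) {
    h <- study$hits[study$hits$database == db, , drop = FALSE]
    aln <- data.frame(query_id = h$gene_id, subject_id = h$subject_id,
                      identity_pct = h$identity_pct,
                      aln_length = h$aln_length, mismatches = 0L,
                      gap_opens = 0L, q_start = 1L, q_end = h$aln_length,
                      s_start = 1L, s_end = h$aln_length,
                      evalue = h$evalue, bit_score = h$bit_score,
                      s_strand = "+", stringsAsFactors = FALSE)
    write_alignment_table(aln, p(sprintf("hits_%s.tsv", db)))
  }
  write_mapping_summary(study$mapping, p("mapping.tsv"))
  write.table(data.frame(names(study$totals), as.numeric(study$totals)),
              p("totals.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_alignment_table(study$phageome_aln, p("meta_vs_phageome.tsv"))
  write.table(study$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant a CRISPR array targeting a phage contig
#'
#' Inserts a repeat-spacer array into a bacterial contig whose spacers
#' are exact substrings (protospacers) of the given phage contig. The
#' array is `n_spacers + 1` identical repeat copies separated by the
#' sampled spacers; at least 2 spacers (3 repeat copies) are needed for
#' the array to be detectable. Protospacer positions are resampled so
#' that the bases flanking each repeat copy differ between copies, which
#' guarantees the planted repeat boundaries are recoverable exactly.
#'
#' @param bacterial_seq,phage_seq DNA strings.
#' @param n_spacers number of spacers to plant (0 leaves the sequence
#'   unchanged).
#' @param repeat_length repeat length in bp (default 28).
#' @param spacer_length spacer length in bp (default 32).
#' @param insert_at insertion position in the bacterial contig (default:
#'   uniformly random in the interior).
#' @return list with `sequence` (modified bacterial contig), `truth`
#'   (data.frame: `spacer_seq`, `protospacer_start`, `spacer_start`),
#'   `repeat_seq`, `array_start`, `array_end`.
#' @export
plant_crispr <- function(bacterial_seq, phage_seq, n_spacers,
                         repeat_length = 28L, spacer_length = 32L,
                         insert_at = NULL) {
  if (n_spacers == 0L)
    return(list(sequence = bacterial_seq,
                truth = data.frame(spacer_seq = character(),
                                   protospacer_start = integer(),
                                   spacer_start = integer(),
                                   stringsAsFactors = FALSE),
                repeat_seq = NA_character_, array_start = NA_integer_,
                array_end = NA_integer_))
  nb <- nchar(bacterial_seq); np <- nchar(phage_seq)
  if (np < spacer_length * (n_spacers + 2L))
    stop("phage contig too short to sample protospacers", call. = FALSE)
  if (nb < 200L)
    stop("bacterial contig too short to host an array", call. = FALSE)
  rep_seq <- .random_dna(repeat_length)
  spacers <- character(n_spacers); ps_start <- integer(n_spacers)
  for (try in seq_len(100L)) {
    ps_start <- sort(sample(seq_len(np - spacer_length + 1L), n_spacers))
    if (n_spacers > 1L && any(diff(ps_start) < spacer_length)) next
    spacers <- substring(phage_seq, ps_start,
                         ps_start + spacer_length - 1L)
    first <- substring(spacers, 1L, 1L)
    last <- substring(spacers, spacer_length, spacer_length)
    # flanking columns must not be unanimous, so repeat extension stops
    # exactly at the planted boundary
    if (length(unique(first)) > 1L && length(unique(last)) > 1L) break
  }
  array_seq <- paste0(rep_seq,
                      paste0(spacers, rep_seq, collapse = ""))
  if (is.null(insert_at))
    insert_at <- sample(seq(100L, nb - 100L), 1L)
  out_seq <- paste0(substr(bacterial_seq, 1L, insert_at), array_seq,
                    substr(bacterial_seq, insert_at + 1L, nb))
  spacer_start <- insert_at + repeat_length +
    (seq_len(n_spacers) - 1L) * (repeat_length + spacer_length) + 1L
  list(sequence = out_seq,
       truth = data.frame(spacer_seq = spacers,
                          protospacer_start = ps_start,
                          spacer_start = spacer_start,
                          stringsAsFactors = FALSE),
       repeat_seq = rep_seq, array_start = insert_at + 1L,
       array_end = insert_at + nchar(array_seq))
}

#' Generate genus-structured synthetic phage genomes
#'
#' Each genus receives its own random Markov transition matrix of the
#' given order (rows drawn from a flat Dirichlet), and genomes are
#' sampled from it, giving genera distinct 8-mer compositions that a
#' k-mer classifier can learn. With `markov_order = 0` and
#' `shared_composition = TRUE` all genera share one uniform base
#' distribution — a negative control with no learnable signal.
#'
#' @param n_genera number of genera (>= 2 for discrimination tests).
#' @param n_genomes_per_genus genomes per genus.
#' @param genome_length genome length in bp.
#' @param markov_order order of the Markov composition model (default 3).
#' @param shared_composition give all genera identical composition
#'   (order 0 only).
#' @return list with `genomes` (data.frame `id`, `sequence`) and
#'   `taxonomy` (data.frame `genome_id`, `genus`).
#' @export
generate_genus_genomes <- function(n_genera = 2L, n_genomes_per_genus = 5L,
                                   genome_length = 30000L,
                                   markov_order = 3L,
                                   shared_composition = FALSE) {
  stopifnot(n_genera >= 1L, n_genomes_per_genus >= 1L)
  n_states <- 4L^markov_order
  shared <- matrix(0.25, n_states, 4L)
  genomes <- list(); taxonomy <- list()
  for (g in seq_len(n_genera)) {
    genus <- sprintf("genus_%s", LETTERS[g])
    trans <- if (shared_composition) shared else {
      m <- matrix(rgamma(n_states * 4L, shape = 1), n_states, 4L)
      m / rowSums(m)
    }
    cum <- t(apply(trans, 1L, cumsum))
    for (k in seq_len(n_genomes_per_genus)) {
      id <- sprintf("%s_genome%02d", genus, k)
      genomes[[id]] <- data.frame(
        id = id, sequence = .sample_markov(genome_length, cum,
                                           markov_order),
        stringsAsFactors = FALSE)
      taxonomy[[id]] <- data.frame(genome_id = id, genus = genus,
                                   stringsAsFactors = FALSE)
    }
  }
  list(genomes = do.call(rbind, c(genomes, make.row.names = FALSE)),
       taxonomy = do.call(rbind, c(taxonomy, make.row.names = FALSE)))
}

# sample a sequence from an order-k Markov chain given cumulative
# transition rows (4^k x 4); state index encodes the last k bases
.sample_markov <- function(len, cum, order) {
  bases <- c("A", "C", "G", "T")
  out <- integer(len)
  u <- runif(len)
  if (order == 0L) {
    for (i in seq_len(len))
      out[i] <- findInterval(u[i], cum[1L, ], left.open = TRUE) + 1L
  } else {
    # seed the first `order` bases uniformly
    out[seq_len(order)] <- sample.int(4L, order, replace = TRUE)
    state <- 0L
    for (i in seq_len(order)) state <- state * 4L + (out[i] - 1L)
    mod <- 4L^(order - 1L)
    for (i in (order + 1L):len) {
      b <- findInterval(u[i], cum[state + 1L, ], left.open = TRUE) + 1L
      out[i] <- b
      state <- (state %% mod) * 4L + (b - 1L)
    }
  }
  paste(bases[out], collapse = "")
}
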