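small_cfg <- function(rng_seed = 5L, ...) {
  sim_config(n_subjects = 2L, n_samples_per_subject = 2L,
             n_contigs_per_sample = 60L, rng_seed = rng_seed, ...)
}

test_that("study generation is deterministic under its seed", {
  s1 <- generate_study(small_cfg())
  s2 <- generate_study(small_cfg())
  expect_identical(s1[setdiff(names(s1), "config")],
                   s2[setdiff(names(s2), "config")])
  s3 <- generate_study(small_cfg(rng_seed = 6L))
  expect_false(identical(s1$truth$true_class, s3$truth$true_class))
})

test_that("the phage fraction behaves binomially", {
  cfg <- sim_config(n_subjects = 5L, n_samples_per_subject = 4L,
                    n_contigs_per_sample = 250L, rng_seed = 42L)
  study <- generate_study(cfg)
  n <- nrow(study$truth)
  k <- sum(study$truth$true_class == "phage")
  expected <- n * cfg$phage_fraction
  expect_lt(abs(k - expected), 4 * sqrt(expected * (1 - cfg$phage_fraction)))
})

test_that("a perfect phageome echo labels every true phage contig phage", {
  study <- generate_study(small_cfg())   # easy preset: recovery 1, no noise
  lab <- study_labels(study)
  truth <- study$truth$true_class[match(lab$contig_id,
                                        study$truth$contig_id)]
  expect_true(all(lab$label[truth == "phage"] == "phage"))
  expect_true(all(lab$label[truth == "bacterial"] == "non_phage"))
})

test_that("noisy presets produce ambiguous labels and missed phage", {
  study <- generate_study(sim_config(n_subjects = 3L,
                                     n_samples_per_subject = 3L,
                                     n_contigs_per_sample = 120L,
                                     preset = "hard", rng_seed = 9L))
  lab <- study_labels(study)
  expect_true(any(lab$label == "ambiguous"))
  truth <- study$truth$true_class[match(lab$contig_id,
                                        study$truth$contig_id)]
  expect_true(any(lab$label[truth == "phage"] != "phage"))
})

test_that("written studies parse back through the readers", {
  study <- generate_study(small_cfg())
  dir <- tempfile("study")
  write_study(study, dir, sequences = TRUE)

  ctg <- read_fasta(file.path(dir, "contigs.fa"))
  expect_setequal(ctg$id, study$contigs$id)
  expect_equal(ctg$length[match(study$contigs$id, ctg$id)],
               study$contigs$length)
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(nrow(genes), nrow(study$genes))
  for (db in unique(study$hits$database)) {
    hits <- read_annotation_hits(file.path(dir,
                                           sprintf("hits_%s.tsv", db)), db)
    expect_equal(nrow(hits), sum(study$hits$database == db))
    expect_equal(sort(hits$evalue),
                 sort(study$hits$evalue[study$hits$database == db]))
  }
  ms <- read_mapping_summary(file.path(dir, "mapping.tsv"), study$totals,
                             study$contigs)
  expect_equal(ms$relative_abundance, study$mapping$relative_abundance)
  aln <- read_alignment_table(file.path(dir, "meta_vs_phageome.tsv"))
  expect_equal(nrow(aln), nrow(study$phageome_aln))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  expect_setequal(truth$contig_id, study$contigs$id)  # truth covers all
})

test_that("annotation rates differ measurably between the classes", {
  study <- generate_study(sim_config(n_subjects = 2L,
                                     n_samples_per_subject = 3L,
                                     n_contigs_per_sample = 200L,
                                     rng_seed = 13L))
  vf <- study$hits[study$hits$database == "viral_family" &
                     study$hits$evalue <= 1e-5, ]
  gene_contig <- study$genes$contig_id[match(vf$gene_id,
                                             study$genes$gene_id)]
  cls <- study$truth$true_class[match(study$genes$contig_id,
                                      study$truth$contig_id)]
  n_genes <- table(cls)
  n_hit <- table(study$truth$true_class[match(gene_contig,
                                              study$truth$contig_id)])
  tab <- rbind(hit = as.numeric(n_hit[c("phage", "bacterial")]),
               miss = as.numeric(n_genes[c("phage", "bacterial")]) -
                 as.numeric(n_hit[c("phage", "bacterial")]))
  expect_lt(suppressWarnings(chisq.test(tab)$p.value), 1e-6)
})

test_that("infeasible configurations are rejected early", {
  expect_error(sim_config(n_subjects = 1L, n_samples_per_subject = 1L,
                          n_contigs_per_sample = 10L,
                          phage_fraction = 0.02),
               "infeasible")
  expect_error(sim_config(phage_fraction = 0), "phage_fraction")
})

test_that("genus genome generation is seeded and ordered", {
  set.seed(3); g1 <- generate_genus_genomes(2, 2, 5000)
  set.seed(3); g2 <- generate_genus_genomes(2, 2, 5000)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genomes), 4L)
  expect_equal(unique(g1$taxonomy$genus), c("genus_A", "genus_B"))
  expect_true(all(nchar(g1$genomes$sequence) == 5000))
})
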