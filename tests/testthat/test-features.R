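fixture_annotation <- function() {
  contigs <- data.frame(id = c("c1", "c2"), sample_id = "s1",
                        length = c(10000L, 5000L), stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10), contig_id = "c1",
    start = seq(1L, 9001L, by = 1000L),
    end = seq(900L, 9900L, by = 1000L), strand = "+",
    stringsAsFactors = FALSE)
  hit <- function(g, db, ev) data.frame(
    gene_id = g, database = db, subject_id = "x", evalue = ev,
    bit_score = 100, identity_pct = 50, aln_length = 100L,
    stringsAsFactors = FALSE)
  hits <- rbind(hit("g01", "uPOG", 1e-10), hit("g02", "uPOG", 1e-9),
                hit("g03", "uPOG", 1e-8), hit("g04", "uPOG", 1e-5),
                hit("g04", "uPOG", 1e-30),            # same gene twice
                hit("g05", "uPOG", 1e-4),             # above cutoff
                hit("g01", "viral_family", 1e-12),
                hit("g02", "viral_family", 1e-12),
                hit("g03", "viral_family", 1e-12),
                hit("g04", "viral_family", 1e-12),
                hit("g06", "KO", 1e-6), hit("g07", "Pfam", 1e-6),
                hit("g08", "hallmark", 1e-6))
  mapping <- data.frame(contig_id = c("c1", "c2"), sample_id = "s1",
                        mapped_reads = c(500, 100),
                        total_reads_in_sample = 1e6,
                        relative_abundance = c(5e-4, 1e-4),
                        depth = c(0.05, 0.02), stringsAsFactors = FALSE)
  list(contigs = contigs, genes = genes, hits = hits, mapping = mapping)
}

test_that("annotated genes are counted distinctly at the inclusive cutoff", {
  fx <- fixture_annotation()
  # g01-g04 qualify (1e-5 inclusive; duplicate hit counted once), g05 not
  expect_equal(count_annotated_genes(fx$genes, fx$hits, "uPOG"), 4L)
  expect_equal(count_annotated_genes(fx$genes, fx$hits, "KO"), 1L)
  only_weak <- fx$hits[fx$hits$gene_id == "g05", ]
  expect_equal(count_annotated_genes(fx$genes, only_weak, "uPOG"), 0L)
  bad <- fx$hits; bad$gene_id[1] <- "ghost"
  expect_error(count_annotated_genes(fx$genes, bad, "uPOG"),
               "unknown gene")
})

test_that("feature vectors follow the printed definitions", {
  fx <- fixture_annotation()
  fv <- extract_features(fx$contigs, fx$genes, fx$hits, fx$mapping)
  expect_equal(nrow(fv), 1L)          # c2 at exactly 5000 bp is skipped
  expect_equal(fv$contig_id, "c1")
  expect_equal(fv$f1_avg_depth, 0.05) # 500 reads / 10000 bp
  expect_equal(fv$f2_n_genes, 10L)
  expect_equal(fv$f3_n_upog, 4L)
  expect_equal(fv$f4_n_viral_family, 4L)
  expect_equal(fv$f5_pct_viral_family, 0.4)
  expect_equal(fv$f6_n_ko, 1L)
  expect_equal(fv$f7_pct_ko, 0.1)
  expect_equal(fv$f10_n_hallmark, 1L)
})

test_that("length cutoff changes membership but never feature values", {
  fx <- fixture_annotation()
  at5k <- extract_features(fx$contigs, fx$genes, fx$hits, fx$mapping,
                           min_length = 5000L)
  at1k <- extract_features(fx$contigs, fx$genes, fx$hits, fx$mapping,
                           min_length = 1000L)
  expect_equal(nrow(at1k), 2L)
  shared <- intersect(at1k$contig_id, at5k$contig_id)
  expect_equal(at1k[at1k$contig_id %in% shared, ],
               at5k[at5k$contig_id %in% shared, ])
})

test_that("contigs without genes keep zero counts and their depth", {
  fx <- fixture_annotation()
  contigs <- rbind(fx$contigs,
                   data.frame(id = "c3", sample_id = "s1", length = 9000L))
  mapping <- rbind(fx$mapping,
                   data.frame(contig_id = "c3", sample_id = "s1",
                              mapped_reads = 90,
                              total_reads_in_sample = 1e6,
                              relative_abundance = 9e-5, depth = 0.01))
  fv <- extract_features(contigs, fx$genes, fx$hits, mapping)
  row <- fv[fv$contig_id == "c3", ]
  expect_equal(row$f2_n_genes, 0L)
  expect_equal(row$f5_pct_viral_family, 0)
  expect_equal(row$f1_avg_depth, 0.01)
  expect_error(extract_features(contigs, fx$genes, fx$hits, fx$mapping),
               "missing mapping")
})

test_that("feature invariants hold on simulated data", {
  study <- generate_study(sim_config(n_subjects = 2L,
                                     n_samples_per_subject = 2L,
                                     n_contigs_per_sample = 40L,
                                     rng_seed = 5L))
  fv <- extract_features(study$contigs, study$genes, study$hits,
                         study$mapping)
  counts <- as.matrix(fv[, c("f3_n_upog", "f4_n_viral_family", "f6_n_ko",
                             "f8_n_pfam", "f10_n_hallmark")])
  expect_true(all(counts <= fv$f2_n_genes))
  pct <- as.matrix(fv[, c("f5_pct_viral_family", "f7_pct_ko",
                          "f9_pct_pfam")])
  expect_true(all(pct >= 0 & pct <= 1))
  expect_equal(fv$f5_pct_viral_family,
               ifelse(fv$f2_n_genes > 0,
                      fv$f4_n_viral_family / fv$f2_n_genes, 0))
})
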