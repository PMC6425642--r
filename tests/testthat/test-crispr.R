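test_that("bacterial contig selection uses a strict e-value bound", {
  hits <- data.frame(query_id = c("c1", "c2", "c2", "c3"),
                     evalue = c(1e-6, 1e-5, 2e-5, 1e-30))
  expect_setequal(select_bacterial_contigs(hits), c("c1", "c3"))
})

test_that("planted arrays are recovered exactly", {
  set.seed(99)
  phage <- random_dna(20000)
  bact <- random_dna(8000)
  pl <- plant_crispr(bact, phage, n_spacers = 3)
  arr <- detect_crispr_arrays(pl$sequence)
  expect_length(arr, 1L)
  expect_equal(arr[[1]]$repeat_consensus, pl$repeat_seq)
  expect_equal(arr[[1]]$spacers$seq, pl$truth$spacer_seq)
  expect_equal(arr[[1]]$spacers$start, pl$truth$spacer_start)
  expect_equal(nrow(arr[[1]]$repeat_positions), 4L)
})

test_that("array detection ignores case and commutes with reverse complement", {
  set.seed(53)
  pl <- plant_crispr(random_dna(6000), random_dna(5000), n_spacers = 3)
  lower <- detect_crispr_arrays(tolower(pl$sequence))
  expect_length(lower, 1L)
  expect_equal(lower[[1]]$spacers$seq, pl$truth$spacer_seq)
  rc <- detect_crispr_arrays(revcomp(pl$sequence))
  expect_length(rc, 1L)
  expect_setequal(vapply(rev(seq_len(3)), function(i)
    revcomp(rc[[1]]$spacers$seq[i]), ""), pl$truth$spacer_seq)
})

test_that("tandem repeats with identical spacers are rejected", {
  set.seed(5)
  rep_seq <- random_dna(28); sp <- random_dna(32)
  tandem <- paste0(random_dna(500),
                   rep_seq, sp, rep_seq, sp, rep_seq, sp, rep_seq,
                   random_dna(500))
  expect_length(detect_crispr_arrays(tandem), 0L)
})

test_that("random sequence contains no arrays", {
  set.seed(7)
  for (i in 1:5) expect_length(detect_crispr_arrays(random_dna(10000)), 0L)
})

test_that("zero spacers leave the host sequence unchanged", {
  s <- random_dna(2000)
  pl <- plant_crispr(s, random_dna(5000), n_spacers = 0)
  expect_identical(pl$sequence, s)
  expect_equal(nrow(pl$truth), 0L)
})

test_that("spacer matching enforces the mismatch budget and best-hit rule", {
  set.seed(61)
  phage <- random_dna(20000)
  decoy <- random_dna(20000)
  sp32 <- substr(phage, 1001, 1032)
  contigs <- data.frame(id = c("phageA", "decoy"),
                        sequence = c(phage, decoy))
  m <- match_spacers(data.frame(spacer_id = "s1", seq = sp32), contigs)
  expect_equal(m$phage_contig_id, "phageA")
  expect_equal(m$identity_pct, 100)
  expect_equal(m$aligned_length, 32L)

  # one mismatch in 32 bp: 31/32 = 96.9% passes the 95% rule
  mut1 <- sp32
  substr(mut1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(sp32, 10, 10))[1]
  m1 <- match_spacers(data.frame(spacer_id = "s1", seq = mut1), contigs)
  expect_equal(m1$mismatches, 1L)
  # two mismatches: 30/32 = 93.75% < 95 -> rejected
  mut2 <- mut1
  substr(mut2, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  substr(sp32, 20, 20))[1]
  expect_equal(nrow(match_spacers(data.frame(spacer_id = "s1", seq = mut2),
                                  contigs)), 0L)
  # exact mode rejects even one mismatch
  expect_equal(nrow(match_spacers(data.frame(spacer_id = "s1", seq = mut1),
                                  contigs, exact = TRUE)), 0L)

  # reverse-complemented spacer still matches, on the minus strand
  mrc <- match_spacers(data.frame(spacer_id = "s1", seq = revcomp(sp32)),
                       contigs)
  expect_equal(mrc$phage_contig_id, "phageA")
  expect_equal(mrc$strand, "-")
})

test_that("ties across contigs resolve to one deterministic best match", {
  set.seed(3)
  core <- random_dna(5000)
  sp <- substr(core, 101, 132)
  contigs <- data.frame(id = c("zeta", "alpha"),
                        sequence = c(core, core))  # both match at 100%
  m <- match_spacers(data.frame(spacer_id = "s1", seq = sp), contigs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$phage_contig_id, "alpha")  # lexicographic tie-break
})

test_that("host networks aggregate support and handle missing taxa", {
  matches <- data.frame(
    spacer_id = c("s1", "s2", "s3"),
    phage_contig_id = c("ph1", "ph1", "ph1"),
    identity_pct = 100, aligned_length = 32L, mismatches = 0L,
    strand = "+", evalue_proxy = 1e-10)
  hosts <- data.frame(spacer_id = c("s1", "s2", "s3"),
                      host_contig_id = c("b1", "b2", "b1"),
                      sample_id = "S1", subject_id = "subj1")
  net <- build_host_network(matches, hosts,
                            phage_taxa = c(ph1 = "Tequatrovirus"),
                            host_taxa = c(b1 = "E. coli"),
                            level = "species")
  expect_equal(nrow(net), 2L)
  ecoli <- net[net$host == "E. coli", ]
  expect_equal(ecoli$support, 2L)
  expect_true("unclassified" %in% net$host)  # b2 lacks taxonomy

  contig_net <- build_host_network(matches, hosts, level = "contig")
  expect_equal(sum(contig_net$support), 3L)
  empty <- build_host_network(matches[0, ], hosts)
  expect_equal(nrow(empty), 0L)
})
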