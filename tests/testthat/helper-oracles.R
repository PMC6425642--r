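# Independent oracles used across test files. These re-derive expected
# values from first principles and must stay independent of the package
# implementation paths they check.

# interval-union length by explicit base-position enumeration
brute_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  length(unique(unlist(Map(seq, starts, ends))))
}

# three-category label rules, re-coded literally from their text:
# phage: any pair with coverage > 80% or aligned length > 10 kb;
# ambiguous: any pair with coverage 40-80% or aligned length 4-10 kb;
# else confident non-phage
brute_label <- function(coverage, aligned_length) {
  if (any(coverage > 0.80 | aligned_length > 10000)) return("phage")
  if (any((coverage >= 0.40 & coverage <= 0.80) |
          (aligned_length >= 4000 & aligned_length <= 10000)))
    return("ambiguous")
  "non_phage"
}

# rule-based viral call, re-coded literally from the three conditions
brute_rule_viral <- function(n_genes, n_vf, n_ko, n_pfam) {
  pv <- if (n_genes > 0) n_vf / n_genes else 0
  pk <- if (n_genes > 0) n_ko / n_genes else 0
  pp <- if (n_genes > 0) n_pfam / n_genes else 0
  cond1 <- n_vf >= 5 && pk < 0.20 && pp <= 0.40 && pv > 0.10
  cond2 <- n_vf >= n_pfam
  cond3 <- pv >= 0.60
  cond1 || cond2 || cond3
}

# exact two-sided rank-sum p-value by full enumeration of all
# choose(n+m, n) group assignments of the pooled observations
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# small fully-specified feature frame for classifier tests: the phage
# class has viral-family counts around `sep` and the bacterial class
# around 0, everything else shared noise
make_separable_features <- function(n_phage, n_nonphage, sep = 8,
                                    subject = "s1", prefix = "c") {
  n <- n_phage + n_nonphage
  lab <- rep(c("phage", "non_phage"), c(n_phage, n_nonphage))
  f2 <- pmax(2L, rpois(n, 9))
  f4 <- pmax(0L, round(rnorm(n, ifelse(lab == "phage", sep, 0), 1)))
  f4 <- pmin(f4, f2)
  f6 <- pmin(f2, pmax(0L, round(rnorm(n, ifelse(lab == "phage", 1, 6), 1))))
  f8 <- pmin(f2, pmax(0L, round(rnorm(n, ifelse(lab == "phage", 2, 7), 1))))
  f3 <- pmin(f2, f4 + rbinom(n, 1, 0.3))
  f10 <- pmin(f2, rbinom(n, 1, ifelse(lab == "phage", 0.4, 0.01)))
  data.frame(
    contig_id = paste0(prefix, seq_len(n)), sample_id = subject,
    subject_id = subject,
    f1_avg_depth = runif(n, 0.01, 0.2),
    f2_n_genes = f2, f3_n_upog = f3, f4_n_viral_family = f4,
    f5_pct_viral_family = f4 / f2, f6_n_ko = f6, f7_pct_ko = f6 / f2,
    f8_n_pfam = f8, f9_pct_pfam = f8 / f2, f10_n_hallmark = f10,
    label = lab, stringsAsFactors = FALSE)
}
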