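---
title: "Mining phage contigs from paired metagenome/phageome studies"
author: "phageminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining phage contigs from paired metagenome/phageome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageminer)
```

## The problem

Bacteriophages shape microbial communities, but in bulk metagenomic
sequencing their contigs are mixed with a large bacterial majority —
typically only about 2% of assembled contigs are phage. `phageminer`
implements a supervised approach to this separation: when a study also
sequences purified phage particles (a *phageome*) from the same
samples, the phageome assembly provides ground truth for training a
classifier that then works on metagenomes alone, together with the
downstream analyses a phage study needs (host prediction from CRISPR
spacers, k-mer taxonomy, orthologous-group statistics, abundance and
diversity comparisons).

## Ground-truth labelling

Metagenomic contigs are aligned to the same subject's phageome contigs
(the package consumes the alignment table; running the search is out of
scope). After screening at e-value < 1e-5 and identity > 98%, the local
alignments of each contig pair are merged by query-interval union —
this avoids double-counting overlapping HSPs, and is our choice where
the multi-HSP treatment is genuinely open — and each metagenomic contig
receives one of three labels:

* **phage** — some pair covers > 80% of the shorter contig, or aligns
  > 10 kb;
* **ambiguous** — some pair reaches 40–80% coverage or 4–10 kb;
* **confident non-phage** — nothing qualifies.

Two boundary conventions are deliberate. The phage thresholds are
strict and the ambiguous band is closed, so coverage of exactly 0.80
is ambiguous, mirroring the "> 80%" versus "40–80%" wording of the
rules. And a single pair must satisfy a criterion on its own: evidence
is never summed across different phageome contigs, since each match is
read as "this contig is present in the phageome".

## Features and the classifier

Each contig longer than 5 kb (a configurable cutoff; 1 kb and 3 kb are
supported variants) is described by 10 predictors: average read depth
(mapped reads / length), gene count, and the counts and gene fractions
of annotations to phage orthologous groups, viral protein families, KO,
Pfam, and viral hallmark genes. Annotation hits qualify at
e-value <= 1e-5; the inclusive boundary here follows the usual reading
of an annotation "cutoff", intentionally different from the strict
alignment filters above. Fractions are stored in [0, 1]; for tree
models the scale is immaterial, and fractions compose cleanly. Contigs
with no predicted genes keep zero counts and stay in the data — their
depth is still informative.

The classifier is a random forest (`randomForest`, mtry = 7,
ntree = 1500, fully grown trees) wrapped as the S3 model `phage_rf`.
Because non-phage contigs outnumber phage contigs ~50:1, each training
set takes **all** phage contigs, **all** ambiguous contigs, and 3000
confident non-phage contigs sampled (seeded) from those at or above the
median non-phage relative abundance. Two open points are resolved as
package choices: ambiguous contigs train as the *negative* class (they
are counted as non-phage at evaluation time, and training and
evaluation should agree; `ambiguous_in_training = FALSE` drops them
instead), and the negative sample is redrawn per cross-validation fold
with a fold-derived seed, so folds are independent given the master
seed. The decision threshold on the ensemble vote is 0.5 and exposed in
the configuration.

Evaluation uses two weighting schemes: **count** (each contig is one
unit) and **abundance** (each contig contributes its fraction of the
sample's mapped reads). The abundance scheme is the one this approach
optimises for — a missed high-abundance phage matters more than a
missed singleton. Cross-validation is leave-one-subject-out: all
samples of one subject form the test fold, so longitudinal samples of
the same person never straddle the train/test boundary. Ratios with
zero denominators are reported as `NaN` with a flag, never silently
zeroed, because zeros would distort fold averages.

A rule-based baseline (`rule_based_viral`) implements the
published annotation-threshold conditions (>= 5 viral-family hits with
< 20% KO, <= 40% Pfam and > 10% viral-family fractions; or
viral-family count >= Pfam count; or >= 60% viral-family genes) for
comparison.

## Orthologous-group statistics

For phage orthologous groups (POGs), the virus quotient is
VQ = viral / (viral + prokaryotic) over *distinct* genomes matched —
genome granularity avoids double-counting paralogous hits — after
excluding prokaryotic genomes on a caller-supplied exclusion list
(e.g. genomes with detected prophage regions). Matches qualify at
e-value <= 0.001, bit score > 40 and >= 40 aligned amino acids. A group
is virus-specific at VQ > 0.85 (strict, so 17 viral vs 3 prokaryotic
genomes — VQ exactly 0.85 — does not qualify), and a taxon-signature
marker needs precision exactly 1 (a set test, not a float tolerance),
recall > 0.85, VQ > 0.85 and single-copy presence. The strict recall
boundary follows the wording adopted here; the earlier literature is
ambiguous between > and >=.

## CRISPR host prediction

The array detector is implemented in-package rather than shelling out
to an external tool, so it is testable end to end: exact 19-mer seeds
recurring at 38–86 bp intervals are chained (>= 3 copies), extended by
column consensus with one mismatch allowed per copy, then trimmed so
boundary columns are unanimous. Repeats must be 19–38 bp, spacers
19–48 bp, and arrays whose spacers are > 90% mutually identical are
rejected as tandem repeats. Spacers are matched ungapped against
predicted phage contigs on both strands; instead of a database-size
dependent e-value the filter is an explicit mismatch budget,
`floor(0.05 * length)` (the 95% identity rule; one mismatch for a 32-bp
spacer), with a naive expected-hit count reported as `evalue_proxy`.
One best hit is kept per spacer (identity, then length, then contig
id), and an `exact` flag reproduces the stricter exact-match reading.
Edges aggregate matches at contig, species or genus level with support
counts; nodes without taxonomy are labelled "unclassified".

## Taxonomy

`phage_nb` is a word-presence naive-Bayes classifier over all 8-base
subsequences, the formulation used by rRNA taxonomy classifiers: prior
P(w) = (n(w)+0.5)/(N+1) over N training genomes, per-taxon conditional
P(w|t) = (m(w)+P(w))/(M+1). Words are merged with their reverse
complements by default because contig strand is arbitrary
(`canonical = FALSE` disables this). Confidence is the fraction of 100
bootstrap trials — each rescoring ceil(W/8) of the contig's W distinct
words — agreeing with the full-word assignment, propagated to genus
level by lineage; assignments at confidence <= 0.5 are flagged for
discarding.

## Community statistics

Abundance uses TPM (length-normalised counts scaled to 10^6 per
sample). Two-group comparisons are two-sided Wilcoxon rank-sum tests
per feature; the raw p < 0.05 flag is reported to mirror common
practice in this setting, with Benjamini–Hochberg FDR alongside since
modern readers expect it. Diversity per sample is richness, Shannon H,
Simpson in Gini form 1 − Σp² (inverse form via an option) and Pielou
J = H / ln S, computed through `vegan`; J is `NaN` for S <= 1.
Diversity uses abundance-weighted inputs — presence-only inputs are the
other defensible reading, and richness covers that view.

## The simulator

`generate_study()` emits a complete synthetic study: by default 10
subjects × 6 longitudinal samples × 150 contigs, 2% phage, lognormal
contig lengths (median ~9 kb) and abundance weights (σ = 1.5, a typical
metagenomic spread), 2×10^6 reads per sample, about one gene per kb,
and class-conditional annotation rates (e.g. viral-family hits on 55%
of phage genes vs 2% of bacterial genes at the `easy` preset), plus a
few percent of hits above the e-value cutoff that the feature extractor
must ignore. The phageome echoes each true phage contig with
probability 1 at `easy` (0.9/0.75 with coverage noise and spurious
partial echoes of bacterial contigs at `medium`/`hard`, which creates
ambiguous labels and missed phage). Everything is a deterministic
function of the seed. Sequence-level behaviour is exercised by
dedicated generators: `plant_crispr()` inserts repeat-spacer arrays
whose spacers are exact phage substrings (protospacer positions are
resampled so repeat boundaries stay recoverable), and
`generate_genus_genomes()` gives each genus its own order-3 Markov
composition; an order-0 shared-composition mode is the negative
control. The main study tables therefore carry no nucleotide sequences
unless `write_study(..., sequences = TRUE)` is asked for them — the
classifier path is purely tabular.

What the simulator does *not* emulate matters for interpreting green
tests: real annotation sparsity structure, assembly artefacts, chimeric
contigs, strain mixtures, shared k-mer composition between phages and
their hosts, and read-level noise are all absent. Passing the closure
tests shows the machinery is correct and the statistical contracts
hold; it does not certify field performance on real gut metagenomes.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run the full
cross-validation at the default study size (9000 contigs, 10 subjects),
50 planted CRISPR arrays, 2×5 training genomes of 25 kb with 10-kb
held-out fragments, and 1000-feature null simulations — sizes chosen so
a complete run stays comfortable on a laptop while keeping every
estimate's Monte-Carlo error well inside the asserted margins. The null
calibration of the two-group test uses 15 samples per group: below ~15
the exact rank-sum test is too discrete to attain a 5% level at all
(its true size at 4 vs 4 is 2/70 ≈ 0.029), so smaller groups would
measure the test's granularity, not its calibration. Ties in
spacer matching and taxonomy argmax break deterministically
(lexicographic / first index). Degenerate inputs (no alignments, empty
groups, all-zero counts, single-taxon models) return explicit flags or
errors rather than silent zeros.
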