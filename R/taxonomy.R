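#' Train the naive-Bayes 8-mer taxonomy classifier
#'
#' Word-presence naive-Bayes model over all 8-base subsequences, the
#' scheme used by rRNA taxonomy classifiers: the prior of word \eqn{w} is
#' \eqn{P(w) = (n(w) + 0.5) / (N + 1)} with \eqn{n(w)} the number of
#' training genomes containing \eqn{w} and \eqn{N} the total genome
#' count, and the per-taxon conditional is
#' \eqn{P(w | t) = (m(w) + P(w)) / (M + 1)} with \eqn{m(w)} the count
#' among the taxon's \eqn{M} genomes. Duplicated words within a genome
#' carry no extra weight (presence/absence semantics). By default, each
#' word is merged with its reverse complement (canonical form), since
#' the sequenced strand of a phage contig is arbitrary.
#'
#' The model is trained at the finest rank present in `taxonomy`
#' (`species` when that column exists, else `genus`); genus-level
#' assignments are propagated through the lineage.
#'
#' @param genomes data.frame with `id` and `sequence` (training phage
#'   genomes).
#' @param taxonomy data.frame with `genome_id`, `genus` and optionally
#'   `species`.
#' @param canonical merge reverse-complement words (default TRUE).
#' @param word_size word length in bases (8).
#' @return an object of class `phage_nb` with `print` and `predict`
#'   methods.
#' @export
phage_nb <- function(genomes, taxonomy, canonical = TRUE, word_size = 8L) {
  mi <- match(genomes$id, taxonomy$genome_id)
  if (anyNA(mi))
    stop("genome without taxonomy: ", genomes$id[is.na(mi)][1L],
         call. = FALSE)
  rank <- if ("species" %in% names(taxonomy)) "species" else "genus"
  taxon <- taxonomy[[rank]][mi]
  genus <- taxonomy$genus[mi]
  if (anyNA(taxon) || any(taxon == ""))
    stop("empty taxon label in taxonomy table", call. = FALSE)
  taxa <- sort(unique(taxon))
  lineage <- vapply(taxa, function(t) unique(genus[taxon == t])[1L], "")

  wmap <- .word_map(word_size, canonical)
  pres <- vapply(genomes$sequence, function(s)
    .word_presence(s, word_size, wmap), logical(wmap$n_words))
  N <- nrow(genomes)
  prior <- (rowSums(pres) + 0.5) / (N + 1)
  cond <- vapply(taxa, function(t) {
    cols <- which(taxon == t)
    M <- length(cols)
    m <- if (length(cols) > 1L) rowSums(pres[, cols, drop = FALSE])
         else as.numeric(pres[, cols])
    (m + prior) / (M + 1)
  }, numeric(wmap$n_words))
  structure(list(taxa = taxa, rank = rank, lineage = lineage,
                 log_cond = log(cond), word_prior = prior,
                 word_size = as.integer(word_size),
                 canonical = isTRUE(canonical),
                 training_counts = table(taxon)),
            class = "phage_nb")
}

# canonical-word bookkeeping: index map from the 4^k lexicographic word
# order (as produced by oligonucleotideFrequency) to model word indices
.word_map <- function(word_size, canonical) {
  n_all <- 4L^word_size
  if (!canonical)
    return(list(index = seq_len(n_all), n_words = n_all))
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), word_size)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(words)))
  canon <- ifelse(words <= rc, words, rc)
  fac <- factor(canon, levels = sort(unique(canon)))
  list(index = as.integer(fac), n_words = nlevels(fac))
}

.word_presence <- function(sequence, word_size, wmap) {
  s <- Biostrings::DNAString(toupper(sequence))
  if (length(s) < word_size)
    stop("sequence shorter than the word size", call. = FALSE)
  freq <- Biostrings::oligonucleotideFrequency(s, width = word_size)
  present <- freq > 0L
  out <- logical(wmap$n_words)
  out[wmap$index[present]] <- TRUE
  out
}

#' @export
print.phage_nb <- function(x, ...) {
  cat("Naive-Bayes", x$word_size, "-mer taxonomy classifier\n", sep = "")
  cat(sprintf("  rank: %s; taxa: %d; words: %d%s\n", x$rank,
              length(x$taxa), nrow(x$log_cond),
              if (x$canonical) " (canonical)" else ""))
  print(x$training_counts)
  invisible(x)
}

#' Classify contigs with bootstrap confidence
#'
#' Assigns each contig to the maximum-posterior taxon over its distinct
#' 8-base words, then estimates confidence as the fraction of
#' `n_bootstrap` trials — each rescoring a random subsample of
#' `ceil(W * word_fraction)` of the contig's `W` distinct words — that
#' agree with the full-word assignment. Genus-level confidence counts
#' trials whose selected taxon lies in the same genus. Assignments with
#' confidence at or below 0.5 are flagged `retained = FALSE` and should
#' be discarded.
#'
#' @param object a fitted [phage_nb()] model.
#' @param newdata data.frame with `id` and `sequence` (contigs), or a
#'   character vector of sequences.
#' @param n_bootstrap number of bootstrap trials (default 100).
#' @param word_fraction fraction of distinct words per trial (default
#'   1/8).
#' @param rng_seed seed for the bootstrap subsampling.
#' @param ... unused.
#' @return data.frame with one row per contig and rank: `contig_id`,
#'   `rank`, `taxon`, `confidence`, `retained`.
#' @export
predict.phage_nb <- function(object, newdata, n_bootstrap = 100L,
                             word_fraction = 1 / 8, rng_seed = 1L, ...) {
  if (is.character(newdata))
    newdata <- data.frame(id = paste0("contig", seq_along(newdata)),
                          sequence = newdata, stringsAsFactors = FALSE)
  wmap <- .word_map(object$word_size, object$canonical)
  ranks <- unique(c(object$rank, "genus"))
  out <- .with_seed(rng_seed, {
    rows <- lapply(seq_len(nrow(newdata)), function(i) {
      pres <- .word_presence(newdata$sequence[i], object$word_size, wmap)
      widx <- which(pres)
      score <- colSums(object$log_cond[widx, , drop = FALSE])
      best <- which.max(score)
      n_sub <- ceiling(length(widx) * word_fraction)
      boots <- vapply(seq_len(n_bootstrap), function(b) {
        sub <- sample(widx, n_sub)
        which.max(colSums(object$log_cond[sub, , drop = FALSE]))
      }, integer(1))
      res <- list()
      for (r in ranks) {
        if (r == object$rank) {
          taxon <- object$taxa[best]
          conf <- mean(boots == best)
        } else {
          taxon <- object$lineage[best]
          conf <- mean(object$lineage[boots] == taxon)
        }
        res[[r]] <- data.frame(contig_id = newdata$id[i], rank = r,
                               taxon = unname(taxon), confidence = conf,
                               retained = conf > 0.5,
                               stringsAsFactors = FALSE)
      }
      do.call(rbind, res)
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}
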