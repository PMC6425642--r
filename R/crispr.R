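#' Select bacterial contigs from prokaryote-reference hits
#'
#' A contig is treated as bacterial when it has at least one alignment to
#' a prokaryotic reference genome at e-value strictly below `evalue_max`.
#'
#' @param hits data.frame with `query_id` (contig id) and `evalue`
#'   columns, e.g. from [read_alignment_table()].
#' @param evalue_max exclusive e-value bound (default `1e-5`).
#' @return character vector of bacterial contig ids.
#' @export
select_bacterial_contigs <- function(hits, evalue_max = 1e-5) {
  unique(hits$query_id[hits$evalue < evalue_max])
}

#' Detect CRISPR repeat-spacer arrays in a contig
#'
#' Seed-and-extend detector in the style of repeat-recognition tools:
#' exact k-mer seeds recurring at regular intervals are chained, the
#' repeat is extended in both directions by column consensus (each copy
#' is allowed `max_repeat_mismatch` mismatches against the consensus),
#' and the intervening spacers are extracted. Arrays are rejected when
#' the repeat or any spacer falls outside the length bounds, or when any
#' two spacers are more than `spacer_max_identity` identical (which
#' discards plain tandem repeats). Detection is case-insensitive.
#'
#' @param sequence a single DNA string.
#' @param contig_id id recorded in the result.
#' @param min_repeats minimum repeat copies (default 3).
#' @param repeat_len,spacer_len inclusive length bounds, bp (defaults
#'   19--38 and 19--48).
#' @param max_repeat_mismatch per-copy mismatch allowance against the
#'   repeat consensus during extension.
#' @param spacer_max_identity two spacers above this identity reject the
#'   array (default 0.90).
#' @return list of arrays; each is a list with `contig_id`,
#'   `repeat_consensus`, `repeat_positions` (two-column matrix of
#'   start/end) and `spacers` (data.frame `seq`, `start`, `end`).
#' @export
detect_crispr_arrays <- function(sequence, contig_id = "contig",
                                 min_repeats = 3L,
                                 repeat_len = c(19L, 38L),
                                 spacer_len = c(19L, 48L),
                                 max_repeat_mismatch = 1L,
                                 spacer_max_identity = 0.90) {
  seq <- toupper(sequence)
  n <- nchar(seq)
  k <- repeat_len[1L]
  if (n < min_repeats * repeat_len[1L] + (min_repeats - 1L) * spacer_len[1L])
    return(list())
  ch <- strsplit(seq, "")[[1L]]
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  counts <- table(kmers)
  seeds <- names(counts)[counts >= min_repeats & !grepl("N", names(counts))]
  gap_min <- repeat_len[1L] + spacer_len[1L]
  gap_max <- repeat_len[2L] + spacer_len[2L]
  candidates <- list()
  for (sd in seeds) {
    pos <- starts[kmers == sd]
    # maximal runs of positions with consecutive gaps inside the window
    run_start <- 1L
    for (i in seq_along(pos)) {
      end_run <- i == length(pos) ||
        (pos[i + 1L] - pos[i] < gap_min || pos[i + 1L] - pos[i] > gap_max)
      if (end_run) {
        if (i - run_start + 1L >= min_repeats) {
          arr <- .extend_repeat(ch, pos[run_start:i], k, repeat_len,
                                spacer_len, max_repeat_mismatch)
          if (!is.null(arr)) candidates[[length(candidates) + 1L]] <- arr
        }
        run_start <- i + 1L
      }
    }
  }
  arrays <- .finalize_arrays(seq, candidates, contig_id, spacer_len,
                             spacer_max_identity)
  arrays
}

# Extend a chained seed into a repeat; returns list(starts, len) or NULL.
.extend_repeat <- function(ch, pos, k, repeat_len, spacer_len,
                           max_repeat_mismatch) {
  n <- length(ch)
  m <- length(pos)
  budget <- integer(m)
  left <- 0L; right <- 0L
  repeat_length <- function() k + left + right
  # right extension
  while (repeat_length() < repeat_len[2L]) {
    idx <- pos + k + right
    if (any(idx > n)) break
    # keep at least min spacer before the next repeat copy
    gap_after <- c(pos[-1L] - (pos[-m] + k + right), Inf)
    if (any(gap_after - 1L < spacer_len[1L])) break
    col <- ch[idx]
    cons <- names(which.max(table(col)))
    nb <- budget + (col != cons)
    if (any(nb > max_repeat_mismatch)) break
    budget <- nb; right <- right + 1L
  }
  # left extension
  while (repeat_length() < repeat_len[2L]) {
    idx <- pos - left - 1L
    if (any(idx < 1L)) break
    gap_before <- c(Inf, (pos[-1L] - left) - (pos[-m] + k + right))
    if (any(gap_before - 1L < spacer_len[1L])) break
    col <- ch[idx]
    cons <- names(which.max(table(col)))
    nb <- budget + (col != cons)
    if (any(nb > max_repeat_mismatch)) break
    budget <- nb; left <- left + 1L
  }
  len <- repeat_length()
  st <- pos - left
  # trim: boundary columns must be unanimous across copies, so fuzzy
  # extension never eats into the spacers
  unanimous <- function(idx) length(unique(ch[idx])) == 1L
  while (len > repeat_len[1L] && !unanimous(st + len - 1L)) len <- len - 1L
  while (len > repeat_len[1L] && !unanimous(st)) { st <- st + 1L; len <- len - 1L }
  if (len < repeat_len[1L] || len > repeat_len[2L]) return(NULL)
  list(starts = st, len = len)
}

.finalize_arrays <- function(seq, candidates, contig_id, spacer_len,
                             spacer_max_identity) {
  if (!length(candidates)) return(list())
  built <- list()
  for (cand in candidates) {
    st <- cand$starts; len <- cand$len
    ends <- st + len - 1L
    sp_start <- ends[-length(ends)] + 1L
    sp_end <- st[-1L] - 1L
    sp_len <- sp_end - sp_start + 1L
    if (any(sp_len < spacer_len[1L] | sp_len > spacer_len[2L])) next
    spacers <- substring(seq, sp_start, sp_end)
    if (.too_similar(spacers, spacer_max_identity)) next
    consensus <- .column_consensus(seq, st, len)
    built[[length(built) + 1L]] <- list(
      contig_id = contig_id, repeat_consensus = consensus,
      repeat_positions = cbind(start = st, end = ends),
      spacers = data.frame(seq = spacers, start = sp_start, end = sp_end,
                           stringsAsFactors = FALSE),
      span = c(st[1L], ends[length(ends)]),
      n_repeats = length(st))
  }
  if (!length(built)) return(list())
  # same physical array is found from every seed offset inside the repeat:
  # keep the widest candidate of each overlapping group
  ord <- order(-vapply(built, function(a) a$n_repeats, 0L),
               -vapply(built, function(a) diff(a$span), 0L),
               vapply(built, function(a) a$span[1L], 0L))
  accepted <- list()
  for (i in ord) {
    sp <- built[[i]]$span
    overlaps <- any(vapply(accepted, function(a)
      sp[1L] <= a$span[2L] && sp[2L] >= a$span[1L], TRUE))
    if (!overlaps) accepted[[length(accepted) + 1L]] <- built[[i]]
  }
  accepted[order(vapply(accepted, function(a) a$span[1L], 0L))]
}

.too_similar <- function(spacers, max_identity) {
  m <- length(spacers)
  if (m < 2L) return(FALSE)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    a <- spacers[i]; b <- spacers[j]
    la <- nchar(a); lb <- nchar(b)
    l <- min(la, lb)
    same <- sum(strsplit(substr(a, 1L, l), "")[[1L]] ==
                  strsplit(substr(b, 1L, l), "")[[1L]])
    if (same / max(la, lb) > max_identity) return(TRUE)
  }
  FALSE
}

.column_consensus <- function(seq, starts, len) {
  cols <- vapply(seq_len(len) - 1L, function(off) {
    col <- substring(seq, starts + off, starts + off)
    names(which.max(table(col)))
  }, "")
  paste(cols, collapse = "")
}

#' Match CRISPR spacers against phage contigs
#'
#' Ungapped full-length matching of each spacer (both strands) against a
#' set of predicted phage contigs. A hit qualifies when its mismatch
#' count is at most `floor((1 - identity_min/100) * spacer length)` —
#' at 95% identity a 32-bp spacer tolerates one mismatch. Only the best
#' hit per spacer is kept (highest identity, then longest alignment,
#' then lexicographically smallest contig id). `exact = TRUE` restricts
#' to perfect matches. The `evalue_proxy` column reports the naive
#' expected count of an equally good ungapped match in the searched
#' bases.
#'
#' @param spacers data.frame with `spacer_id` and `seq`.
#' @param phage_contigs data.frame with `id` and `sequence`.
#' @param identity_min minimum percent identity (default 95).
#' @param exact keep perfect matches only.
#' @return data.frame with `spacer_id`, `phage_contig_id`,
#'   `identity_pct`, `aligned_length`, `mismatches`, `strand`,
#'   `evalue_proxy`; at most one row per spacer.
#' @export
match_spacers <- function(spacers, phage_contigs, identity_min = 95,
                          exact = FALSE) {
  out <- list()
  if (nrow(spacers) == 0L || nrow(phage_contigs) == 0L)
    return(.empty_spacer_matches())
  subject <- Biostrings::DNAStringSet(toupper(phage_contigs$sequence))
  names(subject) <- phage_contigs$id
  total_bases <- sum(Biostrings::width(subject))
  for (i in seq_len(nrow(spacers))) {
    sp <- toupper(spacers$seq[i])
    len <- nchar(sp)
    budget <- if (exact) 0L else floor((1 - identity_min / 100) * len)
    pat <- Biostrings::DNAString(sp)
    rcpat <- Biostrings::reverseComplement(pat)
    best <- NULL
    for (mm in 0L:budget) {
      fwd <- Biostrings::vcountPattern(pat, subject, max.mismatch = mm)
      rev <- Biostrings::vcountPattern(rcpat, subject, max.mismatch = mm)
      hit <- which(fwd + rev > 0L)
      if (length(hit)) {
        # mm is the smallest budget with a hit => min mismatch count
        cid <- sort(phage_contigs$id[hit])[1L]
        j <- match(cid, phage_contigs$id)
        best <- data.frame(
          spacer_id = spacers$spacer_id[i], phage_contig_id = cid,
          identity_pct = 100 * (len - mm) / len, aligned_length = len,
          mismatches = mm,
          strand = if (fwd[j] > 0L) "+" else "-",
          evalue_proxy = 2 * total_bases * choose(len, mm) *
            3^mm * 0.25^len,
          stringsAsFactors = FALSE)
        break
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  if (!length(out)) return(.empty_spacer_matches())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_spacer_matches <- function() {
  data.frame(spacer_id = character(), phage_contig_id = character(),
             identity_pct = numeric(), aligned_length = integer(),
             mismatches = integer(), strand = character(),
             evalue_proxy = numeric(), stringsAsFactors = FALSE)
}

#' Build a phage-host network from spacer matches
#'
#' Aggregates spacer-to-phage matches into host-prediction edges at the
#' requested level. At `level = "contig"` nodes are contig ids; at
#' `"species"`/`"genus"` nodes are taken from the taxonomy maps, with
#' missing assignments labelled `"unclassified"`. Support counts the
#' spacer matches behind each edge.
#'
#' @param matches data.frame from [match_spacers()].
#' @param spacer_hosts data.frame with `spacer_id`, `host_contig_id` and
#'   optionally `sample_id`, `subject_id`.
#' @param phage_taxa,host_taxa optional named character vectors mapping
#'   contig ids to taxa at the requested level.
#' @param level aggregation level.
#' @return data.frame of edges: `phage`, `host`, `support`, plus
#'   `sample_id`/`subject_id` when supplied (edges are per sample/subject
#'   combination in that case).
#' @export
build_host_network <- function(matches, spacer_hosts, phage_taxa = NULL,
                               host_taxa = NULL,
                               level = c("contig", "species", "genus")) {
  level <- match.arg(level)
  if (nrow(matches) == 0L)
    return(data.frame(phage = character(), host = character(),
                      support = integer(), stringsAsFactors = FALSE))
  mi <- match(matches$spacer_id, spacer_hosts$spacer_id)
  if (anyNA(mi))
    stop("spacer without host-contig record: ",
         matches$spacer_id[is.na(mi)][1L], call. = FALSE)
  node <- function(ids, taxa) {
    if (level == "contig" || is.null(taxa)) return(ids)
    out <- unname(taxa[ids])
    out[is.na(out)] <- "unclassified"
    out
  }
  edges <- data.frame(
    phage = node(matches$phage_contig_id, phage_taxa),
    host = node(spacer_hosts$host_contig_id[mi], host_taxa),
    stringsAsFactors = FALSE)
  keys <- c("phage", "host")
  for (extra in c("sample_id", "subject_id"))
    if (extra %in% names(spacer_hosts)) {
      edges[[extra]] <- spacer_hosts[[extra]][mi]
      keys <- c(keys, extra)
    }
  agg <- aggregate(list(support = rep(1L, nrow(edges))), edges[keys], sum)
  agg[order(agg$phage, agg$host), , drop = FALSE]
}
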