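#' Configuration for the random-forest phage classifier
#'
#' Defaults follow the published model: 1500 trees, 7 candidate features
#' per split, and a training set built from all phage contigs, all
#' ambiguous contigs (as negatives) and 3000 confident non-phage contigs
#' sampled from those with relative abundance at or above the median of
#' the non-phage contigs.
#'
#' @param n_trees number of trees (`ntree`).
#' @param candidate_features_per_split features tried per split (`mtry`),
#'   in \[1, 10\].
#' @param probability_threshold phage call threshold on the ensemble vote
#'   fraction, in (0, 1).
#' @param n_nonphage_sample number of confident non-phage contigs drawn
#'   into each training set.
#' @param nonphage_abundance_percentile abundance percentile (over
#'   confident non-phage contigs) below which contigs are ineligible for
#'   the negative sample.
#' @param ambiguous_in_training include ambiguous contigs in the training
#'   set as negatives (default) or drop them from training entirely.
#' @param rng_seed seed used for negative sampling and tree growing.
#' @return a list of class `phage_rf_config`.
#' @export
phage_rf_config <- function(n_trees = 1500L,
                            candidate_features_per_split = 7L,
                            probability_threshold = 0.5,
                            n_nonphage_sample = 3000L,
                            nonphage_abundance_percentile = 0.50,
                            ambiguous_in_training = TRUE,
                            rng_seed = 1L) {
  stopifnot(candidate_features_per_split >= 1L,
            candidate_features_per_split <= 10L,
            probability_threshold > 0, probability_threshold < 1,
            n_trees >= 1L, n_nonphage_sample >= 1L,
            nonphage_abundance_percentile >= 0,
            nonphage_abundance_percentile <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 candidate_features_per_split =
                   as.integer(candidate_features_per_split),
                 probability_threshold = probability_threshold,
                 n_nonphage_sample = as.integer(n_nonphage_sample),
                 nonphage_abundance_percentile =
                   nonphage_abundance_percentile,
                 ambiguous_in_training = isTRUE(ambiguous_in_training),
                 rng_seed = as.integer(rng_seed)),
            class = "phage_rf_config")
}

#' Build an imbalance-aware training set
#'
#' The phage class is rare (about 2% of contigs), so training uses all
#' phage contigs, all ambiguous contigs, and a seeded uniform sample of
#' `n_nonphage_sample` confident non-phage contigs restricted to those
#' whose relative abundance is at or above the
#' `nonphage_abundance_percentile` quantile of the confident non-phage
#' abundances (the "top 50th percentile" rule by default). If fewer
#' eligible contigs exist than requested, all are taken with a warning.
#'
#' @param features feature data.frame from [extract_features()].
#' @param labels labelling data.frame from [assign_labels()] (or any
#'   data.frame with `contig_id` and `label`).
#' @param abundances numeric vector of relative abundances parallel to
#'   `features` rows (or a mapping data.frame with `contig_id` and
#'   `relative_abundance`).
#' @param config a [phage_rf_config()].
#' @return `features` rows selected for training, with columns `label`
#'   (`"phage"`/`"non_phage"`) and `truth_category` (the original
#'   three-way label) appended.
#' @export
build_training_set <- function(features, labels, abundances,
                               config = phage_rf_config()) {
  lab <- labels$label[match(features$contig_id, labels$contig_id)]
  if (anyNA(lab))
    stop("missing label for contig: ",
         features$contig_id[is.na(lab)][1L], call. = FALSE)
  ab <- .resolve_abundances(abundances, features$contig_id)
  if (!any(lab == "phage"))
    stop("no phage contigs in the labelled set; model untrainable",
         call. = FALSE)
  pos <- which(lab == "phage")
  amb <- if (config$ambiguous_in_training) which(lab == "ambiguous")
         else integer()
  np <- which(lab == "non_phage")
  thr <- quantile(ab[np], probs = config$nonphage_abundance_percentile,
                  names = FALSE, type = 7)
  eligible <- np[ab[np] >= thr]
  n_take <- min(config$n_nonphage_sample, length(eligible))
  if (n_take < config$n_nonphage_sample)
    warning("only ", length(eligible), " eligible non-phage contigs; ",
            "requested ", config$n_nonphage_sample, call. = FALSE)
  neg_sample <- .with_seed(config$rng_seed, {
    if (n_take > 0L) sample(eligible, n_take) else integer()
  })
  idx <- c(pos, amb, neg_sample)
  out <- features[idx, , drop = FALSE]
  out$truth_category <- lab[idx]
  out$label <- ifelse(lab[idx] == "phage", "phage", "non_phage")
  rownames(out) <- NULL
  out
}

.resolve_abundances <- function(abundances, contig_ids) {
  if (is.data.frame(abundances)) {
    ab <- abundances$relative_abundance[match(contig_ids,
                                              abundances$contig_id)]
  } else ab <- abundances
  if (length(ab) != length(contig_ids) || anyNA(ab))
    stop("relative abundance missing for some contigs", call. = FALSE)
  ab
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Fit the random-forest phage-contig model
#'
#' Fits a random forest (bootstrap-resampled, fully grown trees;
#' `candidate_features_per_split` features tried at each split) to a
#' training set of 10-feature contig vectors. The returned object is a
#' classed model with `print`, `summary` and `predict` methods.
#'
#' @param training data.frame from [build_training_set()], or any
#'   data.frame holding the 10 feature columns and a `label` column with
#'   both `"phage"` and `"non_phage"` present.
#' @param config a [phage_rf_config()].
#' @return an object of class `phage_rf`.
#' @export
phage_rf <- function(training, config = phage_rf_config()) {
  fcols <- .feature_columns()
  missing_cols <- setdiff(c(fcols, "label"), names(training))
  if (length(missing_cols))
    stop("training set lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  y <- factor(training$label, levels = c("non_phage", "phage"))
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  x <- training[, fcols]
  if (all(vapply(x, function(col) length(unique(col)) == 1L, TRUE)))
    stop("all features are constant; no split is possible", call. = FALSE)
  fit <- .with_seed(config$rng_seed,
    randomForest::randomForest(
      x = x, y = y, ntree = config$n_trees,
      mtry = config$candidate_features_per_split))
  structure(list(forest = fit, config = config,
                 n_training = nrow(training),
                 class_counts = table(y)),
            class = "phage_rf")
}

#' @export
print.phage_rf <- function(x, ...) {
  cat("Random-forest phage-contig classifier\n")
  cat(sprintf("  trees: %d, features per split: %d\n",
              x$config$n_trees, x$config$candidate_features_per_split))
  cat(sprintf("  training contigs: %d (phage %d, non-phage %d)\n",
              x$n_training, x$class_counts[["phage"]],
              x$class_counts[["non_phage"]]))
  cat(sprintf("  call threshold: %.2f\n", x$config$probability_threshold))
  invisible(x)
}

#' @export
summary.phage_rf <- function(object, ...) {
  print(object)
  cat("\nOut-of-bag confusion (training labels):\n")
  print(object$forest$confusion)
  invisible(object)
}

#' Predict phage probability for contig feature vectors
#'
#' @param object a fitted [phage_rf()] model.
#' @param newdata feature data.frame (10 feature columns; a `contig_id`
#'   column is carried through if present).
#' @param ... unused.
#' @return data.frame with `contig_id`, `phage_probability` (ensemble
#'   vote fraction) and `call` (`"phage"` iff the probability is at or
#'   above the configured threshold).
#' @export
predict.phage_rf <- function(object, newdata, ...) {
  prob <- predict(object$forest, newdata[, .feature_columns()],
                  type = "prob")[, "phage"]
  data.frame(
    contig_id = if ("contig_id" %in% names(newdata)) newdata$contig_id
                else rownames(newdata),
    phage_probability = as.numeric(prob),
    call = ifelse(prob >= object$config$probability_threshold,
                  "phage", "non_phage"),
    stringsAsFactors = FALSE)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject in turn, pools all other subjects, builds the
#' imbalance-aware training set (negatives redrawn per fold with a
#' fold-specific seed derived from `config$rng_seed`), fits the forest,
#' predicts the held-out subject's contigs and evaluates under both
#' weighting schemes. Holding out whole subjects prevents within-subject
#' leakage between longitudinal samples.
#'
#' @param features feature data.frame with a `subject_id` column (or
#'   supply `subjects`).
#' @param labels labelling data.frame (`contig_id`, `label`).
#' @param abundances relative abundances (vector parallel to `features`,
#'   or data.frame with `contig_id`, `relative_abundance`).
#' @param config a [phage_rf_config()].
#' @param subjects optional character vector of subject ids parallel to
#'   `features` rows, overriding `features$subject_id`.
#' @return list with `per_subject` (named list of lists holding the
#'   `count` and `abundance` reports plus predictions), `aggregate_count`
#'   and `aggregate_abundance` (mean/sd tables from
#'   [aggregate_reports()]).
#' @export
cross_validate_by_subject <- function(features, labels, abundances,
                                      config = phage_rf_config(),
                                      subjects = NULL) {
  subj <- if (!is.null(subjects)) subjects else features$subject_id
  if (is.null(subj)) stop("subject ids required", call. = FALSE)
  ids <- unique(subj)
  if (length(ids) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  ab <- .resolve_abundances(abundances, features$contig_id)
  lab <- labels$label[match(features$contig_id, labels$contig_id)]
  per_subject <- list()
  for (k in seq_along(ids)) {
    test_idx <- subj == ids[k]
    if (!any(test_idx)) { warning("subject ", ids[k], " has no contigs");
      next }
    fold_cfg <- config
    fold_cfg$rng_seed <- config$rng_seed + k
    train_feat <- features[!test_idx, , drop = FALSE]
    ts <- build_training_set(train_feat, labels, ab[!test_idx], fold_cfg)
    model <- phage_rf(ts, fold_cfg)
    pred <- predict(model, features[test_idx, , drop = FALSE])
    per_subject[[ids[k]]] <- list(
      predictions = pred,
      count = evaluate_predictions(pred$call, lab[test_idx],
                                   weighting = "count"),
      abundance = evaluate_predictions(pred$call, lab[test_idx],
                                       ab[test_idx], "abundance"))
  }
  list(per_subject = per_subject,
       aggregate_count = aggregate_reports(
         lapply(per_subject, `[[`, "count")),
       aggregate_abundance = aggregate_reports(
         lapply(per_subject, `[[`, "abundance")))
}

#' Rule-based viral contig call
#'
#' Annotation-threshold baseline: a contig is called viral if any of
#' three conditions holds: (1) at least 5 viral-protein-family hits AND
#' < 20% of genes KO-annotated AND <= 40% Pfam-annotated AND > 10% of
#' genes viral-protein-family-annotated; (2) the viral-protein-family
#' count is >= the Pfam count; (3) >= 60% of genes are
#' viral-protein-family-annotated.
#'
#' @param n_genes,n_viral_family,n_ko,n_pfam per-contig counts (vectors
#'   recycle to a common length).
#' @return data.frame with `viral` (logical) and `condition_fired`
#'   (integer 1--3, or NA when non-viral). When several conditions hold
#'   the lowest-numbered one is reported.
#' @export
rule_based_viral <- function(n_genes, n_viral_family, n_ko, n_pfam) {
  n <- max(length(n_genes), length(n_viral_family), length(n_ko),
           length(n_pfam))
  g <- rep_len(n_genes, n); v <- rep_len(n_viral_family, n)
  k <- rep_len(n_ko, n); p <- rep_len(n_pfam, n)
  pv <- ifelse(g > 0, v / g, 0)
  pk <- ifelse(g > 0, k / g, 0)
  pp <- ifelse(g > 0, p / g, 0)
  c1 <- v >= 5 & pk < 0.20 & pp <= 0.40 & pv > 0.10
  c2 <- v >= p
  c3 <- pv >= 0.60
  fired <- ifelse(c1, 1L, ifelse(c2, 2L, ifelse(c3, 3L, NA_integer_)))
  data.frame(viral = c1 | c2 | c3, condition_fired = fired)
}
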