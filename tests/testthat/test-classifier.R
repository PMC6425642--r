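test_that("training sets follow the imbalance-aware construction", {
  set.seed(12)
  n <- 270
  lab <- rep(c("phage", "ambiguous", "non_phage"), c(50, 20, 200))
  feats <- make_separable_features(50, 220)[seq_len(n), ]
  feats$label <- NULL
  labels <- data.frame(contig_id = feats$contig_id, label = lab)
  ab <- seq_len(n) / n  # distinct abundances; non-phage occupy 71..270
  cfg <- phage_rf_config(n_nonphage_sample = 30L, rng_seed = 7L)
  ts <- build_training_set(feats, labels, ab, cfg)
  # 100 non-phage contigs sit at or above the median non-phage abundance
  np_ab <- ab[lab == "non_phage"]
  eligible <- sum(np_ab >= quantile(np_ab, 0.5))
  expect_equal(eligible, 100L)
  expect_equal(nrow(ts), 50L + 20L + 30L)
  expect_equal(sum(ts$label == "phage"), 50L)
  expect_equal(sum(ts$truth_category == "ambiguous"), 20L)
  expect_true(all(ts$label[ts$truth_category == "ambiguous"] == "non_phage"))
  # sampled negatives really come from the eligible top half
  neg <- ts$contig_id[ts$truth_category == "non_phage"]
  expect_true(all(ab[match(neg, feats$contig_id)] >= quantile(np_ab, 0.5)))

  ts2 <- build_training_set(feats, labels, ab, cfg)
  expect_identical(ts, ts2)  # same seed, same sample

  expect_warning(
    big <- build_training_set(feats, labels, ab,
                              phage_rf_config(n_nonphage_sample = 3000L)),
    "eligible")
  expect_equal(sum(big$truth_category == "non_phage"), eligible)

  labels$label[labels$label == "phage"] <- "non_phage"
  expect_error(build_training_set(feats, labels, ab, cfg), "no phage")
})

test_that("ambiguous contigs can be excluded from training", {
  set.seed(12)
  feats <- make_separable_features(10, 40)
  feats$label <- NULL
  labels <- data.frame(contig_id = feats$contig_id,
                       label = rep(c("phage", "ambiguous", "non_phage"),
                                   c(10, 10, 30)))
  cfg <- phage_rf_config(n_nonphage_sample = 10L,
                         ambiguous_in_training = FALSE)
  ts <- suppressWarnings(build_training_set(feats, labels,
                                            runif(50), cfg))
  expect_false(any(ts$truth_category == "ambiguous"))
})

test_that("the forest separates a separable fixture and is deterministic", {
  set.seed(42)
  train <- make_separable_features(40, 120, sep = 8)
  cfg <- phage_rf_config(n_trees = 300L, rng_seed = 42L)
  fit <- phage_rf(train, cfg)
  pred <- predict(fit, train)
  expect_equal(mean(pred$call == train$label), 1.0)
  expect_true(all(pred$phage_probability >= 0 & pred$phage_probability <= 1))

  fit2 <- phage_rf(train, cfg)
  expect_identical(predict(fit2, train), pred)

  one_class <- train[train$label == "phage", ]
  expect_error(phage_rf(one_class, cfg), "both classes")
})

test_that("conflicting labels on identical rows give intermediate votes", {
  set.seed(6)
  base <- make_separable_features(6, 6)
  dup <- base[rep(1L, 8L), ]        # one row duplicated with both labels
  dup$label <- rep(c("phage", "non_phage"), 4L)
  dup$contig_id <- paste0("dup", 1:8)
  train <- rbind(base, dup)
  fit <- phage_rf(train, phage_rf_config(n_trees = 300L, rng_seed = 3L))
  p <- predict(fit, dup[1, ])$phage_probability
  expect_gt(p, 0); expect_lt(p, 1)

  # fully constant features are untrainable and rejected outright
  flat <- base[rep(1L, 4L), ]
  flat$label <- rep(c("phage", "non_phage"), 2L)
  expect_error(phage_rf(flat, phage_rf_config(n_trees = 50L)), "constant")
})

test_that("leave-one-subject-out bookkeeping is sound", {
  set.seed(21)
  feats <- do.call(rbind, lapply(1:3, function(s)
    make_separable_features(8, 60, subject = paste0("subj", s),
                            prefix = paste0("s", s, "c"))))
  labels <- data.frame(contig_id = feats$contig_id,
                       label = ifelse(feats$label == "phage",
                                      "phage", "non_phage"))
  feats$label <- NULL
  cfg <- phage_rf_config(n_trees = 200L, n_nonphage_sample = 30L,
                         rng_seed = 11L)
  cv <- suppressWarnings(
    cross_validate_by_subject(feats, labels, runif(nrow(feats), 0.001, 1),
                              cfg))
  expect_named(cv$per_subject, paste0("subj", 1:3))
  sens <- vapply(cv$per_subject, function(s) s$count$sensitivity, 1)
  agg <- cv$aggregate_count
  expect_equal(agg$mean[agg$metric == "sensitivity"], mean(sens))
  expect_equal(agg$sd[agg$metric == "sensitivity"], sd(sens))

  one <- feats[feats$subject_id == "subj1", ]
  expect_error(cross_validate_by_subject(one, labels, runif(nrow(one)),
                                         cfg), "at least 2 subjects")
})

test_that("rule-based calls reproduce the three printed conditions", {
  # condition 1: >=5 viral hits, <20% KO, <=40% Pfam, >10% viral
  expect_true(rule_based_viral(20, 6, 3, 8)$viral)
  expect_equal(rule_based_viral(20, 6, 3, 8)$condition_fired, 1L)
  # condition 2: viral count >= Pfam count
  r2 <- rule_based_viral(20, 5, 10, 4)
  expect_true(r2$viral); expect_equal(r2$condition_fired, 2L)
  # condition 3: >= 60% viral genes
  r3 <- rule_based_viral(10, 6, 5, 7)
  expect_true(r3$viral); expect_equal(r3$condition_fired, 3L)
  # none: 12% viral, 4 hits, 25% KO, Pfam above viral
  r0 <- rule_based_viral(33, 4, 8, 12)
  expect_false(r0$viral); expect_true(is.na(r0$condition_fired))
})

test_that("rule-based calls agree with an independent truth table", {
  set.seed(17)
  g <- sample(1:40, 800, replace = TRUE)
  v <- vapply(g, function(x) sample(0:x, 1), 1L)
  k <- vapply(g, function(x) sample(0:x, 1), 1L)
  p <- vapply(g, function(x) sample(0:x, 1), 1L)
  got <- rule_based_viral(g, v, k, p)$viral
  want <- mapply(brute_rule_viral, g, v, k, p)
  expect_equal(got, unname(want))
})
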