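# ROC sweep, optimal cut-point, folds, grid search, ensemble, ablation.

test_that("geometric mean reproduces printed sensitivity/specificity trade-offs", {
  # published (Se, Sp, G) rows, G printed to 4 decimals
  rows <- rbind(c(0.9846, 0.9782, 0.9814),
                c(0.9918, 0.9842, 0.9880),
                c(0.9987, 0.9985, 0.9986),
                c(0.9763, 0.9342, 0.9550),
                c(0.9648, 0.9436, 0.9541))
  for (i in seq_len(nrow(rows)))
    expect_equal(round(geometric_mean(rows[i, 1], rows[i, 2]), 4), rows[i, 3])
  expect_equal(geometric_mean(1, 0.49), 0.7)
  expect_error(geometric_mean(1.2, 0.5), ">= 0")
})

test_that("perfectly separated scores give AUC 1 and G* 1", {
  set.seed(17)
  adl <- runif(40, 0, 1); fall <- runif(30, 2, 3)
  r <- sweep_roc(adl, fall)
  expect_equal(r$auc, 1)
  expect_equal(r$g_opt, 1)
  expect_equal(r$se_opt, 1)
  expect_equal(r$sp_opt, 1)
  # the optimal cut sits in the gap between the two classes
  expect_true(r$threshold_opt > max(adl) && r$threshold_opt <= min(fall))
})

test_that("identical score distributions give chance-level AUC", {
  set.seed(19)
  aucs <- replicate(200, {
    s <- rnorm(40)
    sweep_roc(sample(s), sample(s))$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

# Exhaustive-threshold ROC: every midpoint between consecutive distinct
# pooled scores (plus outer sentinels) is a threshold.
brute_roc_auc <- function(adl, fall) {
  u <- sort(unique(c(adl, fall)))
  thr <- c(u[1] - 1, u, u[length(u)] + 1)
  se <- vapply(thr, function(t) mean(fall >= t), 0)
  sp <- vapply(thr, function(t) mean(adl < t), 0)
  fpr <- 1 - sp
  ord <- order(fpr, se)
  sum(diff(fpr[ord]) * (se[ord][-1] + se[ord][-length(se)]) / 2)
}

test_that("swept AUC agrees with the exhaustive-threshold oracle", {
  set.seed(23)
  for (i in 1:20) {
    adl <- rnorm(sample(20:150, 1))
    fall <- rnorm(sample(10:50, 1), mean = runif(1, 0, 2))
    r <- sweep_roc(adl, fall)
    expect_lt(abs(r$auc - brute_roc_auc(adl, fall)), 1e-3)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(
        pROC::roc(response = c(rep(0, length(adl)), rep(1, length(fall))),
                  predictor = c(adl, fall), quiet = TRUE,
                  direction = "<")))
      expect_lt(abs(r$auc - ref), 1e-3)
    }
  }
})

test_that("ROC curve is monotone along the threshold grid and G* is consistent", {
  set.seed(29)
  r <- sweep_roc(rnorm(80), rnorm(40, mean = 1))
  expect_true(all(diff(r$thresholds) > 0))
  expect_true(all(diff(r$se) <= 1e-12))
  expect_true(all(diff(r$sp) >= -1e-12))
  expect_equal(r$g_opt, sqrt(r$se_opt * r$sp_opt), tolerance = 1e-12)
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_equal(length(r$thresholds), 2500L)
  expect_error(sweep_roc(numeric(0), rnorm(5)), "non-empty")
})

test_that("folds are stratified, disjoint, covering, and fall-free in training", {
  hdr <- data.frame(
    trace_id = c(sprintf("a%03d", 1:100), sprintf("f%02d", 1:10)),
    path = "x.csv",
    label = c(rep("ADL", 100), rep("FALL", 10)),
    activity_type = c(rep(sprintf("type%02d", 1:10), each = 10),
                      rep("fall", 10)),
    category = c(rep(c("basic", "standard"), 50), rep("none", 10)),
    subject_id = "s1", fs = 100, unit = "g", stringsAsFactors = FALSE)
  split <- make_folds(hdr, k = 5, seed = 1)
  test_ids <- unlist(lapply(split$folds, `[[`, "test_adl"))
  expect_equal(sort(test_ids), sort(hdr$trace_id[hdr$label == "ADL"]))
  expect_equal(anyDuplicated(test_ids), 0L)
  for (fold in split$folds) {
    expect_length(fold$test_adl, 20L)
    expect_false(any(grepl("^f", fold$train_adl)))
    expect_equal(sort(fold$test_fall), sort(sprintf("f%02d", 1:10)))
    # fair stratification: every activity type in every partition
    types <- hdr$activity_type[match(fold$test_adl, hdr$trace_id)]
    expect_equal(sort(unique(types)), sprintf("type%02d", 1:10))
    expect_setequal(c(fold$train_adl, fold$test_adl),
                    hdr$trace_id[hdr$label == "ADL"])
  }
  split2 <- make_folds(hdr, k = 5, seed = 1)
  expect_identical(split, split2)
  split3 <- make_folds(hdr, k = 5, seed = 2)
  expect_false(identical(split$folds, split3$folds))
  expect_error(make_folds(hdr, k = 1), "at least 2")
})

test_that("grid search reports internally consistent winners", {
  d <- small_dataset()
  rep <- suppressWarnings(
    run_fair_experiment(d$manifest, "ocknn", feature_sets = list("BCDFGIK"),
                        seed = 1, feats = d$feats))
  w <- rep$winner
  expect_equal(w$mean_g, mean(w$g), tolerance = 1e-12)
  expect_equal(w$sd_g, sd(w$g), tolerance = 1e-12)
  expect_length(w$g, 5L)
  expect_length(w$thresholds, 5L)
  expect_equal(w$mean_g, max(rep$combinations$g))
  expect_true(all(rep$combinations$g >= 0 & rep$combinations$g <= 1))
})

test_that("indistinguishable classes yield chance-level separability", {
  # falls whose feature vectors exactly duplicate ADL vectors
  set.seed(31)
  n <- 40
  feats <- data.frame(trace_id = c(sprintf("a%02d", 1:n),
                                   sprintf("f%02d", 1:n)),
                      label = rep(c("ADL", "FALL"), each = n),
                      category = rep(c("basic", "none"), each = n),
                      stringsAsFactors = FALSE)
  base <- matrix(rnorm(n * 3), n, 3)
  feats[, c("B", "C", "G")] <- rbind(base, base)
  man <- feats[, 1:3]
  man$path <- "x.csv"; man$activity_type <- rep(c("t1", "fall"), each = n)
  man$subject_id <- "s1"; man$fs <- 100; man$unit <- "g"
  rep <- run_fair_experiment(man, "ocknn",
                             grid = data.frame(metric = "euclidean", k = 5,
                                               stringsAsFactors = FALSE),
                             feature_sets = list(c("B", "C", "G")),
                             seed = 1, feats = feats)
  expect_lt(abs(rep$winner$mean_auc - 0.5), 0.12)
})

test_that("majority voting follows the two-of-three rule", {
  d <- small_dataset()
  rep <- suppressWarnings(
    run_fair_experiment(d$manifest, "ocknn", feature_sets = list("BCDFGIK"),
                        seed = 1, feats = d$feats))
  w <- rep$winner
  cfg <- list(kind = "ocknn", feature_set = w$feature_set, params = w$params,
              thresholds = w$thresholds)
  # three identical base learners: ensemble equals the single learner
  ens <- run_ensemble(d$manifest, list(cfg, cfg, cfg), seed = 1,
                      feats = d$feats)
  expect_equal(ens$se, w$se, tolerance = 1e-12)
  expect_equal(ens$sp, w$sp, tolerance = 1e-12)
  expect_equal(ens$g, sqrt(ens$se * ens$sp), tolerance = 1e-12)
  expect_error(run_ensemble(d$manifest, list(cfg, cfg), seed = 1),
               "exactly 3")
})

test_that("ensemble of decorrelated learners is not worse than its weakest member", {
  d <- small_dataset()
  for (seed in c(1, 2, 3)) {
    reps <- lapply(c("ocknn", "gmm", "ppnn"), function(kind)
      suppressWarnings(run_fair_experiment(
        d$manifest, kind, feature_sets = list("BCDFGIK"),
        seed = seed, feats = d$feats)))
    cfgs <- lapply(seq_along(reps), function(i) {
      w <- reps[[i]]$winner
      list(kind = c("ocknn", "gmm", "ppnn")[i], feature_set = w$feature_set,
           params = w$params, thresholds = w$thresholds)
    })
    ens <- run_ensemble(d$manifest, cfgs, seed = seed, feats = d$feats)
    base_g <- vapply(reps, function(r) r$winner$mean_g, 0)
    expect_gte(ens$mean_g, min(base_g) - 0.05)
  }
})

test_that("ablation uses the fair threshold and reports exact Loss arithmetic", {
  d <- small_dataset()
  rep <- suppressWarnings(
    run_fair_experiment(d$manifest, "ocknn", feature_sets = list("BCDFGIK"),
                        seed = 1, feats = d$feats))
  w <- rep$winner
  cfg <- list(kind = "ocknn", feature_set = w$feature_set, params = w$params,
              thresholds = w$thresholds)
  ab <- run_ablation(d$manifest, cfg, g_fair = w$mean_g, seed = 1,
                     feats = d$feats)
  expect_setequal(ab$category, c("basic", "standard", "sporting"))
  expect_equal(ab$loss, ab$g - w$mean_g, tolerance = 1e-12)
  expect_equal(attr(ab, "threshold"), median(w$thresholds))
  expect_true(all(abs(ab$loss) <= 1))
  expect_equal(ab$g, sqrt(ab$se * ab$sp), tolerance = 1e-12)
})

test_that("duplicated held-out category incurs (near) zero loss", {
  # the held-out category's vectors also exist inside a training category,
  # so nothing about it is novel at test time
  set.seed(37)
  n <- 30
  base <- matrix(rnorm(n * 3), n, 3)
  feats <- data.frame(
    trace_id = c(sprintf("b%02d", 1:n), sprintf("s%02d", 1:n),
                 sprintf("f%02d", 1:10)),
    label = c(rep("ADL", 2 * n), rep("FALL", 10)),
    category = c(rep("basic", n), rep("standard", n), rep("none", 10)),
    stringsAsFactors = FALSE)
  feats[, c("B", "C", "G")] <- rbind(base, base,
                                     matrix(rnorm(30), 10, 3) + 8)
  man <- feats[, 1:3]
  man$path <- "x.csv"
  man$activity_type <- rep(c("basic_t", "standard_t", "fall"), c(n, n, 10))
  man$subject_id <- "s1"; man$fs <- 100; man$unit <- "g"
  rep <- run_fair_experiment(man, "ocknn",
                             grid = data.frame(metric = "euclidean", k = 5,
                                               stringsAsFactors = FALSE),
                             feature_sets = list(c("B", "C", "G")),
                             seed = 1, feats = feats)
  w <- rep$winner
  ab <- run_ablation(man, list(kind = "ocknn", feature_set = w$feature_set,
                               params = w$params, thresholds = w$thresholds),
                     g_fair = w$mean_g, seed = 1, feats = feats)
  expect_lt(max(abs(ab$loss)), 0.1)
})
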