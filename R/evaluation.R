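# Experimental protocols: ROC threshold sweep with geometric-mean optimal
# cut-point, stratified 5-fold cross-validation over ADLs, hyperparameter
# grid search, top-3 majority-voting ensemble, and the
# leave-one-activity-category-out ablation.

#' Geometric mean of sensitivity and specificity
#'
#' The study's global trade-off metric: \eqn{G = \sqrt{Se \cdot Sp}}. It is
#' also the criterion that selects the optimal cut-point on the ROC.
#'
#' @param se,sp Proportions in \[0, 1\].
#' @return \eqn{\sqrt{se \cdot sp}}.
#' @export
geometric_mean <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  sqrt(se * sp)
}

#' Sweep detection thresholds and build a ROC
#'
#' Evaluates 2500 linearly spaced thresholds spanning the pooled score range
#' (plus one threshold beyond the maximum so the ROC reaches (0,0); the
#' minimum threshold itself attains Se = 1). The decision rule is
#' score >= threshold => fall. Sensitivity is the fraction of fall scores at
#' or above the threshold; specificity the fraction of ADL scores below it.
#' AUC is computed by the trapezoidal rule over (1 - Sp, Se); the optimal
#' cut-point maximizes \eqn{\sqrt{Se \cdot Sp}}, smallest threshold on ties.
#'
#' @param scores_adl Anomaly scores of the test ADLs.
#' @param scores_fall Anomaly scores of the test falls.
#' @param n_thresholds Number of thresholds in the sweep.
#' @return A list of class `roc_result`: `thresholds`, `se`, `sp`, `auc`,
#'   `threshold_opt`, `se_opt`, `sp_opt`, `g_opt`.
#' @export
sweep_roc <- function(scores_adl, scores_fall, n_thresholds = 2500L) {
  if (!length(scores_adl) || !length(scores_fall))
    stop("both score vectors must be non-empty")
  if (!all(is.finite(c(scores_adl, scores_fall))))
    stop("scores must be finite")
  pooled <- c(scores_adl, scores_fall)
  lo <- min(pooled); hi <- max(pooled)
  if (hi <= lo) hi <- lo + 1e-9
  thr <- seq(lo, hi, length.out = n_thresholds)
  eps <- (hi - lo) * 1e-9
  thr_ext <- c(thr, hi + eps)  # extra point beyond max: Se = 0, Sp = 1

  se <- vapply(thr_ext, function(tau) mean(scores_fall >= tau), 0)
  sp <- vapply(thr_ext, function(tau) mean(scores_adl < tau), 0)

  fpr <- 1 - sp
  ord <- order(fpr, se)
  auc <- sum(diff(fpr[ord]) * (se[ord][-1L] + se[ord][-length(se)]) / 2)
  auc <- min(max(auc, 0), 1)

  g <- sqrt(se * sp)
  best <- which.max(g)  # ties: first index = smallest threshold
  structure(list(thresholds = thr, se = se[seq_len(n_thresholds)],
                 sp = sp[seq_len(n_thresholds)], auc = auc,
                 threshold_opt = thr_ext[best], se_opt = se[best],
                 sp_opt = sp[best], g_opt = g[best]),
            class = "roc_result")
}

#' Stratified cross-validation folds over the ADLs
#'
#' ADL traces are partitioned into k disjoint subsets, stratified by
#' activity type (each type is shuffled with the given seed, then dealt
#' round-robin), so in "fair" mode every type with at least k traces is
#' represented in every partition. Falls never enter a training set: each
#' fold trains on the other k-1 ADL partitions and tests on the reserved
#' ADL partition plus all falls.
#'
#' @param manifest A `fall_manifest`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the stratified shuffle.
#' @return A list of class `fold_split`: `folds` (each with `train_adl`,
#'   `test_adl`, `test_fall` trace-id vectors), `k`, `seed`.
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  adl <- manifest[manifest$label == "ADL", ]
  falls <- manifest$trace_id[manifest$label == "FALL"]
  if (nrow(adl) < k) stop("need at least k ADL traces")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  assignment <- integer(nrow(adl))
  names(assignment) <- adl$trace_id
  for (type in sort(unique(adl$activity_type))) {
    ids <- adl$trace_id[adl$activity_type == type]
    ids <- sample(ids)
    assignment[ids] <- (seq_along(ids) - 1L) %% k + 1L
  }
  folds <- lapply(seq_len(k), function(f) {
    list(train_adl = names(assignment)[assignment != f],
         test_adl = names(assignment)[assignment == f],
         test_fall = falls)
  })
  structure(list(folds = folds, k = k, seed = seed), class = "fold_split")
}

# Evaluate one (feature set, hyperparameters) combination across folds.
# feats: full feature data.frame from feature_matrix(); spec: feature IDs.
eval_combination <- function(feats, split, kind, params, spec, seed) {
  per_fold <- lapply(split$folds, function(fold) {
    train <- feats[match(fold$train_adl, feats$trace_id), spec, drop = FALSE]
    test_adl <- feats[match(fold$test_adl, feats$trace_id), spec,
                      drop = FALSE]
    test_fall <- feats[match(fold$test_fall, feats$trace_id), spec,
                       drop = FALSE]
    nz <- fit_normalizer(train)
    model <- tryCatch(occ_train(kind, apply_normalizer(nz, train),
                                params, seed = seed),
                      error = function(e) e)
    if (inherits(model, "error")) return(model)
    roc <- sweep_roc(occ_score(model, apply_normalizer(nz, test_adl)),
                     occ_score(model, apply_normalizer(nz, test_fall)))
    list(auc = roc$auc, se = roc$se_opt, sp = roc$sp_opt, g = roc$g_opt,
         threshold = roc$threshold_opt)
  })
  failed <- vapply(per_fold, inherits, TRUE, what = "error")
  if (any(failed))
    return(list(ok = FALSE,
                message = conditionMessage(per_fold[[which(failed)[1L]]])))
  list(ok = TRUE,
       auc = vapply(per_fold, `[[`, 0, "auc"),
       se = vapply(per_fold, `[[`, 0, "se"),
       sp = vapply(per_fold, `[[`, 0, "sp"),
       g = vapply(per_fold, `[[`, 0, "g"),
       thresholds = vapply(per_fold, `[[`, 0, "threshold"))
}

#' Grid-search a model kind under fair cross-validation
#'
#' For every hyperparameter x feature-set combination: per fold, the
#' normalizer is fitted on the training ADLs only, the model trained on
#' them, and the reserved ADLs plus all falls scored and swept into a ROC.
#' The winning combination maximizes the mean per-fold geometric mean
#' (ties: higher mean AUC, then grid order).
#'
#' @param manifest A `fall_manifest`.
#' @param kind Model kind (see [hyper_grid()]).
#' @param grid Hyperparameter grid (defaults to [hyper_grid()] for `kind`).
#' @param feature_sets List of feature-set specifications to try.
#' @param k Number of folds.
#' @param seed Integer seed (folds and stochastic trainers).
#' @param feats Optional precomputed [feature_matrix()] with all 12 features.
#' @return A list of class `eval_report`: `combinations` (per-combination
#'   summary data.frame), `winner` (list with params, feature set, per-fold
#'   metrics and thresholds), `kind`, `folds`.
#' @export
run_fair_experiment <- function(manifest, kind, grid = hyper_grid(kind),
                                feature_sets = list("BCDFGIK",
                                                    "ABCDEFGHIJKL"),
                                k = 5L, seed = 1L, feats = NULL) {
  if (!any(manifest$label == "ADL") || !any(manifest$label == "FALL"))
    stop("manifest must contain both ADL and FALL traces")
  if (is.null(feats)) feats <- feature_matrix(manifest)
  split <- make_folds(manifest, k = k, seed = seed)

  rows <- list(); details <- list()
  for (fi in seq_along(feature_sets)) {
    spec <- feature_set(feature_sets[[fi]])
    for (gi in seq_len(nrow(grid))) {
      params <- as.list(grid[gi, , drop = FALSE])
      res <- eval_combination(feats, split, kind, params, spec, seed)
      label <- paste0(paste(spec, collapse = ""), "/",
                      paste(names(params), unlist(params), sep = "=",
                            collapse = ","))
      if (!res$ok) {
        warning("combination ", label, " disqualified: ", res$message)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        features = paste(spec, collapse = ""),
        params = paste(names(params), unlist(params), sep = "=",
                       collapse = ","),
        auc = mean(res$auc), se = mean(res$se), sp = mean(res$sp),
        g = mean(res$g), g_sd = stats::sd(res$g),
        stringsAsFactors = FALSE)
      details[[length(details) + 1L]] <-
        list(spec = spec, params = params, fold_metrics = res)
    }
  }
  if (!length(rows)) stop("every combination failed to train")
  tab <- do.call(rbind, rows)
  best <- order(-tab$g, -tab$auc)[1L]
  win <- details[[best]]
  structure(list(
    kind = kind,
    combinations = tab,
    winner = list(feature_set = win$spec, params = win$params,
                  auc = win$fold_metrics$auc, se = win$fold_metrics$se,
                  sp = win$fold_metrics$sp, g = win$fold_metrics$g,
                  thresholds = win$fold_metrics$thresholds,
                  mean_auc = tab$auc[best], mean_se = tab$se[best],
                  mean_sp = tab$sp[best], mean_g = tab$g[best],
                  sd_g = tab$g_sd[best]),
    folds = split, seed = seed), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  w <- x$winner
  cat(sprintf("<eval_report %s> best %s (%s): AUC %.4f, Se %.4f, Sp %.4f, G %.4f +/- %.4f\n",
              x$kind, paste(w$feature_set, collapse = ""),
              paste(names(w$params), unlist(w$params), sep = "=",
                    collapse = ","),
              w$mean_auc, w$mean_se, w$mean_sp, w$mean_g, w$sd_g))
  invisible(x)
}

#' Majority-voting ensemble of the three best configurations
#'
#' Re-trains the three base learners on every fold's training ADLs; each
#' votes "fall" when its anomaly score reaches its own per-fold optimal
#' threshold, and the ensemble labels a trace a fall when at least two of
#' the three votes agree.
#'
#' @param manifest A `fall_manifest`.
#' @param top3 List of exactly three configurations, each a list with
#'   `kind`, `feature_set`, `params`, and per-fold `thresholds` (as stored
#'   in an [run_fair_experiment()] winner).
#' @param k,seed Fold controls; must match the runs that produced the
#'   thresholds.
#' @param feats Optional precomputed [feature_matrix()].
#' @return A list of class `ensemble_report` with per-fold and mean
#'   `se`, `sp`, `g`.
#' @export
run_ensemble <- function(manifest, top3, k = 5L, seed = 1L, feats = NULL) {
  if (length(top3) != 3L)
    stop("the voting ensemble needs exactly 3 configurations")
  if (is.null(feats)) feats <- feature_matrix(manifest)
  split <- make_folds(manifest, k = k, seed = seed)

  per_fold <- lapply(seq_len(split$k), function(f) {
    fold <- split$folds[[f]]
    votes_adl <- matrix(FALSE, length(fold$test_adl), 3L)
    votes_fall <- matrix(FALSE, length(fold$test_fall), 3L)
    for (m in 1:3) {
      cfg <- top3[[m]]
      spec <- feature_set(cfg$feature_set)
      train <- feats[match(fold$train_adl, feats$trace_id), spec,
                     drop = FALSE]
      nz <- fit_normalizer(train)
      model <- occ_train(cfg$kind, apply_normalizer(nz, train), cfg$params,
                         seed = seed)
      tau <- cfg$thresholds[f]
      sa <- occ_score(model, apply_normalizer(
        nz, feats[match(fold$test_adl, feats$trace_id), spec, drop = FALSE]))
      sf <- occ_score(model, apply_normalizer(
        nz, feats[match(fold$test_fall, feats$trace_id), spec,
                  drop = FALSE]))
      votes_adl[, m] <- sa >= tau
      votes_fall[, m] <- sf >= tau
    }
    se <- mean(rowSums(votes_fall) >= 2L)
    sp <- mean(rowSums(votes_adl) < 2L)
    list(se = se, sp = sp, g = geometric_mean(se, sp))
  })
  se <- vapply(per_fold, `[[`, 0, "se")
  sp <- vapply(per_fold, `[[`, 0, "sp")
  g <- vapply(per_fold, `[[`, 0, "g")
  structure(list(se = se, sp = sp, g = g,
                 mean_se = mean(se), mean_sp = mean(sp), mean_g = mean(g),
                 sd_g = stats::sd(g), seed = seed),
            class = "ensemble_report")
}

#' Leave-one-activity-category-out ablation
#'
#' For each ADL intensity category present in the manifest, the model is
#' trained on the ADLs of the other categories (normalizer refitted on that
#' training set) and tested on all falls plus the held-out category's ADLs,
#' classifying with the fair-case threshold (median of the per-fold optimal
#' thresholds) rather than re-optimizing. `Loss` is the geometric mean under
#' ablation minus the fair-case geometric mean.
#'
#' @param manifest A `fall_manifest`.
#' @param config A configuration list (`kind`, `feature_set`, `params`,
#'   per-fold `thresholds`), e.g. an [run_fair_experiment()] winner plus its
#'   `kind`.
#' @param g_fair Fair-case mean geometric mean the Loss is measured against.
#' @param seed Integer seed for stochastic trainers.
#' @param feats Optional precomputed [feature_matrix()].
#' @return A `data.frame` of class `ablation_report`: one row per held-out
#'   category with `se`, `sp`, `g`, `loss`.
#' @export
run_ablation <- function(manifest, config, g_fair, seed = 1L, feats = NULL) {
  if (is.null(feats)) feats <- feature_matrix(manifest)
  spec <- feature_set(config$feature_set)
  tau <- stats::median(config$thresholds)
  cats <- intersect(c("basic", "standard", "sporting"),
                    unique(manifest$category[manifest$label == "ADL"]))
  if (length(cats) < 2L)
    stop("ablation needs at least 2 non-empty ADL categories")
  rows <- lapply(cats, function(held) {
    train_ids <- manifest$trace_id[manifest$label == "ADL" &
                                     manifest$category != held]
    test_adl <- manifest$trace_id[manifest$label == "ADL" &
                                    manifest$category == held]
    if (!length(test_adl)) {
      warning("held-out category ", held, " is empty; skipped")
      return(NULL)
    }
    test_fall <- manifest$trace_id[manifest$label == "FALL"]
    train <- feats[match(train_ids, feats$trace_id), spec, drop = FALSE]
    nz <- fit_normalizer(train)
    model <- occ_train(config$kind, apply_normalizer(nz, train),
                       config$params, seed = seed)
    sa <- occ_score(model, apply_normalizer(
      nz, feats[match(test_adl, feats$trace_id), spec, drop = FALSE]))
    sf <- occ_score(model, apply_normalizer(
      nz, feats[match(test_fall, feats$trace_id), spec, drop = FALSE]))
    se <- mean(sf >= tau)
    sp <- mean(sa < tau)
    g <- geometric_mean(se, sp)
    data.frame(category = held, se = se, sp = sp, g = g,
               loss = g - g_fair, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- tau
  attr(out, "g_fair") <- g_fair
  class(out) <- c("ablation_report", "data.frame")
  out
}
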