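# Assay-discrimination layer: correlation-threshold feature selection and
# SVM-RBF repeated cross-validated ROC / accuracy / sensitivity / specificity
# reporting.

numeric_feature_cols <- function(table, exclude = character(0)) {
  nm <- names(table)[vapply(table, is.numeric, logical(1))]
  setdiff(nm, exclude)
}

#' Rank-based AUC of a score vector
#'
#' Equals the Mann-Whitney U normalisation and the trapezoidal integral of
#' the ROC curve; ties contribute 1/2.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param positive Logical vector: `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Drop highly correlated features iteratively
#'
#' At each step the feature pair with the largest absolute Pearson
#' correlation is found; if it reaches `threshold`, the member with the
#' larger mean absolute correlation against all remaining features is
#' removed (ties broken by column order, keeping the earlier column). The
#' process repeats until every remaining pair correlates below the
#' threshold. Constant features have undefined correlations and are treated
#' as uncorrelated, with a warning. Column order is preserved.
#'
#' @param table `data.frame`; all numeric columns are treated as features,
#'   non-numeric columns pass through untouched.
#' @param threshold Absolute correlation threshold in (0, 1).
#' @return `data.frame` with the surviving columns.
#' @export
select_features_by_correlation <- function(table, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  feats <- numeric_feature_cols(table)
  if (length(feats) < 2L) stop("need at least two numeric features")
  x <- as.matrix(table[feats])
  const <- apply(x, 2, sd) == 0
  if (any(const)) warning("constant feature(s) treated as uncorrelated: ",
                          paste(feats[const], collapse = ", "))
  cm <- suppressWarnings(abs(cor(x)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  keep <- seq_along(feats)
  while (length(keep) >= 2L) {
    sub <- cm[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx < threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    pair <- keep[hit]
    mean_r <- vapply(pair, function(j) mean(cm[j, setdiff(keep, j)]), numeric(1))
    drop_j <- if (mean_r[1] > mean_r[2]) pair[1]
              else if (mean_r[2] > mean_r[1]) pair[2]
              else max(pair)           # tie: keep the earlier column
    keep <- setdiff(keep, drop_j)
  }
  dropped <- feats[-keep]
  table[setdiff(names(table), dropped)]
}

fold_assignment <- function(y, folds) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

# z-score with training-fold statistics; constant columns left unscaled
zscore_fit <- function(xtr) {
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2, sd)
  sg[sg == 0] <- 1
  list(mu = mu, sg = sg)
}
zscore_apply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$sg, "/")

svm_scores <- function(xtr, ytr, xte, cost, gamma, positive) {
  fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  pr <- predict(fit, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv), "/")[[1]][1]
  score <- if (first == positive) dv[, 1] else -dv[, 1]
  list(score = score, pred = as.character(pr))
}

#' Repeated cross-validated SVM-RBF evaluation
#'
#' For each of `repeats` random stratified `folds`-fold partitions, an
#' SVM with radial-basis kernel is trained on 4/5 of the samples and scored
#' on the held-out fold. Features are z-scored with training-fold statistics
#' only. When the (cost, gamma) grid has more than one point, the grid point
#' is chosen inside each training split by an inner stratified
#' `inner_folds`-fold cross-validation maximising AUC, preventing test
#' leakage. Per repeat, held-out decision values are pooled into one AUC;
#' the report carries the mean and standard deviation over repeats, plus
#' accuracy, sensitivity (true-positive rate of `positive`) and specificity
#' from the pooled predicted labels. Deterministic under `seed`.
#'
#' @param table `data.frame` of features (all numeric columns are used).
#' @param labels Class labels (vector) or the name of a column of `table`.
#' @param positive Label of the positive class (sensitivity anchor).
#' @param folds,repeats Cross-validation layout.
#' @param c_grid,gamma_grid SVM hyperparameter grids; defaults are 21
#'   log-spaced cost values in 1e-5..1e5 and 10 log-spaced gamma values in
#'   1e-3..10.
#' @param inner_folds Folds of the inner model-selection loop.
#' @param seed Integer seed.
#' @return An object of class `classifier_report`.
#' @export
evaluate_classifier <- function(table, labels, positive,
                                folds = 5, repeats = 200,
                                c_grid = 10^seq(-5, 5, length.out = 21),
                                gamma_grid = 10^seq(-3, 1, length.out = 10),
                                inner_folds = 3, seed = 1L) {
  if (is.character(labels) && length(labels) == 1L && labels %in% names(table)) {
    y <- factor(table[[labels]])
    feats <- numeric_feature_cols(table, exclude = labels)
  } else {
    y <- factor(labels)
    feats <- numeric_feature_cols(table)
  }
  if (nlevels(y) != 2L) stop("labels must contain exactly two classes")
  if (!positive %in% levels(y)) stop("positive class not found in labels")
  if (min(table(y)) < folds) stop("each class needs at least `folds` members")
  x <- as.matrix(table[feats])
  grid <- expand.grid(cost = c_grid, gamma = gamma_grid)

  set.seed(seed)
  auc_rep <- acc_rep <- sens_rep <- spec_rep <- numeric(repeats)
  for (rep_i in seq_len(repeats)) {
    fa <- fold_assignment(y, folds)
    scores <- numeric(length(y)); preds <- character(length(y))
    for (fo in seq_len(folds)) {
      te <- which(fa == fo); tr <- which(fa != fo)
      z <- zscore_fit(x[tr, , drop = FALSE])
      xtr <- zscore_apply(x[tr, , drop = FALSE], z)
      xte <- zscore_apply(x[te, , drop = FALSE], z)
      best <- c(grid$cost[1], grid$gamma[1])
      if (nrow(grid) > 1L) {
        ifa <- fold_assignment(y[tr], inner_folds)
        best_auc <- -Inf
        for (gi in seq_len(nrow(grid))) {
          sc <- numeric(length(tr))
          ok <- TRUE
          for (ifo in seq_len(inner_folds)) {
            ite <- which(ifa == ifo); itr <- which(ifa != ifo)
            if (length(unique(y[tr][itr])) < 2L) { ok <- FALSE; break }
            sc[ite] <- svm_scores(xtr[itr, , drop = FALSE], y[tr][itr],
                                  xtr[ite, , drop = FALSE],
                                  grid$cost[gi], grid$gamma[gi], positive)$score
          }
          if (!ok) next
          a <- auc_from_scores(sc, y[tr] == positive)
          if (a > best_auc + 1e-12) { best_auc <- a; best <- c(grid$cost[gi], grid$gamma[gi]) }
        }
      }
      out <- svm_scores(xtr, y[tr], xte, best[1], best[2], positive)
      scores[te] <- out$score
      preds[te] <- out$pred
    }
    pos <- y == positive
    auc_rep[rep_i] <- auc_from_scores(scores, pos)
    acc_rep[rep_i] <- mean(preds == as.character(y))
    sens_rep[rep_i] <- mean(preds[pos] == positive)
    spec_rep[rep_i] <- mean(preds[!pos] != positive)
  }
  structure(list(comparison = paste(levels(y), collapse = " vs "),
                 positive = positive,
                 features_after_selection = length(feats),
                 auc_mean = mean(auc_rep), auc_sd = sd(auc_rep),
                 auc_per_repeat = auc_rep,
                 accuracy = 100 * mean(acc_rep),
                 sensitivity = 100 * mean(sens_rep),
                 specificity = 100 * mean(spec_rep),
                 folds = folds, repeats = repeats,
                 c_grid = c_grid, gamma_grid = gamma_grid, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report: %s (positive = %s)\n",
                     "  features %d | AUC %.3f +/- %.3f | accuracy %.1f%% | ",
                     "sensitivity %.1f%% | specificity %.1f%%\n",
                     "  %d x %d-fold CV, seed %d>\n"),
              x$comparison, x$positive, x$features_after_selection,
              x$auc_mean, x$auc_sd, x$accuracy, x$sensitivity, x$specificity,
              x$repeats, x$folds, x$seed))
  invisible(x)
}

#' Choose the correlation-selection threshold by classifier performance
#'
#' Runs [select_features_by_correlation()] followed by
#' [evaluate_classifier()] for every candidate and returns the candidate
#' with the highest mean AUC (ties broken toward the smaller threshold).
#'
#' @param table,labels,positive As in [evaluate_classifier()].
#' @param candidate_thresholds Numeric vector of thresholds to try.
#' @param ... Passed to [evaluate_classifier()].
#' @return List with `threshold` (chosen value) and `reports` (named list of
#'   `classifier_report`s, one per candidate).
#' @export
choose_selection_threshold <- function(table, labels, positive,
                                       candidate_thresholds = c(0.75, 0.8, 0.85, 0.9),
                                       ...) {
  if (length(candidate_thresholds) < 1L) stop("need at least one candidate")
  cand <- sort(candidate_thresholds)
  reports <- list()
  for (th in cand) {
    sel <- select_features_by_correlation(table, th)
    reports[[as.character(th)]] <- evaluate_classifier(sel, labels, positive, ...)
  }
  aucs <- vapply(reports, function(r) r$auc_mean, numeric(1))
  best <- cand[which.max(aucs)]      # which.max takes the first (smallest) on ties
  list(threshold = best, reports = reports)
}
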