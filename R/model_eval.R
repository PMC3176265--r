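# RBF-kernel SVM training with grid search, cross-validation, prediction,
# metrics, ROC/AUC, feature ablation, the random baseline and group
# statistics. The quadratic-programming fit is delegated to e1071 (libsvm);
# scaling, model selection, the decision function used for scoring, and all
# evaluation code are implemented here.

#' SVM configuration
#'
#' @param C_grid candidate soft-margin costs (default 2^(-5..15) step 2).
#' @param gamma_grid candidate RBF widths (default 2^(-15..3) step 2).
#' @param cv_folds folds for cross-validation and grid search (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param scaling one of "zscore", "minmax", "none"; fit on training data
#'   only (and refit inside each CV fold).
#' @return list of class \code{svm_config}.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, 2),
                       gamma_grid = 2^seq(-15, 3, 2),
                       cv_folds = 10, seed = 1,
                       scaling = c("zscore", "minmax", "none")) {
  scaling <- match.arg(scaling)
  if (length(C_grid) == 0 || length(gamma_grid) == 0)
    stop("empty parameter grid", call. = FALSE)
  if (any(C_grid <= 0) || any(gamma_grid <= 0))
    stop("C and gamma must be positive", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 scaling = scaling),
            class = "svm_config")
}

## scaling -------------------------------------------------------------------

fit_scaler <- function(X, scaling) {
  if (scaling == "zscore") {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
  } else if (scaling == "minmax") {
    center <- apply(X, 2, min)
    scale_ <- apply(X, 2, max) - center
  } else {
    center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
  }
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  list(center = center, scale = scale_, scaling = scaling)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

## stratified seeded fold assignment: shuffles within each class so every
## fold sees both classes whenever possible
fold_assignment <- function(y, k, seed) {
  set.seed(seed)
  ids <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    ids[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  ids
}

## fit libsvm at fixed (C, gamma) on a pre-scaled matrix
fit_rbf <- function(X, y, C, gamma) {
  yf <- factor(ifelse(y, "hot", "nonhot"), levels = c("hot", "nonhot"))
  e1071::svm(x = X, y = yf, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

## decision score oriented so positive = hot spot, computed from the model's
## support data (reproducible from the persisted form)
decision_score <- function(sv, coefs, rho, gamma, flip, X) {
  k <- exp(-gamma * (outer(rowSums(X^2), rowSums(sv^2), "+") -
                     2 * tcrossprod(X, sv)))
  flip * (as.numeric(k %*% coefs) - rho)
}

#' Train an RBF-kernel SVM with grid search
#'
#' Selects (C, gamma) maximizing mean cross-validated F1 over the config
#' grids (ties resolved toward the smallest C, then the smallest gamma),
#' then refits on the full dataset. Scaling parameters are fit on the
#' training data only.
#'
#' @param ds an \code{hs_dataset} containing both classes.
#' @param cfg an \code{\link{svm_config}}.
#' @return object of class \code{hs_model} holding support vectors, dual
#'   coefficients, bias, chosen (C, gamma), scaler and feature schema.
#' @export
train_svm <- function(ds, cfg = svm_config()) {
  stopifnot(inherits(ds, "hs_dataset"))
  X <- ds$X; y <- ds$y
  if (length(unique(y)) < 2)
    stop("dataset contains a single class", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)

  grid <- expand.grid(C = cfg$C_grid, gamma = cfg$gamma_grid)
  if (nrow(grid) > 1) {
    folds <- fold_assignment(y, cfg$cv_folds, cfg$seed)
    score <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      f1s <- numeric(cfg$cv_folds)
      for (f in seq_len(cfg$cv_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2 || sum(!tr) == 0) { f1s[f] <- NA; next }
        sc <- fit_scaler(X[tr, , drop = FALSE], cfg$scaling)
        m <- fit_rbf(apply_scaler(X[tr, , drop = FALSE], sc), y[tr],
                     grid$C[g], grid$gamma[g])
        pred <- svm_predict_raw(m, apply_scaler(X[!tr, , drop = FALSE], sc))
        cm <- confusion(y[!tr], pred$label)
        f1s[f] <- eval_metrics(cm$tp, cm$fp, cm$tn, cm$fn)$f1
      }
      score[g] <- mean(f1s, na.rm = TRUE)
    }
    ## ties -> smallest C then smallest gamma (grid is sorted that way)
    best <- order(-score, grid$C, grid$gamma)[1]
  } else best <- 1L
  C <- grid$C[best]; gamma <- grid$gamma[best]

  sc <- fit_scaler(X, cfg$scaling)
  m <- fit_rbf(apply_scaler(X, sc), y, C, gamma)
  as_hs_model(m, sc, C, gamma, colnames(ds$X))
}

## orientation: libsvm's positive decision value votes for the class in
## m$labels[1]; flip so positive always means hot
as_hs_model <- function(m, sc, C, gamma, columns) {
  flip <- if (m$levels[m$labels[1]] == "hot") 1 else -1
  structure(list(schema = "hs_model/1",
                 columns = columns,
                 scaler = sc, C = C, gamma = gamma,
                 sv = unname(as.matrix(m$SV)),
                 coefs = as.numeric(m$coefs), rho = as.numeric(m$rho),
                 flip = flip),
            class = "hs_model")
}

svm_predict_raw <- function(m, Xs) {
  flip <- if (m$levels[m$labels[1]] == "hot") 1 else -1
  score <- decision_score(unname(as.matrix(m$SV)), as.numeric(m$coefs),
                          as.numeric(m$rho), m$gamma, flip, Xs)
  list(label = score >= 0, score = score)
}

#' @export
print.hs_model <- function(x, ...) {
  cat(sprintf("<hs_model: RBF SVM, C=%g, gamma=%g, %d SVs, %d features>\n",
              x$C, x$gamma, nrow(x$sv), length(x$columns)))
  invisible(x)
}

#' Predict hot spots with a trained model
#'
#' The decision score is the RBF kernel expansion over the stored support
#' vectors; the predicted label is its sign, with a score of exactly 0
#' assigned to the positive (hot-spot) class.
#'
#' @param m an \code{hs_model}.
#' @param X numeric matrix whose column names match the training schema
#'   (same names, same order).
#' @return list with \code{label} (logical) and \code{score} (numeric).
#' @export
predict_svm <- function(m, X) {
  stopifnot(inherits(m, "hs_model"))
  if (inherits(X, "hs_dataset")) X <- X$X
  if (is.null(colnames(X)) || !identical(colnames(X), m$columns))
    stop("feature columns do not match the training schema", call. = FALSE)
  Xs <- apply_scaler(X, m$scaler)
  score <- decision_score(m$sv, m$coefs, m$rho, m$gamma, m$flip, Xs)
  list(label = score >= 0, score = score)
}

#' Persist / restore a trained model
#'
#' The model is written as a JSON artifact with all numeric fields encoded
#' as hexadecimal floating point, so a reloaded model reproduces decision
#' scores bit-identically.
#'
#' @param m an \code{hs_model}.
#' @param path output path.
#' @return \code{save_model}: the path, invisibly. \code{load_model}: the
#'   restored \code{hs_model}.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "hs_model"))
  hex <- function(x) sprintf("%a", x)
  obj <- list(schema = m$schema, columns = m$columns,
              scaling = m$scaler$scaling,
              center = hex(m$scaler$center), scale = hex(m$scaler$scale),
              C = hex(m$C), gamma = hex(m$gamma), rho = hex(m$rho),
              coefs = hex(m$coefs), flip = m$flip,
              sv = apply(m$sv, 1, hex, simplify = FALSE))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "hs_model/1"))
    stop("unrecognized model schema in ", path, call. = FALSE)
  unhex <- function(s) as.numeric(s)
  sv <- if (is.list(obj$sv)) {
    do.call(rbind, lapply(obj$sv, unhex))
  } else if (is.matrix(obj$sv)) {
    matrix(unhex(obj$sv), nrow(obj$sv), ncol(obj$sv))
  } else {
    matrix(unhex(obj$sv), nrow = 1)
  }
  structure(list(schema = obj$schema, columns = obj$columns,
                 scaler = list(center = unhex(obj$center),
                               scale = unhex(obj$scale),
                               scaling = obj$scaling),
                 C = unhex(obj$C), gamma = unhex(obj$gamma),
                 sv = sv, coefs = unhex(obj$coefs), rho = unhex(obj$rho),
                 flip = obj$flip),
            class = "hs_model")
}

## evaluation ---------------------------------------------------------------

confusion <- function(truth, pred) {
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R). A ratio
#' with zero denominator is reported as 0 and flagged in
#' \code{$degenerate}.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return list with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{precision}, \code{recall}, \code{f1}, \code{degenerate}.
#' @export
eval_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  degenerate <- FALSE
  p <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else { degenerate <- TRUE; 0 }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = p, recall = r, f1 = f1, degenerate = degenerate)
}

#' ROC curve and trapezoidal AUC
#'
#' Thresholds sweep the distinct score values; tied scores move along the
#' curve together, so the trapezoidal area equals the Mann-Whitney
#' rank-sum form with ties counted one half.
#'
#' @param scores numeric decision scores, larger = more hot-spot-like.
#' @param labels logical (or 0/1) true labels; both classes required.
#' @return list with \code{roc} (data.frame fpr, tpr, ordered) and
#'   \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("ROC requires both classes", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  ## group tied scores
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_end]; fp <- cumsum(!l)[grp_end]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

eval_report <- function(truth, label, score = NULL) {
  cm <- confusion(truth, label)
  rep <- eval_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
  if (!is.null(score) && length(unique(truth)) == 2) {
    ra <- roc_auc(score, truth)
    rep$roc <- ra$roc; rep$auc <- ra$auc
  }
  class(rep) <- "hs_eval"
  rep
}

#' @export
print.hs_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d | P %.3f  R %.3f  F1 %.3f%s\n",
              x$tp, x$fp, x$tn, x$fn, x$precision, x$recall, x$f1,
              if (!is.null(x$auc)) sprintf("  AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' k-fold cross-validation
#'
#' Rows are randomly divided into \code{cfg$cv_folds} near-equal subsets
#' (stratified by class, assignment fixed by \code{cfg$seed}); each fold is
#' predicted by a model trained on the others, with scaling refit inside
#' each fold. When the config grids contain more than one (C, gamma) pair,
#' the pair is selected once by \code{\link{train_svm}}'s grid search before
#' the folds are evaluated. Confusion counts are pooled over folds
#' (fold-averaged metrics are returned alongside).
#'
#' @param ds an \code{hs_dataset}.
#' @param cfg an \code{\link{svm_config}}.
#' @return an \code{hs_eval} report with pooled counts, ROC/AUC over pooled
#'   scores, chosen \code{C}/\code{gamma}, and \code{fold_f1}.
#' @export
cross_validate <- function(ds, cfg = svm_config()) {
  stopifnot(inherits(ds, "hs_dataset"))
  n <- length(ds$y)
  if (cfg$cv_folds > n) stop("more folds than rows", call. = FALSE)
  if (length(cfg$C_grid) * length(cfg$gamma_grid) > 1) {
    sel <- train_svm(ds, cfg)
    C <- sel$C; gamma <- sel$gamma
  } else {
    C <- cfg$C_grid; gamma <- cfg$gamma_grid
  }
  folds <- fold_assignment(ds$y, cfg$cv_folds, cfg$seed)
  pred <- logical(n); score <- numeric(n)
  fold_f1 <- numeric(cfg$cv_folds)
  for (f in seq_len(cfg$cv_folds)) {
    tr <- folds != f
    sc <- fit_scaler(ds$X[tr, , drop = FALSE], cfg$scaling)
    m <- fit_rbf(apply_scaler(ds$X[tr, , drop = FALSE], sc), ds$y[tr],
                 C, gamma)
    p <- svm_predict_raw(m, apply_scaler(ds$X[!tr, , drop = FALSE], sc))
    pred[!tr] <- p$label; score[!tr] <- p$score
    cm <- confusion(ds$y[!tr], p$label)
    fold_f1[f] <- eval_metrics(cm$tp, cm$fp, cm$tn, cm$fn)$f1
  }
  rep <- eval_report(ds$y, pred, score)
  rep$C <- C; rep$gamma <- gamma; rep$fold_f1 <- fold_f1
  rep
}

#' Self-consistency test
#'
#' Trains on the full dataset (grid search included) and evaluates on the
#' same rows; an optimistic upper reference for the cross-validated
#' performance.
#'
#' @inheritParams cross_validate
#' @return an \code{hs_eval} report.
#' @export
self_consistency <- function(ds, cfg = svm_config()) {
  m <- train_svm(ds, cfg)
  p <- predict_svm(m, ds$X)
  rep <- eval_report(ds$y, p$label, p$score)
  rep$C <- m$C; rep$gamma <- m$gamma
  rep
}

#' Leave-one-group-out feature ablation
#'
#' Cross-validated F1 with each feature group removed, minus the
#' full-model cross-validated F1 (negative delta = the group helps).
#'
#' @param ds an \code{hs_dataset}; group-to-column mapping is taken from
#'   \code{ds$feature_groups} if present, else from the built-in groups of
#'   \code{ds$combo}.
#' @param cfg an \code{\link{svm_config}}.
#' @param groups group names to ablate (default: all groups of the dataset).
#' @return data.frame with columns group, f1_without, delta_f1, plus the
#'   full-model F1 in \code{attr(, "f1_full")}.
#' @export
ablate_features <- function(ds, cfg = svm_config(), groups = NULL) {
  stopifnot(inherits(ds, "hs_dataset"))
  gmap <- ds$feature_groups
  if (is.null(gmap)) gmap <- FEATURE_GROUPS[ds$combo]
  if (is.null(groups)) groups <- names(gmap)
  full <- cross_validate(ds, cfg)
  out <- data.frame(group = groups, f1_without = NA_real_,
                    delta_f1 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    drop_cols <- gmap[[groups[i]]]
    keep <- setdiff(colnames(ds$X), drop_cols)
    if (length(keep) == 0)
      stop("ablating group '", groups[i], "' empties the feature matrix",
           call. = FALSE)
    sub <- ds
    sub$X <- ds$X[, keep, drop = FALSE]
    rep <- cross_validate(sub, cfg)
    out$f1_without[i] <- rep$f1
    out$delta_f1[i] <- rep$f1 - full$f1
  }
  attr(out, "f1_full") <- full$f1
  out
}

#' Random-assignment baseline
#'
#' Against a fixed label vector with \code{n_pos} positives out of
#' \code{n_total}, each replicate predicts positive a uniformly random
#' subset of size \code{n_pred} (default \code{n_pos}) and scores it;
#' reported metrics are means over replicates.
#'
#' @param n_total number of residues.
#' @param n_pos number of true positives in the fixed labels.
#' @param replicates number of random replicates.
#' @param seed RNG seed.
#' @param n_pred size of the random predicted-positive subset.
#' @return list with mean \code{precision}, \code{recall}, \code{f1}, the
#'   per-replicate \code{f1_values}, and the setup.
#' @export
random_baseline <- function(n_total, n_pos, replicates = 1000, seed = 1,
                            n_pred = n_pos) {
  if (n_pos > n_total || n_pred > n_total)
    stop("more positives than residues", call. = FALSE)
  truth <- c(rep(TRUE, n_pos), rep(FALSE, n_total - n_pos))
  set.seed(seed)
  p <- r <- f1 <- numeric(replicates)
  for (i in seq_len(replicates)) {
    pred <- logical(n_total)
    pred[sample.int(n_total, n_pred)] <- TRUE
    cm <- confusion(truth, pred)
    m <- eval_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
    p[i] <- m$precision; r[i] <- m$recall; f1[i] <- m$f1
  }
  list(precision = mean(p), recall = mean(r), f1 = mean(f1),
       f1_values = f1, n_total = n_total, n_pos = n_pos,
       n_pred = n_pred, replicates = replicates, seed = seed)
}

#' Compare a feature between hot spots and non-hot spots
#'
#' Two-sample location comparison of per-residue feature values; Welch's
#' t-test by default, Wilcoxon rank-sum optionally.
#'
#' @param values_hot,values_nonhot numeric vectors (at least 2 values each;
#'   NAs dropped).
#' @param method "welch" or "wilcoxon".
#' @return list with \code{mean_hot}, \code{mean_nonhot}, \code{diff},
#'   \code{p_value}, \code{method}.
#' @export
compare_groups <- function(values_hot, values_nonhot,
                           method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  values_hot <- values_hot[!is.na(values_hot)]
  values_nonhot <- values_nonhot[!is.na(values_nonhot)]
  if (length(values_hot) < 2 || length(values_nonhot) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  pv <- if (method == "welch") {
    stats::t.test(values_hot, values_nonhot)$p.value
  } else {
    stats::wilcox.test(values_hot, values_nonhot, exact = FALSE)$p.value
  }
  list(mean_hot = mean(values_hot), mean_nonhot = mean(values_nonhot),
       diff = mean(values_hot) - mean(values_nonhot),
       p_value = pv, method = method)
}
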