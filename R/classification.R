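# SVM baselines, the per-seed MCF ensemble, and the balanced repeated
# cross-validation protocol.

# Rank (Mann-Whitney) AUC of `score` for discriminating `truth == positive`;
# score ties count half, so a constant predictor scores exactly 0.5.
binary_auc <- function(score, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

positive_class <- function(labels) {
  cls <- sort(unique(as.character(labels)))
  if ("cancer" %in% cls) "cancer" else cls[1]
}

#' Fit a two-class SVM with oriented decision values
#'
#' Thin wrapper over [e1071::svm()] that standardizes features on the
#' training data and orients decision values so that positive means the
#' positive (cancer) class. Defaults — linear kernel, cost 1 — suit the
#' small feature sets used here and are configurable.
#'
#' @param x Samples x features numeric matrix.
#' @param labels Two-class labels aligned to rows of `x`.
#' @param kernel,cost Passed to [e1071::svm()].
#' @return An `mcf_svm`: the fitted model plus the positive-class
#'   convention and the feature names it expects.
#' @export
fit_svm <- function(x, labels, kernel = "linear", cost = 1) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("need exactly two classes, got: ",
                              paste(cls, collapse = ", "))
  if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
  y <- factor(labels, levels = cls)
  scale_cols <- apply(x, 2L, stats::sd) > 0
  fit <- e1071::svm(x = x, y = y, kernel = kernel, cost = cost,
                    scale = scale_cols)
  structure(list(fit = fit, positive = positive_class(labels),
                 classes = cls, features = colnames(x)),
            class = "mcf_svm")
}

#' Decision values of a fitted SVM
#'
#' @param object An `mcf_svm`.
#' @param x Samples x features matrix (columns matched by name when
#'   present).
#' @return Named numeric vector; positive values favor the positive class.
#' @export
svm_decision <- function(object, x) {
  x <- as.matrix(x)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    x <- x[, object$features, drop = FALSE]
  }
  pred <- stats::predict(object$fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 labels the column "A/B": positive decision value favors A
  favored <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  out <- dv[, 1]
  if (favored != object$positive) out <- -out
  stats::setNames(as.numeric(out), rownames(x))
}

#' @export
predict.mcf_svm <- function(object, newdata, type = c("label", "decision"),
                            ...) {
  type <- match.arg(type)
  dv <- svm_decision(object, newdata)
  if (type == "decision") return(dv)
  other <- setdiff(object$classes, object$positive)
  stats::setNames(ifelse(dv > 0, object$positive, other), names(dv))
}

#' Baseline SVM on individual metabolic gene expression (MGE-SVM)
#'
#' Trains a single SVM using each metabolic gene's (ranked) expression as
#' a feature — the gene-level baseline the composite-pathway ensemble is
#' compared against.
#'
#' @param ranked Genes x samples matrix (typically [rank_transform()]
#'   output).
#' @param labels Two-class sample labels.
#' @param model Optional `metabolic_model`; when given, features are
#'   restricted to the model's genes.
#' @param ... Passed to [fit_svm()].
#' @return An `mcf_svm`.
#' @export
train_mge_svm <- function(ranked, labels, model = NULL, ...) {
  if (!is.null(model)) {
    keep <- intersect(rownames(ranked), model$genes)
    if (length(keep) == 0L) stop("no model genes present in the matrix")
    ranked <- ranked[keep, , drop = FALSE]
  }
  labels <- align_labels(labels, colnames(ranked))
  fit_svm(t(ranked), labels, ...)
}

#' Baseline SVM on canonical pathway expression
#'
#' @param pw Pathway x sample matrix from [pathway_expression()]. All-`NA`
#'   pathways are dropped; remaining missing entries enter as 0.
#' @param labels Two-class sample labels.
#' @param ... Passed to [fit_svm()].
#' @return An `mcf_svm`.
#' @export
train_pathway_svm <- function(pw, labels, ...) {
  pw <- pw[rowSums(!is.na(pw)) > 0L, , drop = FALSE]
  if (nrow(pw) == 0L) stop("no evaluable pathway features")
  pw[is.na(pw)] <- 0
  labels <- align_labels(labels, colnames(pw))
  fit_svm(t(pw), labels, ...)
}

#' Train the MCF per-seed SVM ensemble
#'
#' Discovers composite-pathway features with [build_features()] and trains
#' one SVM per seed reporter metabolite on that seed's L heaviest-distance
#' features. Prediction is by majority vote of the members, with the
#' summed decision value ([mcf_score()]) as the continuous score.
#'
#' @inheritParams build_features
#' @param kernel,cost Passed to [fit_svm()].
#' @param ... Further arguments for [build_features()].
#' @return An `mcf_ensemble`: list of members (seed, feature set, svm)
#'   plus the search configuration.
#' @export
train_mcf <- function(model, graph, rxn, labels, k = 5L, L = 10L,
                      cfg = search_config(), kernel = "linear", cost = 1,
                      ...) {
  labels <- align_labels(labels, colnames(rxn))
  fsets <- build_features(model, graph, rxn, labels, k = k, L = L,
                          cfg = cfg, ...)
  members <- lapply(fsets, function(fs) {
    list(seed = fs$seed, feature_set = fs,
         svm = fit_svm(fs$features, labels[rownames(fs$features)],
                       kernel = kernel, cost = cost))
  })
  structure(list(members = members, cfg = cfg,
                 seeds = attr(fsets, "seeds"), de = attr(fsets, "de")),
            class = "mcf_ensemble")
}

#' @export
print.mcf_ensemble <- function(x, ...) {
  cat(sprintf("MCF ensemble: %d per-seed SVMs (seeds: %s)\n",
              length(x$members),
              paste(vapply(x$members, `[[`, character(1), "seed"),
                    collapse = ", ")))
  invisible(x)
}

#' Compute ensemble member features for (new) samples
#'
#' @param ens An `mcf_ensemble`.
#' @param graph A `metabolite_graph`.
#' @param rxn Reaction x sample matrix for the samples to featurize.
#' @return Named list (by seed) of samples x L feature matrices.
#' @export
mcf_features <- function(ens, graph, rxn) {
  lapply(stats::setNames(ens$members,
                         vapply(ens$members, `[[`, character(1), "seed")),
         function(m) compute_features(m$feature_set, graph, rxn,
                                      cfg = ens$cfg)$features)
}

#' Majority-vote class prediction of the MCF ensemble
#'
#' Each member votes with its own decision; the label winning more than
#' half the votes is returned. An exact tie (possible only for even
#' ensemble sizes) falls back to the sign of the summed decision value.
#'
#' @param ens An `mcf_ensemble`.
#' @param features List of per-member feature matrices from
#'   [mcf_features()].
#' @return Named character vector of predicted labels.
#' @export
predict_majority <- function(ens, features) {
  pos <- ens$members[[1]]$svm$positive
  neg <- setdiff(ens$members[[1]]$svm$classes, pos)
  dvs <- member_decisions(ens, features)
  votes_pos <- rowSums(dvs > 0)
  n <- length(ens$members)
  lab <- ifelse(votes_pos > n / 2, pos,
                ifelse(votes_pos < n / 2, neg,
                       ifelse(rowSums(dvs) > 0, pos, neg)))
  stats::setNames(lab, rownames(dvs))
}

member_decisions <- function(ens, features) {
  stopifnot(length(features) == length(ens$members))
  dvs <- vapply(seq_along(ens$members), function(i)
    svm_decision(ens$members[[i]]$svm, features[[i]]),
    numeric(nrow(features[[1]])))
  if (is.null(dim(dvs))) dvs <- matrix(dvs, nrow = 1L)
  rownames(dvs) <- rownames(features[[1]])
  dvs
}

#' Continuous MCF classification score
#'
#' The sum of the N member SVMs' decision values; the continuous
#' counterpart of the majority vote, used for ROC/AUC.
#'
#' @inheritParams predict_majority
#' @return Named numeric vector.
#' @export
mcf_score <- function(ens, features) {
  dvs <- member_decisions(ens, features)
  stats::setNames(rowSums(dvs), rownames(dvs))
}

#' Evaluation protocol: balanced down-sampling + repeated k-fold CV
#'
#' @param n_repetitions Number of independent repetitions (default 100);
#'   each down-samples the majority class to the minority size.
#' @param n_folds Folds per repetition (default 5), stratified by class.
#' @param seed Master RNG seed; all repetition streams derive from it.
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(n_repetitions = 100L, n_folds = 5L, seed = 1L) {
  structure(list(n_repetitions = as.integer(n_repetitions),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "eval_protocol")
}

# Stratified fold assignment for a balanced sample set.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Balanced repeated cross-validation
#'
#' Implements the evaluation protocol: per repetition, (i) the majority
#' class is down-sampled uniformly at random to the minority class size;
#' (ii) the balanced set is split into stratified folds; (iii) the
#' supplied fit/predict closure is trained on each training fold — any
#' feature selection happens inside it, so test-fold labels are never
#' seen — and scored on the held-out fold by AUC and accuracy.
#'
#' @param fit_predict `function(train_ids, test_ids)` returning
#'   `list(score = <named numeric>, label = <named character>)` over
#'   `test_ids`.
#' @param labels Named two-class labels over all candidate samples.
#' @param protocol An [eval_protocol()].
#' @param keep_scores Keep per-sample test scores (for ROC curves).
#' @return A `cv_result`: data frame (repetition, fold, auc, accuracy)
#'   with summary attributes; `mean_auc`/`mean_accuracy` are means over
#'   repetition means.
#' @export
cross_validate <- function(fit_predict, labels, protocol = eval_protocol(),
                           keep_scores = FALSE) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels))) stop("labels must be named by sample id")
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("labels must contain exactly two classes")
  sizes <- table(labels)
  if (min(sizes) < protocol$n_folds) {
    stop("minority class smaller than the number of folds")
  }
  pos <- positive_class(labels)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(protocol$seed)
  rep_seeds <- sample.int(.Machine$integer.max, protocol$n_repetitions)
  rows <- list()
  score_rows <- list()
  for (rep_i in seq_len(protocol$n_repetitions)) {
    set.seed(rep_seeds[rep_i])
    minority <- names(sizes)[which.min(sizes)]
    majority <- setdiff(cls, minority)
    keep <- c(names(labels)[labels == minority],
              sample(names(labels)[labels == majority], min(sizes)))
    lab <- labels[keep]
    fold <- stratified_folds(lab, protocol$n_folds)
    for (f in seq_len(protocol$n_folds)) {
      test_ids <- keep[fold == f]
      train_ids <- keep[fold != f]
      pred <- fit_predict(train_ids, test_ids)
      truth <- lab[test_ids]
      auc <- binary_auc(pred$score[test_ids], truth, pos)
      acc <- mean(pred$label[test_ids] == truth)
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = rep_i, fold = f, auc = auc, accuracy = acc)
      if (keep_scores) {
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          repetition = rep_i, fold = f, sample = test_ids,
          score = unname(pred$score[test_ids]), truth = unname(truth))
      }
    }
  }
  res <- do.call(rbind, rows)
  rep_means <- stats::aggregate(cbind(auc, accuracy) ~ repetition, res, mean)
  structure(res, class = c("cv_result", "data.frame"),
            protocol = protocol,
            rep_means = rep_means,
            mean_auc = mean(rep_means$auc),
            mean_accuracy = mean(rep_means$accuracy),
            scores = if (keep_scores) do.call(rbind, score_rows) else NULL)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV result: %d repetitions x %d folds; mean AUC %.3f, mean accuracy %.3f\n",
              attr(x, "protocol")$n_repetitions, attr(x, "protocol")$n_folds,
              attr(x, "mean_auc"), attr(x, "mean_accuracy")))
  invisible(x)
}

#' Paired one-sided comparison of two cross-validation results
#'
#' Pairs the per-fold metric values of two classifiers evaluated on
#' identical splits (same protocol seed) and tests whether the first
#' outperforms the second with a one-sided paired t-test. When every
#' paired difference is identical the t statistic is degenerate; the
#' result is then reported as p below machine epsilon (consistent
#' advantage), 0.5 (no difference), or 1 (consistent deficit), flagged as
#' degenerate.
#'
#' @param cv_a,cv_b `cv_result` objects with matching fold structure.
#' @param metric `"auc"` or `"accuracy"`.
#' @return List: `statistic`, `p`, `mean_difference`, `degenerate`.
#' @export
compare_classifiers <- function(cv_a, cv_b, metric = c("auc", "accuracy")) {
  metric <- match.arg(metric)
  if (nrow(cv_a) != nrow(cv_b) ||
      !identical(cv_a$repetition, cv_b$repetition) ||
      !identical(cv_a$fold, cv_b$fold)) {
    stop("cross-validation results are not matched (same protocol required)")
  }
  d <- cv_a[[metric]] - cv_b[[metric]]
  if (stats::sd(d) == 0) {
    p <- if (mean(d) > 0) .Machine$double.eps else if (mean(d) == 0) 0.5 else 1
    return(list(statistic = NA_real_, p = p, mean_difference = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(cv_a[[metric]], cv_b[[metric]], paired = TRUE,
                      alternative = "greater")
  list(statistic = unname(tt$statistic), p = tt$p.value,
       mean_difference = mean(d), degenerate = FALSE)
}

#' Fit/predict closure for the MCF ensemble, for use in [cross_validate()]
#'
#' All feature discovery (differential reactions, seeds, targets) is redone
#' inside each training fold. A training fold in which no seed reporter
#' metabolite passes the threshold yields an uninformative null model that
#' scores every test sample 0 and predicts the majority training label:
#' a classifier with no features cannot discriminate, and the tie-aware
#' AUC of a constant score is exactly 0.5.
#'
#' @param model,graph,rxn,k,L,cfg,... As in [train_mcf()].
#' @param labels Named labels over all samples (folds index into these).
#' @return A closure `function(train_ids, test_ids)`.
#' @export
mcf_trainer <- function(model, graph, rxn, labels, k = 5L, L = 10L,
                        cfg = search_config(), ...) {
  labels <- align_labels(labels, colnames(rxn))
  function(train_ids, test_ids) {
    ens <- tryCatch(
      train_mcf(model, graph, rxn[, train_ids, drop = FALSE],
                labels[train_ids], k = k, L = L, cfg = cfg, ...),
      error = function(e) {
        if (grepl("no seed metabolites", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(ens)) {
      tab <- table(labels[train_ids])
      maj <- names(tab)[which.max(tab)]
      return(list(score = stats::setNames(rep(0, length(test_ids)), test_ids),
                  label = stats::setNames(rep(maj, length(test_ids)), test_ids)))
    }
    feats <- mcf_features(ens, graph, rxn[, test_ids, drop = FALSE])
    list(score = mcf_score(ens, feats),
         label = predict_majority(ens, feats))
  }
}

#' Fit/predict closure for a plain feature-matrix SVM
#'
#' @param x Features x samples matrix (genes for the MGE baseline,
#'   pathways for the canonical-pathway baseline; `NA` entries become 0).
#' @param labels Named labels over all samples.
#' @param ... Passed to [fit_svm()].
#' @return A closure `function(train_ids, test_ids)` for
#'   [cross_validate()].
#' @export
svm_trainer <- function(x, labels, ...) {
  labels <- align_labels(labels, colnames(x))
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  function(train_ids, test_ids) {
    fit <- fit_svm(t(x[, train_ids, drop = FALSE]), labels[train_ids], ...)
    newx <- t(x[, test_ids, drop = FALSE])
    list(score = svm_decision(fit, newx),
         label = stats::predict(fit, newx))
  }
}
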