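make_separable <- function(n_per_class = 20, p = 5, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
  rownames(x) <- sprintf("s%03d", seq_len(2 * n_per_class))
  colnames(x) <- sprintf("f%d", seq_len(p))
  labels <- setNames(rep(c("normal", "cancer"), each = n_per_class),
                     rownames(x))
  list(x = x, labels = labels)
}

test_that("linearly separated classes are fit perfectly", {
  d <- make_separable()
  fit <- fit_svm(d$x, d$labels)
  expect_equal(unname(predict(fit, d$x)), unname(d$labels))
  dv <- svm_decision(fit, d$x)
  expect_true(all(dv[d$labels == "cancer"] > 0))
  expect_true(all(dv[d$labels == "normal"] < 0))
})

test_that("degenerate single-sample classes are refused", {
  x <- matrix(rnorm(10), nrow = 2,
              dimnames = list(c("s1", "s2"), sprintf("f%d", 1:5)))
  expect_error(fit_svm(x, c(s1 = "cancer", s2 = "normal")), "at least 2")
  expect_error(fit_svm(x, c(s1 = "cancer", s2 = "cancer")), "two classes")
})

test_that("MGE baseline restricts to model genes and separates planted data", {
  st <- planted_study(seed = 2L, n_metabolites = 40L, n_reactions = 70L,
                      n_chains = 6L, n_normal = 25L, n_cancer = 25L)
  fit <- train_mge_svm(st$ranked, st$sim$labels, model = st$model)
  expect_setequal(fit$features, st$model$genes)
  expect_equal(unname(predict(fit, t(st$ranked))), unname(st$sim$labels))
})

test_that("pathway SVM sees aggregate features only", {
  st <- planted_study(seed = 2L, n_metabolites = 40L, n_reactions = 70L,
                      n_chains = 6L, n_normal = 25L, n_cancer = 25L)
  pw <- pathway_expression(st$rxn, st$model, "sum")
  fit <- train_pathway_svm(pw, st$sim$labels)
  expect_true(length(fit$features) <= length(st$model$pathways))
})

test_that("antagonistic within-pathway shifts favor gene over pathway SVM", {
  # two genes per pathway shifted in opposite directions: the pathway sum
  # cancels while individual genes remain informative
  set.seed(31)
  n <- 30
  genes <- sprintf("g%02d", 1:20)
  expr <- matrix(rnorm(length(genes) * 2 * n, mean = 8), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%03d", seq_len(2 * n))))
  labels <- setNames(rep(c("normal", "cancer"), each = n), colnames(expr))
  canc <- labels == "cancer"
  expr[seq(1, 20, 2), canc] <- expr[seq(1, 20, 2), canc] + 2
  expr[seq(2, 20, 2), canc] <- expr[seq(2, 20, 2), canc] - 2
  df <- data.frame(from = sprintf("a%02d", 1:20), to = sprintf("b%02d", 1:20),
                   gene = genes,
                   pathway = rep(sprintf("P%02d", 1:10), each = 2))
  model <- edges_model(df)
  ranked <- rank_transform(expr)
  rxn <- reactions_from_genes(ranked, model)
  pwx <- pathway_expression(rxn, model, "sum")
  proto <- eval_protocol(n_repetitions = 5, n_folds = 5, seed = 7)
  cv_gene <- cross_validate(svm_trainer(ranked, labels), labels, proto)
  cv_pw <- cross_validate(svm_trainer(pwx, labels), labels, proto)
  expect_gt(attr(cv_gene, "mean_auc"), attr(cv_pw, "mean_auc"))
})

test_that("ensemble votes, ties and scores follow the stated rules", {
  st <- planted_study(seed = 4L, n_metabolites = 40L, n_reactions = 70L,
                      n_chains = 6L, n_normal = 25L, n_cancer = 25L)
  ens <- train_mcf(st$model, st$graph, st$rxn, st$sim$labels, L = 5L)
  feats <- mcf_features(ens, st$graph, st$rxn)
  dv <- mcfnet:::member_decisions(ens, feats)
  sc <- mcf_score(ens, feats)
  # score is the sum of member decision values
  expect_equal(sc, setNames(rowSums(dv), rownames(dv)))
  # single-member ensemble: vote equals the member prediction, score the
  # member decision value
  ens1 <- ens
  ens1$members <- ens$members[1]
  f1 <- feats[1]
  expect_equal(mcf_score(ens1, f1),
               svm_decision(ens1$members[[1]]$svm, f1[[1]]))
  expect_equal(unname(predict_majority(ens1, f1)),
               unname(predict(ens1$members[[1]]$svm, f1[[1]])))
  # even-sized ensemble with a split vote falls back to the score sign
  flipped <- ens$members[[1]]
  flipped$svm$positive <- setdiff(flipped$svm$classes, flipped$svm$positive)
  ens2 <- ens
  ens2$members <- list(ens$members[[1]], flipped)
  f2 <- list(feats[[1]], feats[[1]])
  dv2 <- mcfnet:::member_decisions(ens2, f2)
  split_vote <- (dv2[, 1] > 0) != (dv2[, 2] > 0)
  lab2 <- predict_majority(ens2, f2)
  s2 <- mcf_score(ens2, f2)
  expect_true(all(lab2[split_vote] ==
                  ifelse(s2[split_vote] > 0, "cancer", "normal")))
})

test_that("majority vote recovers the planted classes on training data", {
  st <- planted_study(seed = 4L, n_metabolites = 40L, n_reactions = 70L,
                      n_chains = 6L, n_normal = 25L, n_cancer = 25L)
  ens <- train_mcf(st$model, st$graph, st$rxn, st$sim$labels, L = 5L)
  feats <- mcf_features(ens, st$graph, st$rxn)
  expect_equal(unname(predict_majority(ens, feats)), unname(st$sim$labels))
})

test_that("down-sampling balances classes exactly in every repetition", {
  labels <- setNames(rep(c("normal", "cancer"), c(40, 15)),
                     sprintf("s%03d", 1:55))
  seen <- list()
  fp <- function(train_ids, test_ids) {
    ids <- c(train_ids, test_ids)
    seen[[length(seen) + 1L]] <<- table(labels[ids])
    list(score = setNames(rnorm(length(test_ids)), test_ids),
         label = setNames(sample(c("normal", "cancer"), length(test_ids),
                                 TRUE), test_ids))
  }
  cv <- cross_validate(fp, labels, eval_protocol(4, 5, seed = 11))
  for (tab in seen) expect_equal(unname(tab["cancer"]), unname(tab["normal"]))
  expect_equal(nrow(cv), 20L)
})

test_that("a constant classifier scores chance on balanced folds", {
  labels <- setNames(rep(c("normal", "cancer"), each = 25),
                     sprintf("s%03d", 1:50))
  fp <- function(train_ids, test_ids) {
    list(score = setNames(rep(0, length(test_ids)), test_ids),
         label = setNames(rep("cancer", length(test_ids)), test_ids))
  }
  cv <- cross_validate(fp, labels, eval_protocol(5, 5, seed = 2))
  expect_equal(attr(cv, "mean_auc"), 0.5)
  expect_equal(attr(cv, "mean_accuracy"), 0.5)
})

test_that("permuted labels give chance-level AUC for a real SVM", {
  set.seed(17)
  x <- matrix(rnorm(30 * 200), nrow = 30,
              dimnames = list(sprintf("f%d", 1:30), sprintf("s%03d", 1:200)))
  labels <- setNames(rep(c("normal", "cancer"), each = 100), colnames(x))
  cv <- cross_validate(svm_trainer(x, labels), labels,
                       eval_protocol(20, 5, seed = 5))
  expect_gt(attr(cv, "mean_auc"), 0.45)
  expect_lt(attr(cv, "mean_auc"), 0.55)
})

test_that("fixed protocol seeds reproduce cross-validation exactly", {
  d <- make_separable(n_per_class = 15)
  x <- t(d$x)
  cv1 <- cross_validate(svm_trainer(x, d$labels), d$labels,
                        eval_protocol(3, 5, seed = 42))
  cv2 <- cross_validate(svm_trainer(x, d$labels), d$labels,
                        eval_protocol(3, 5, seed = 42))
  expect_identical(as.data.frame(cv1), as.data.frame(cv2))
  expect_equal(attr(cv1, "mean_auc"), 1.0)
})

test_that("classifier comparison handles shifts and degenerate pairing", {
  proto <- eval_protocol(4, 5, seed = 9)
  d <- make_separable(n_per_class = 15)
  cv <- cross_validate(svm_trainer(t(d$x), d$labels), d$labels, proto)
  same <- compare_classifiers(cv, cv)
  expect_true(same$degenerate)
  expect_equal(same$p, 0.5)

  worse <- cv
  worse$auc <- cv$auc - 0.1
  better <- compare_classifiers(cv, worse)
  expect_true(better$degenerate)
  expect_lt(better$p, 1e-10)

  # non-degenerate: matches the closed-form paired t p-value
  set.seed(33)
  a <- cv; b <- cv
  a$auc <- runif(nrow(cv), 0.8, 1.0)
  b$auc <- a$auc - rnorm(nrow(cv), mean = 0.05, sd = 0.02)
  got <- compare_classifiers(a, b)
  dif <- a$auc - b$auc
  tstat <- mean(dif) / (sd(dif) / sqrt(length(dif)))
  expect_equal(got$statistic, tstat)
  expect_equal(got$p, pt(tstat, length(dif) - 1, lower.tail = FALSE))
  expect_error(compare_classifiers(cv, cv[1:10, ]), "not matched")
})

test_that("feature selection never sees test-fold labels", {
  st <- planted_study(seed = 6L, n_metabolites = 40L, n_reactions = 70L,
                      n_chains = 6L, n_normal = 25L, n_cancer = 25L)
  labels <- st$sim$labels
  samples <- names(labels)
  test_ids <- samples[seq(1, length(samples), by = 4)]
  train_ids <- setdiff(samples, test_ids)
  fsets <- build_features(st$model, st$graph,
                          st$rxn[, train_ids, drop = FALSE],
                          labels[train_ids], L = 5L, correction = "none")
  # poison the held-out labels: selected features must not change
  poisoned <- labels
  poisoned[test_ids] <- ifelse(poisoned[test_ids] == "cancer",
                               "normal", "cancer")
  fsets_poisoned <- build_features(st$model, st$graph,
                                   st$rxn[, train_ids, drop = FALSE],
                                   poisoned[train_ids], L = 5L, correction = "none")
  expect_identical(lapply(fsets, `[[`, "targets"),
                   lapply(fsets_poisoned, `[[`, "targets"))
})
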