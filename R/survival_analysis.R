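# Transfer of learned pathway definitions to an unseen cohort, pathway
# ratio scoring of patients, and survival evaluation (Kaplan-Meier
# extremes, log-rank, concordance index, enrichment).

check_survival <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("patient", "time", "event") %in% names(surv)))
  if (any(surv$time < 0)) stop("negative follow-up times")
  if (!all(surv$event %in% c(0, 1))) stop("event flags must be 0/1")
  if (anyDuplicated(surv$patient)) stop("duplicate patient ids")
  surv
}

#' Composite-pathway weights for an unseen cohort
#'
#' Applies trained composite pathway definitions (seed, targets, first-hop
#' restriction) to new patients: each patient's expression is converted to
#' a weighted metabolite graph and the heaviest distance from each seed to
#' each trained target becomes that patient's weight for the composite
#' pathway. No seeds or targets are re-selected on the new cohort.
#'
#' @param feature_sets An `mcf_feature_sets` (or list of
#'   `composite_feature_set`).
#' @param expr Genes x patients raw expression of the unseen cohort.
#' @param model A `metabolic_model`.
#' @param graph Its digraph (computed if `NULL`).
#' @param cfg A [search_config()].
#' @return Patients x pathways matrix; columns named `"seed->target"`.
#'   Unreachable pairs are 0 with the missing pattern in attribute
#'   `"missing"`.
#' @export
composite_pathway_weights <- function(feature_sets, expr, model,
                                      graph = NULL, cfg = search_config()) {
  if (is.null(graph)) graph <- to_digraph(model)
  ranked <- rank_transform(expr)
  rxn <- reactions_from_genes(ranked, model)
  blocks <- lapply(feature_sets, function(fs) {
    res <- compute_features(fs, graph, rxn, cfg = cfg)
    colnames(res$features) <- paste0(fs$seed, "->", colnames(res$features))
    colnames(res$missing) <- colnames(res$features)
    res
  })
  weights <- do.call(cbind, lapply(blocks, `[[`, "features"))
  missing <- do.call(cbind, lapply(blocks, `[[`, "missing"))
  all_missing <- colnames(weights)[colSums(!missing) == 0L]
  if (length(all_missing) > 0L) {
    warning("composite pathway(s) unreachable for every patient: ",
            paste(all_missing, collapse = ", "))
  }
  attr(weights, "missing") <- missing
  weights
}

#' Canonical-pathway weights (patients x pathways)
#'
#' The canonical counterpart of [composite_pathway_weights()]: each
#' patient's weight for a canonical pathway is the sum of the ranks of the
#' reactions in that pathway, i.e. the transpose of
#' `pathway_expression(..., aggregator = "sum")`.
#'
#' @param expr Genes x patients raw expression.
#' @param model A `metabolic_model`.
#' @return Patients x pathways matrix.
#' @export
canonical_pathway_weights <- function(expr, model) {
  ranked <- rank_transform(expr)
  rxn <- reactions_from_genes(ranked, model)
  t(pathway_expression(rxn, model, aggregator = "sum"))
}

#' Split pathways by their direction of change in cancer
#'
#' On a labeled cohort, a pathway whose mean weight is higher in cancer
#' samples joins `P_c`, otherwise `P_n` (exact ties go to `P_n` with a
#' warning). The partition is learned once on training data and then
#' applied to unseen cohorts.
#'
#' @param weights Samples x pathways matrix on the labeled cohort.
#' @param labels Two-class sample labels (rows of `weights`).
#' @return A `direction_assignment`: list with character vectors `p_c`
#'   and `p_n`.
#' @export
assign_directions <- function(weights, labels) {
  labels <- align_labels(labels, rownames(weights))
  cancer <- labels == positive_class(labels)
  mc <- colMeans(weights[cancer, , drop = FALSE], na.rm = TRUE)
  mn <- colMeans(weights[!cancer, , drop = FALSE], na.rm = TRUE)
  ties <- which(mc == mn)
  if (length(ties) > 0L) {
    warning("pathway(s) with equal group means assigned to P_n: ",
            paste(colnames(weights)[ties], collapse = ", "))
  }
  structure(list(p_c = colnames(weights)[mc > mn],
                 p_n = colnames(weights)[mc <= mn]),
            class = "direction_assignment")
}

#' Pathway-ratio prognosis score per patient
#'
#' `score_i = sum of P_c weights / sum of P_n weights`: the relative
#' utilization of cancer-associated versus normal-associated pathways.
#' Missing weights count as 0; a patient with a zero denominator gets `NA`
#' and is excluded downstream (with a message).
#'
#' @param weights Patients x pathways matrix.
#' @param dirs A `direction_assignment`.
#' @return Named numeric vector of scores.
#' @export
patient_scores <- function(weights, dirs) {
  if (length(dirs$p_n) == 0L) stop("P_n is empty; scores undefined")
  w <- weights
  w[is.na(w)] <- 0
  num <- rowSums(w[, intersect(dirs$p_c, colnames(w)), drop = FALSE])
  den <- rowSums(w[, intersect(dirs$p_n, colnames(w)), drop = FALSE])
  s <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(s)) {
    message(sum(is.na(s)), " patient(s) with zero P_n weight excluded")
  }
  stats::setNames(s, rownames(weights))
}

# Area under a Kaplan-Meier step curve up to horizon tau, carrying the
# last estimate forward beyond the final observation.
km_area <- function(time, surv, tau) {
  keep <- time <= tau
  tm <- c(0, time[keep], tau)
  sv <- c(1, surv[keep])
  sum(diff(tm) * sv)
}

#' Kaplan-Meier comparison of score extremes
#'
#' Compares the survival of the patients with the top `fraction` of
#' scores (predicted worst prognosis) against the bottom `fraction`
#' (predicted best prognosis): Kaplan-Meier curves, a two-group log-rank
#' test, and the delta-AUC — the normalized area between the two survival
#' step functions over the common follow-up horizon (the latest observed
#' time across both groups): the area under the better-surviving curve
#' minus the other, divided by the horizon, so it is nonnegative and 0
#' when the curves coincide.
#'
#' @param scores Named numeric patient scores (`NA` excluded).
#' @param surv Data frame: patient, time, event.
#' @param fraction Tail fraction per extreme group, in (0, 0.5]
#'   (default 0.10).
#' @return List: `logrank_chisq`, `logrank_p`, `delta_auc`, `groups`
#'   (patient ids per extreme), `fit` (the `survfit` object).
#' @export
km_extremes <- function(scores, surv, fraction = 0.10) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  surv <- check_survival(surv)
  scores <- scores[!is.na(scores)]
  shared <- intersect(names(scores), surv$patient)
  scores <- scores[shared]
  n_ext <- floor(length(scores) * fraction)
  if (n_ext < 2L) stop("fewer than 2 patients per extreme group")
  ord <- order(scores, names(scores))  # deterministic tie-break by id
  bottom <- names(scores)[ord][seq_len(n_ext)]
  top <- rev(names(scores)[ord])[seq_len(n_ext)]
  sub <- surv[match(c(top, bottom), surv$patient), ]
  grp <- factor(rep(c("top", "bottom"), each = n_ext),
                levels = c("bottom", "top"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, data = sub)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = sub)
  tau <- max(sub$time)
  strata <- rep(names(fit$strata), fit$strata)
  area <- vapply(levels(grp), function(g) {
    idx <- strata == paste0("grp=", g)
    km_area(fit$time[idx], fit$surv[idx], tau)
  }, numeric(1))
  list(logrank_chisq = unname(sd_$chisq), logrank_p = p,
       delta_auc = unname(abs(area["bottom"] - area["top"])) / tau,
       groups = list(top = top, bottom = bottom), fit = fit)
}

#' Per-pathway survival screening with FDR control
#'
#' For every pathway, patients in the top versus bottom `fraction` of that
#' pathway's weights are compared by log-rank test; Benjamini-Hochberg
#' controls the FDR over the pathway family.
#'
#' @param weights Patients x pathways matrix.
#' @param surv Data frame: patient, time, event.
#' @param fraction Tail fraction (default 0.10).
#' @param alpha FDR level (default 0.05).
#' @return Data frame: pathway, logrank_p, fdr, significant.
#' @export
per_pathway_km <- function(weights, surv, fraction = 0.10, alpha = 0.05) {
  if (ncol(weights) < 2L) stop("need at least 2 pathways")
  surv <- check_survival(surv)
  p <- vapply(colnames(weights), function(pw) {
    sc <- weights[, pw]
    names(sc) <- rownames(weights)
    res <- tryCatch(km_extremes(sc, surv, fraction), error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$logrank_p
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(pathway = colnames(weights), logrank_p = unname(p),
                    fdr = unname(fdr),
                    significant = !is.na(fdr) & fdr < alpha)
  rownames(out) <- NULL
  out
}

#' Harrell-type concordance index of a risk score
#'
#' The fraction of comparable patient pairs (the earlier failure time is
#' an observed event and the times differ) in which the higher score
#' precedes in failure time; score ties count 0.5. A value of 0.5 is
#' chance, 1 is perfect risk ordering.
#'
#' @param scores Named numeric scores (higher = higher predicted risk).
#' @param surv Data frame: patient, time, event.
#' @return Numeric scalar in \[0, 1\].
#' @export
concordance_index <- function(scores, surv) {
  surv <- check_survival(surv)
  scores <- scores[!is.na(scores)]
  shared <- intersect(names(scores), surv$patient)
  s <- scores[shared]
  idx <- match(shared, surv$patient)
  tm <- surv$time[idx]; ev <- surv$event[idx]
  n <- length(s)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (ev[i] != 1) next
    later <- tm > tm[i]
    comp <- comp + sum(later)
    conc <- conc + sum(s[i] > s[later]) + 0.5 * sum(s[i] == s[later])
  }
  if (comp == 0) stop("no comparable pair; concordance undefined")
  conc / comp
}

#' Correlation between classification and survival predictive power
#'
#' Spearman correlation (with tie handling) between per-pathway
#' classification performance (e.g. cross-validation AUC) and per-pathway
#' survival performance (e.g. concordance index) over matched pathways.
#'
#' @param class_perf,surv_perf Numeric vectors, matched by position or by
#'   names.
#' @return List: `rho`, `p`.
#' @export
classification_survival_correlation <- function(class_perf, surv_perf) {
  if (!is.null(names(class_perf)) && !is.null(names(surv_perf))) {
    shared <- intersect(names(class_perf), names(surv_perf))
    class_perf <- class_perf[shared]
    surv_perf <- surv_perf[shared]
  }
  if (length(class_perf) < 3L) stop("need at least 3 matched pathways")
  ct <- suppressWarnings(stats::cor.test(class_perf, surv_perf,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Canonical-pathway enrichment of composite-pathway reactions
#'
#' One-sided hypergeometric test per canonical pathway: the universe is
#' the model's pathway-labeled reactions, the draw is the union of
#' reactions participating in the composite pathways, and enrichment asks
#' whether a canonical pathway contributes more reactions to that union
#' than expected. Bonferroni correction over the pathway family.
#'
#' @param composite_reactions Character vector of reaction ids (e.g.
#'   [composite_reaction_union()]).
#' @param model A `metabolic_model`.
#' @param alpha Family significance level (default 0.05).
#' @return Data frame: pathway, n_pathway, n_overlap, p, p_adjusted,
#'   significant.
#' @export
canonical_enrichment <- function(composite_reactions, model, alpha = 0.05) {
  pw <- vapply(model$reactions, `[[`, character(1), "pathway")
  pw <- pw[!is.na(pw)]
  universe <- names(pw)
  draw <- intersect(unique(composite_reactions), universe)
  if (length(draw) == 0L) stop("composite reaction set is empty (or outside the labeled universe)")
  labels <- sort(unique(pw))
  res <- do.call(rbind, lapply(labels, function(lb) {
    members <- names(pw)[pw == lb]
    x <- length(intersect(draw, members))
    p <- stats::phyper(x - 1, length(members),
                       length(universe) - length(members), length(draw),
                       lower.tail = FALSE)
    data.frame(pathway = lb, n_pathway = length(members), n_overlap = x,
               p = p)
  }))
  res$p_adjusted <- pmin(res$p * length(labels), 1)
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}
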