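# Rank transformation, GPR evaluation to reaction expression, differential
# reaction detection, and canonical pathway expression.

#' Rank-transform an expression matrix within each sample
#'
#' Within every sample (column), gene values are replaced by ascending
#' midranks: the most highly expressed gene receives rank G (the number of
#' genes), ties share their average rank. Ranking makes samples comparable
#' across platforms and is the unit carried through all downstream graph
#' weights.
#'
#' @param expr Numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @return Matrix of the same shape holding per-sample midranks.
#' @export
rank_transform <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes to rank")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  bad <- which(!is.finite(expr), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cells <- apply(utils::head(bad, 5L), 1L, function(ij)
      paste0(rownames(expr)[ij[1]], "/", colnames(expr)[ij[2]]))
    stop("non-finite expression values, e.g. at: ", paste(cells, collapse = ", "))
  }
  apply(expr, 2L, rank, ties.method = "average")
}

#' Convert ranked gene expression to reaction expression via GPR rules
#'
#' Evaluates every reaction's GPR rule on each sample's gene ranks,
#' replacing `and` with `min` and `or` with `max`. Genes absent from the
#' matrix are dropped at each node; a reaction with an empty rule or no
#' measured gene is marked absent (`NA`).
#'
#' @param ranked Matrix from [rank_transform()].
#' @param model A `metabolic_model`.
#' @return Numeric matrix, reactions x samples; `NA` marks absent
#'   reactions.
#' @export
reactions_from_genes <- function(ranked, model) {
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  out <- matrix(NA_real_, nrow = length(rids), ncol = ncol(ranked),
                dimnames = list(rids, colnames(ranked)))
  gene_rows <- rownames(ranked)
  for (r in model$reactions) {
    if (is.null(r$gpr)) next
    genes <- intersect(gpr_genes(r$gpr), gene_rows)
    if (length(genes) == 0L) next
    sub <- ranked[genes, , drop = FALSE]
    out[r$id, ] <- vapply(seq_len(ncol(sub)), function(j) {
      vals <- sub[, j]
      names(vals) <- genes  # 1-row matrices drop names on extraction
      gpr_eval(r$gpr, vals)
    }, numeric(1))
  }
  if (all(is.na(out))) stop("no reaction is evaluable from the given genes")
  out
}

# Wilcoxon rank-sum two-sided p-value: exact null when both groups have at
# most `exact_max` observations and no ties straddle groups; tie-corrected
# normal approximation (no continuity correction) otherwise.
ranksum_p <- function(x, y, exact_max = 6L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) return(NA_real_)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE)$p.value)
  if (is.na(p)) p <- 1  # all values tied: no evidence of a shift
  min(p, 1)
}

#' Detect differentially expressed reactions
#'
#' Two-sided Wilcoxon rank-sum test of each reaction's expression between
#' the two sample classes. The null is exact for group sizes up to 6
#' without ties and a tie-corrected normal approximation otherwise.
#'
#' @param rxn Reaction x sample matrix from [reactions_from_genes()].
#' @param labels Character/factor vector (named by sample or aligned to
#'   columns) with exactly two classes, conventionally `"cancer"` and
#'   `"normal"`.
#' @param alpha Significance level (default 0.05).
#' @param correction `"bonferroni"` or `"none"`; applied before comparing
#'   to `alpha`.
#' @return Data frame (class `differential_reactions`): reaction, p,
#'   p_adjusted, significant. Absent reactions are excluded from testing
#'   and from the correction family.
#' @export
differential_reactions <- function(rxn, labels, alpha = 0.05,
                                   correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  labels <- align_labels(labels, colnames(rxn))
  classes <- unique(labels)
  if (length(classes) != 2L) stop("labels must contain exactly two classes")
  if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
  g1 <- labels == classes[1]
  tested <- rownames(rxn)[rowSums(!is.na(rxn)) > 0L]
  p <- vapply(tested, function(rid)
    ranksum_p(rxn[rid, g1], rxn[rid, !g1]), numeric(1))
  p_adj <- stats::p.adjust(p, method = if (correction == "bonferroni")
    "bonferroni" else "none")
  res <- data.frame(reaction = tested, p = unname(p),
                    p_adjusted = unname(p_adj),
                    significant = unname(p_adj < alpha))
  rownames(res) <- NULL
  class(res) <- c("differential_reactions", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "correction") <- correction
  res
}

#' Ids of the significant reactions in a differential set
#'
#' @param de A `differential_reactions` result (or `NULL`).
#' @return Character vector of reaction ids.
#' @export
significant_reactions <- function(de) {
  if (is.null(de)) return(character())
  de$reaction[de$significant]
}

#' Aggregate reaction expression into canonical pathway expression
#'
#' Each canonical pathway's expression in a sample is the sum (or mean) of
#' the ranks of its member reactions; absent reactions are skipped. A
#' pathway with no evaluable reaction is emitted as all-`NA` with a
#' warning.
#'
#' @param rxn Reaction x sample matrix.
#' @param model A `metabolic_model`.
#' @param aggregator `"sum"` (default, the better-performing variant) or
#'   `"mean"`.
#' @return Matrix, pathway labels x samples.
#' @export
pathway_expression <- function(rxn, model, aggregator = c("sum", "mean")) {
  aggregator <- match.arg(aggregator)
  pw <- vapply(model$reactions, `[[`, character(1), "pathway")
  labels <- sort(unique(stats::na.omit(pw)))
  if (length(labels) == 0L) stop("model has no pathway labels")
  out <- matrix(NA_real_, nrow = length(labels), ncol = ncol(rxn),
                dimnames = list(labels, colnames(rxn)))
  agg <- if (aggregator == "sum") {
    function(m) colSums(m, na.rm = TRUE)
  } else {
    function(m) colMeans(m, na.rm = TRUE)
  }
  empty <- character()
  for (lb in labels) {
    members <- intersect(names(pw)[!is.na(pw) & pw == lb], rownames(rxn))
    m <- rxn[members, , drop = FALSE]
    if (nrow(m) == 0L || all(is.na(m))) {
      empty <- c(empty, lb)
      next
    }
    v <- agg(m)
    # columns where every member is absent stay missing rather than 0
    v[colSums(!is.na(m)) == 0L] <- NA_real_
    out[lb, ] <- v
  }
  if (length(empty) > 0L) {
    warning("pathway(s) with no evaluable reaction: ",
            paste(empty, collapse = ", "))
  }
  out
}

#' Weight the metabolite graph with one sample's reaction ranks
#'
#' Every edge receives the expression rank of its reaction in the given
#' sample; edges of absent reactions are dropped, yielding the
#' patient-specific weighted metabolic network the path search runs on.
#'
#' @param graph A `metabolite_graph` from [to_digraph()].
#' @param rxn Reaction x sample matrix.
#' @param sample Sample id (column of `rxn`).
#' @return A `metabolite_graph` whose `edges` gain a `weight` column.
#' @export
sample_weighted_graph <- function(graph, rxn, sample) {
  if (!sample %in% colnames(rxn)) stop("unknown sample id: ", sample)
  w <- rxn[graph$edges$reaction, sample]
  keep <- !is.na(w)
  edges <- graph$edges[keep, , drop = FALSE]
  edges$weight <- unname(w[keep])
  rownames(edges) <- NULL
  structure(list(nodes = graph$nodes, edges = edges),
            class = "metabolite_graph")
}

# Align a (possibly named) label vector to a set of sample ids.
align_labels <- function(labels, sample_ids) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels)) && all(nzchar(names(labels)))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing) > 0L) {
      stop("labels missing for sample(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("unnamed labels must match the number of samples")
  } else {
    names(labels) <- sample_ids
  }
  labels
}

#' Concatenate rank-transformed cohorts on their shared genes
#'
#' Cross-cohort merging: each cohort is rank-transformed separately (ranks
#' are the unit that survives platform differences), restricted to the gene
#' intersection, and the columns concatenated.
#'
#' @param ... Two or more genes x samples matrices of raw expression.
#' @return A single ranked matrix over the shared genes.
#' @export
merge_cohorts_ranked <- function(...) {
  mats <- list(...)
  if (length(mats) < 2L) stop("need at least two cohorts to merge")
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < 2L) stop("fewer than 2 shared genes across cohorts")
  ranked <- lapply(mats, function(m) rank_transform(m[shared, , drop = FALSE]))
  do.call(cbind, ranked)
}
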