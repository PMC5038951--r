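# Composite-pathway discovery: seed reporter metabolites, heaviest
# simple-path distances on per-sample weighted metabolite graphs, and
# selection of maximally differential target metabolites.

#' Configuration for the heaviest simple-path search
#'
#' Finding the heaviest simple path is NP-hard (it subsumes longest path),
#' so the search is budgeted. `exact_bounded` enumerates all simple paths
#' of at most `max_depth` edges by depth-first search and is exact within
#' that budget; `beam` keeps only the `beam_width` heaviest partial paths
#' per depth and is a faster lower bound.
#'
#' @param strategy `"exact_bounded"` or `"beam"`.
#' @param max_depth Maximum number of edges in a path (default 6:
#'   composite pathways of up to six reactions stay interpretable and
#'   tractable on genome-scale graphs).
#' @param beam_width Beam size for `strategy = "beam"` (default 50).
#' @param restrict_first_hop_to_de If `TRUE` (default), the first reaction
#'   of every path must be differentially expressed — the tractability
#'   restriction that pairs with seed selection.
#' @param record_paths Keep the edge (reaction) sequence realizing each
#'   best distance (needed for [extract_pathway_reactions()]).
#' @return A `search_config` list.
#' @export
search_config <- function(strategy = c("exact_bounded", "beam"),
                          max_depth = 6L, beam_width = 50L,
                          restrict_first_hop_to_de = TRUE,
                          record_paths = FALSE) {
  strategy <- match.arg(strategy)
  max_depth <- as.integer(max_depth)
  beam_width <- as.integer(beam_width)
  if (max_depth < 1L) stop("max_depth must be >= 1")
  if (beam_width < 1L) stop("beam_width must be >= 1")
  structure(list(strategy = strategy, max_depth = max_depth,
                 beam_width = beam_width,
                 restrict_first_hop_to_de = restrict_first_hop_to_de,
                 record_paths = record_paths),
            class = "search_config")
}

#' Identify seed reporter metabolites
#'
#' A seed is a metabolite that is a substrate in at least `k`
#' differentially expressed reactions; such reporter metabolites are hubs
#' of metabolic alteration and anchor the composite-path search. For
#' reversible reactions both sides count as substrates.
#'
#' @param de A `differential_reactions` result.
#' @param model A `metabolic_model`.
#' @param k Minimum number of significant reactions (default 5).
#' @return Data frame (class `seed_set`): metabolite, count, selected;
#'   sorted by decreasing count then id.
#' @export
find_seeds <- function(de, model, k = 5L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  sig <- significant_reactions(de)
  substrate_sides <- lapply(model$reactions[intersect(sig, names(model$reactions))],
    function(r) {
      mets <- r$substrates$metabolite
      if (r$reversible) mets <- c(mets, r$products$metabolite)
      unique(mets)
    })
  tab <- table(unlist(substrate_sides))
  res <- data.frame(metabolite = as.character(names(tab)),
                    count = as.integer(tab))
  if (nrow(res) == 0L) {
    res <- data.frame(metabolite = character(), count = integer())
  }
  res <- res[order(-res$count, res$metabolite), , drop = FALSE]
  res$selected <- res$count >= k
  rownames(res) <- NULL
  class(res) <- c("seed_set", "data.frame")
  attr(res, "k") <- k
  res
}

#' Ids of the selected seed metabolites
#'
#' @param seeds A `seed_set` from [find_seeds()].
#' @return Character vector of metabolite ids passing the threshold.
#' @export
seed_ids <- function(seeds) seeds$metabolite[seeds$selected]

# Build an adjacency index from a weighted metabolite graph. Self-loops
# are dropped (never traversed); parallel edges between the same ordered
# pair are pruned to the heaviest (ties broken by reaction id) since with
# positive additive weights the heavier parallel edge dominates.
build_adjacency <- function(wg) {
  edges <- wg$edges
  if (is.null(edges$weight)) stop("graph is not weighted; use sample_weighted_graph()")
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) > 1L) {
    key <- paste(edges$from, edges$to, sep = "\r")
    ord <- order(key, -edges$weight, edges$reaction)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  nodes <- wg$nodes
  from_i <- match(edges$from, nodes)
  to_i <- match(edges$to, nodes)
  adj <- split(seq_len(nrow(edges)), factor(from_i, levels = seq_along(nodes)))
  list(nodes = nodes, n = length(nodes), adj = adj,
       to = to_i, weight = edges$weight, reaction = edges$reaction)
}

#' Heaviest simple-path distances from a seed metabolite
#'
#' Computes, for every metabolite reachable within the search budget, the
#' maximum over simple directed paths (no repeated metabolite) of the sum
#' of edge weights — each weight being the reaction's expression rank in
#' one sample. Optionally restricts the first edge to differentially
#' expressed reactions.
#'
#' @param wg A weighted `metabolite_graph` from [sample_weighted_graph()].
#' @param source Source metabolite id.
#' @param cfg A [search_config()].
#' @param first_hop Either a `differential_reactions` object or a character
#'   vector of admissible first-hop reaction ids; `NULL` disables the
#'   restriction regardless of `cfg$restrict_first_hop_to_de`.
#' @return A `heaviest_distances` list: `source`; `distances`, a named
#'   numeric vector over all nodes (`NA` = not reached); and, when
#'   `cfg$record_paths`, `paths`, a named list of reaction-id sequences
#'   realizing each distance.
#' @export
heaviest_distances <- function(wg, source, cfg = search_config(),
                               first_hop = NULL) {
  if (!source %in% wg$nodes) stop("source metabolite not in graph: ", source)
  g <- build_adjacency(wg)
  src <- match(source, g$nodes)
  allowed_first <- NULL
  if (cfg$restrict_first_hop_to_de && !is.null(first_hop)) {
    sig <- if (inherits(first_hop, "differential_reactions"))
      significant_reactions(first_hop) else as.character(first_hop)
    allowed_first <- g$reaction %in% sig
  }
  res <- if (cfg$strategy == "exact_bounded") {
    hd_exact(g, src, cfg$max_depth, allowed_first, cfg$record_paths)
  } else {
    hd_beam(g, src, cfg$max_depth, cfg$beam_width, allowed_first,
            cfg$record_paths)
  }
  dist <- res$best
  dist[dist == -Inf] <- NA_real_
  names(dist) <- g$nodes
  out <- list(source = source, distances = dist, config = cfg)
  if (cfg$record_paths) {
    paths <- lapply(res$path_edges, function(eids)
      if (is.null(eids)) NULL else g$reaction[eids])
    names(paths) <- g$nodes
    out$paths <- paths
  }
  structure(out, class = "heaviest_distances")
}

# Exhaustive DFS over simple paths of <= max_depth edges.
hd_exact <- function(g, src, max_depth, allowed_first, record) {
  best <- rep(-Inf, g$n)
  path_edges <- vector("list", g$n)
  visited <- logical(g$n)
  visited[src] <- TRUE
  edge_stack <- integer(max_depth)
  dfs <- function(node, depth, weight) {
    for (e in g$adj[[node]]) {
      if (depth == 0L && !is.null(allowed_first) && !allowed_first[e]) next
      v <- g$to[e]
      if (visited[v]) next
      w2 <- weight + g$weight[e]
      edge_stack[depth + 1L] <<- e
      if (w2 > best[v]) {
        best[v] <<- w2
        if (record) path_edges[[v]] <<- edge_stack[seq_len(depth + 1L)]
      }
      if (depth + 1L < max_depth) {
        visited[v] <<- TRUE
        dfs(v, depth + 1L, w2)
        visited[v] <<- FALSE
      }
    }
  }
  dfs(src, 0L, 0)
  list(best = best, path_edges = path_edges)
}

# Breadth-limited search: keep the beam_width heaviest partial simple
# paths per depth. Deterministic: ties ordered by the node sequence.
hd_beam <- function(g, src, max_depth, beam_width, allowed_first, record) {
  best <- rep(-Inf, g$n)
  path_edges <- vector("list", g$n)
  beam <- list(list(nodes = src, edges = integer(0), weight = 0))
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (p in beam) {
      tip <- p$nodes[length(p$nodes)]
      for (e in g$adj[[tip]]) {
        if (depth == 1L && !is.null(allowed_first) && !allowed_first[e]) next
        v <- g$to[e]
        if (v %in% p$nodes) next
        w2 <- p$weight + g$weight[e]
        q <- list(nodes = c(p$nodes, v), edges = c(p$edges, e), weight = w2)
        nxt[[length(nxt) + 1L]] <- q
        if (w2 > best[v]) {
          best[v] <- w2
          if (record) path_edges[[v]] <- q$edges
        }
      }
    }
    if (length(nxt) == 0L) break
    if (length(nxt) > beam_width) {
      w <- vapply(nxt, `[[`, numeric(1), "weight")
      key <- vapply(nxt, function(p) paste(p$nodes, collapse = ","), character(1))
      nxt <- nxt[order(-w, key)[seq_len(beam_width)]]
    }
    beam <- nxt
  }
  list(best = best, path_edges = path_edges)
}

#' Select the most differential target metabolites for a seed
#'
#' For every candidate target the heaviest distances from the seed are
#' compared between cancer and normal samples with a two-sided Wilcoxon
#' rank-sum test; the `L` targets with the smallest p-values form the
#' seed's composite pathways. Unreachable distances enter the feature
#' matrix as 0 ("no expressed route"); targets reachable in fewer than
#' `coverage` of samples are ineligible. Ties in p are broken
#' lexicographically by metabolite id.
#'
#' @param dist_mat Samples x metabolites matrix of heaviest distances
#'   (`NA` = unreachable), e.g. stacked [heaviest_distances()] results.
#' @param labels Two-class sample labels (named or aligned to rows).
#' @param L Number of targets to select (default 10).
#' @param seed_id Seed metabolite id (excluded from candidates; recorded).
#' @param coverage Minimum fraction of samples in which a target must be
#'   reachable (default 0.8).
#' @param exclude Optional metabolite ids never to select (e.g. currency
#'   metabolites).
#' @return A `composite_feature_set`: `seed`; `targets` data frame
#'   (target, p, direction); `features` samples x L matrix (0-filled);
#'   `missing` logical matrix of unreachability.
#' @export
select_targets <- function(dist_mat, labels, L = 10L, seed_id = NA_character_,
                           coverage = 0.8, exclude = character()) {
  L <- as.integer(L)
  labels <- align_labels(labels, rownames(dist_mat))
  if (length(unique(labels)) != 2L) stop("labels must contain exactly two classes")
  if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
  cancer <- labels == "cancer"
  if (!any(cancer)) {  # generic two-class fallback: first level plays "cancer"
    cancer <- labels == sort(unique(labels))[1]
  }
  cand <- setdiff(colnames(dist_mat), c(seed_id, exclude))
  reach <- colMeans(!is.na(dist_mat[, cand, drop = FALSE]))
  cand <- cand[reach >= coverage]
  if (length(cand) == 0L) stop("no eligible target metabolite (coverage filter)")
  filled <- dist_mat
  filled[is.na(filled)] <- 0
  p <- vapply(cand, function(t)
    ranksum_p(filled[cancer, t], filled[!cancer, t]), numeric(1))
  ord <- order(p, cand)
  if (length(cand) < L) {
    warning(sprintf("only %d eligible targets (< L = %d)", length(cand), L))
  }
  take <- ord[seq_len(min(L, length(cand)))]
  sel <- cand[take]
  direction <- vapply(sel, function(t) {
    if (mean(filled[cancer, t]) > mean(filled[!cancer, t]))
      "up_in_cancer" else "down_in_cancer"
  }, character(1))
  structure(list(
    seed = seed_id,
    targets = data.frame(target = sel, p = unname(p[take]),
                         direction = unname(direction), row.names = NULL),
    features = filled[, sel, drop = FALSE],
    missing = is.na(dist_mat[, sel, drop = FALSE])),
    class = "composite_feature_set")
}

#' @export
print.composite_feature_set <- function(x, ...) {
  cat(sprintf("Composite feature set: seed %s, %d targets, %d samples\n",
              x$seed, nrow(x$targets), nrow(x$features)))
  invisible(x)
}

# Stack per-sample heaviest-distance tables into a samples x nodes matrix
# (and optionally collect realized paths).
distance_matrix_for_seed <- function(graph, rxn, samples, seed, cfg, first_hop) {
  tabs <- lapply(samples, function(s) {
    wg <- sample_weighted_graph(graph, rxn, s)
    heaviest_distances(wg, seed, cfg, first_hop)
  })
  dist <- do.call(rbind, lapply(tabs, `[[`, "distances"))
  rownames(dist) <- samples
  paths <- if (cfg$record_paths) {
    stats::setNames(lapply(tabs, `[[`, "paths"), samples)
  } else NULL
  list(dist = dist, paths = paths)
}

#' Build composite-pathway feature sets for all seeds
#'
#' Runs the full discovery pipeline on labeled training data: detect
#' differentially expressed reactions, pick seed reporter metabolites,
#' compute per-sample heaviest distances from every seed, and select each
#' seed's L most differential targets. The returned feature sets carry the
#' training-fold differential reaction ids so that features can be
#' recomputed on unseen samples without touching their labels.
#'
#' @param model A `metabolic_model`.
#' @param graph Its [to_digraph()] transform.
#' @param rxn Reaction x sample expression from [reactions_from_genes()].
#' @param labels Two-class sample labels.
#' @param k Seed threshold (default 5).
#' @param L Targets per seed (default 10).
#' @param cfg A [search_config()].
#' @param alpha,correction Passed to [differential_reactions()] (defaults
#'   0.05, Bonferroni).
#' @param de Optional precomputed `differential_reactions` (must come from
#'   the same training samples).
#' @param coverage,exclude Passed to [select_targets()].
#' @return List of `composite_feature_set` (class `mcf_feature_sets`),
#'   one per selected seed, with the seed table and DE set as attributes.
#' @export
build_features <- function(model, graph, rxn, labels, k = 5L, L = 10L,
                           cfg = search_config(), alpha = 0.05,
                           correction = "bonferroni", de = NULL,
                           coverage = 0.8, exclude = character()) {
  labels <- align_labels(labels, colnames(rxn))
  if (length(unique(labels)) != 2L) stop("labels must contain exactly two classes")
  if (is.null(de)) {
    de <- differential_reactions(rxn, labels, alpha = alpha,
                                 correction = correction)
  }
  seeds <- find_seeds(de, model, k = k)
  sids <- seed_ids(seeds)
  if (length(sids) == 0L) {
    stop("no seed metabolites found at k = ", k,
         "; consider lowering k or relaxing the correction")
  }
  sig <- significant_reactions(de)
  samples <- colnames(rxn)
  out <- lapply(sids, function(sd) {
    dm <- distance_matrix_for_seed(graph, rxn, samples, sd, cfg, sig)
    fs <- select_targets(dm$dist, labels, L = L, seed_id = sd,
                         coverage = coverage, exclude = exclude)
    if (!is.null(dm$paths)) fs$paths <- dm$paths
    fs$first_hop <- sig
    fs
  })
  names(out) <- sids
  structure(out, class = "mcf_feature_sets", seeds = seeds, de = de)
}

#' Recompute a feature set's distance features on (possibly new) samples
#'
#' Applies a trained `composite_feature_set` to a reaction-expression
#' matrix: per sample, the heaviest distances from the stored seed to the
#' stored targets, with the training-time first-hop restriction.
#' Unreachable targets yield 0.
#'
#' @param fs A `composite_feature_set` from [build_features()].
#' @param graph A `metabolite_graph`.
#' @param rxn Reaction x sample matrix for the new samples.
#' @param cfg A [search_config()].
#' @param first_hop Override for the stored first-hop reaction set; pass
#'   `NULL` inside `cfg` handling to disable.
#' @return List: `features` (samples x L, 0-filled), `missing`, `paths`
#'   (when recorded).
#' @export
compute_features <- function(fs, graph, rxn, cfg = search_config(),
                             first_hop = fs$first_hop) {
  samples <- colnames(rxn)
  dm <- distance_matrix_for_seed(graph, rxn, samples, fs$seed, cfg, first_hop)
  dist <- dm$dist[, fs$targets$target, drop = FALSE]
  filled <- dist
  filled[is.na(filled)] <- 0
  list(features = filled, missing = is.na(dist), paths = dm$paths)
}

#' Reactions realizing the composite pathways
#'
#' Returns, per (seed, target, sample), the set of reaction ids on the
#' realized heaviest path. Requires the distances to have been computed
#' with `record_paths = TRUE`.
#'
#' @param fs A `composite_feature_set` with recorded paths, or an
#'   `mcf_feature_sets` list of them.
#' @return Data frame: seed, target, sample, reactions
#'   (comma-separated reaction ids; empty for unreachable targets).
#' @export
extract_pathway_reactions <- function(fs) {
  if (inherits(fs, "mcf_feature_sets")) {
    return(do.call(rbind, lapply(fs, extract_pathway_reactions)))
  }
  if (is.null(fs$paths)) {
    stop("no recorded paths; rerun with search_config(record_paths = TRUE)")
  }
  rows <- list()
  for (s in names(fs$paths)) {
    for (t in fs$targets$target) {
      rxns <- fs$paths[[s]][[t]]
      rows[[length(rows) + 1L]] <- data.frame(
        seed = fs$seed, target = t, sample = s,
        reactions = paste(rxns, collapse = ","))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Union of reactions over composite pathways
#'
#' @param path_df Output of [extract_pathway_reactions()].
#' @return Character vector of distinct reaction ids.
#' @export
composite_reaction_union <- function(path_df) {
  unique(unlist(strsplit(path_df$reactions[nzchar(path_df$reactions)], ",",
                         fixed = TRUE)))
}
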