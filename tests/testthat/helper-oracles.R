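# Independent brute-force oracles used to validate the package's search
# and GPR machinery. These deliberately share no code with the package:
# plain recursive enumeration, no pruning, no adjacency indexing.

# Best simple-path weight from `source` to every node by exhaustive
# enumeration of all simple paths with at most `max_depth` edges.
oracle_heaviest <- function(edges, nodes, source, max_depth,
                            allowed_first = NULL) {
  best <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  recurse <- function(node, seen, weight, depth) {
    out <- edges[edges$from == node & edges$from != edges$to, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      if (depth == 0 && !is.null(allowed_first) &&
          !(out$reaction[i] %in% allowed_first)) next
      v <- out$to[i]
      if (v %in% seen) next
      w <- weight + out$weight[i]
      if (is.na(best[v]) || w > best[v]) best[v] <<- w
      if (depth + 1 < max_depth) recurse(v, c(seen, v), w, depth + 1)
    }
  }
  recurse(source, source, 0, 0)
  best
}

# Random weighted digraph as a bare edge table.
random_weighted_graph <- function(n_nodes, edge_prob = 0.18,
                                  weight_max = 20) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < edge_prob
  edges <- pairs[keep, , drop = FALSE]
  edges$reaction <- sprintf("r%03d", seq_len(nrow(edges)))
  edges$weight <- round(runif(nrow(edges), 1, weight_max), 3)
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

as_weighted_graph <- function(g) {
  structure(list(nodes = g$nodes, edges = g$edges),
            class = "metabolite_graph")
}

# Independent recursive evaluator over GPR trees built directly as nested
# lists (never routed through parse_gpr).
oracle_gpr_eval <- function(tree, values) {
  if (!is.null(tree$gene)) {
    v <- unname(values[tree$gene])
    if (length(v) == 0 || is.na(v)) return(NA_real_)
    return(v)
  }
  vals <- numeric(0)
  for (a in tree$args) {
    v <- oracle_gpr_eval(a, values)
    if (!is.na(v)) vals <- c(vals, v)
  }
  if (length(vals) == 0) return(NA_real_)
  if (tree$op == "and") min(vals) else max(vals)
}

# Random GPR tree of bounded depth over a gene pool; returns both the
# nested-list tree and an equivalent rule string.
random_gpr <- function(genes, depth) {
  if (depth == 0 || runif(1) < 0.4) {
    g <- sample(genes, 1)
    return(list(tree = list(gene = g), text = g))
  }
  op <- sample(c("and", "or"), 1)
  n_args <- sample(2:3, 1)
  kids <- lapply(seq_len(n_args), function(i) random_gpr(genes, depth - 1))
  list(tree = list(op = op, args = lapply(kids, `[[`, "tree")),
       text = paste0("(", paste(vapply(kids, `[[`, character(1), "text"),
                                collapse = paste0(" ", op, " ")), ")"))
}

# Exact two-sided rank-sum p-value by complete enumeration of group
# assignments (small n only).
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  obs <- sum(rank(pooled)[seq_len(m)])
  combos <- utils::combn(n, m)
  r <- rank(pooled)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- m * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
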