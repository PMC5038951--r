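test_that("heaviest distances solve hand-checkable graphs", {
  # line s -> a (2) -> b (3)
  line <- as_weighted_graph(list(
    nodes = c("s", "a", "b"),
    edges = data.frame(from = c("s", "a"), to = c("a", "b"),
                       reaction = c("r_sa", "r_ab"), weight = c(2, 3))))
  hd <- heaviest_distances(line, "s", search_config(record_paths = TRUE))
  expect_equal(hd$distances[["b"]], 5)
  expect_equal(hd$paths[["b"]], c("r_sa", "r_ab"))

  # diamond: s->a->t = 6 vs s->b->t = 12
  hd2 <- heaviest_distances(diamond_graph(), "s",
                            search_config(record_paths = TRUE))
  expect_equal(hd2$distances[["t"]], 12)
  expect_equal(hd2$paths[["t"]], c("r_sb", "r_bt"))

  # cycle: the s->a->s loop is never extended
  cyc <- as_weighted_graph(list(
    nodes = c("s", "a", "t"),
    edges = data.frame(from = c("s", "a", "a"), to = c("a", "s", "t"),
                       reaction = c("r1", "r2", "r3"), weight = c(1, 1, 1))))
  hd3 <- heaviest_distances(cyc, "s", search_config())
  expect_equal(hd3$distances[["t"]], 2)
  expect_true(is.na(hd3$distances[["s"]]))

  expect_error(heaviest_distances(line, "zz"), "not in graph")
})

test_that("exact bounded search equals exhaustive simple-path enumeration", {
  set.seed(101)
  cfg <- search_config(max_depth = 11, restrict_first_hop_to_de = FALSE)
  for (i in 1:200) {
    g <- random_weighted_graph(sample(5:12, 1))
    src <- g$nodes[1]
    got <- heaviest_distances(as_weighted_graph(g), src, cfg)$distances
    want <- oracle_heaviest(g$edges, g$nodes, src, 11)
    expect_equal(got, want)
  }
})

test_that("first-hop restriction limits paths to differential openings", {
  g <- diamond_graph()
  hd <- heaviest_distances(g, "s", search_config(), first_hop = "r_sa")
  expect_equal(hd$distances[["t"]], 6)  # s->b blocked despite being heavier
  expect_true(is.na(hd$distances[["b"]]))
  # no admissible first hop: empty table, not an error
  hd2 <- heaviest_distances(g, "s", search_config(), first_hop = character(0))
  expect_true(all(is.na(hd2$distances)))
})

test_that("parallel edges resolve to the heavier reaction", {
  g <- as_weighted_graph(list(
    nodes = c("a", "c"),
    edges = data.frame(from = c("a", "a"), to = c("c", "c"),
                       reaction = c("r10", "r30"), weight = c(10, 30))))
  hd <- heaviest_distances(g, "a", search_config(record_paths = TRUE))
  expect_equal(hd$distances[["c"]], 30)
  expect_equal(hd$paths[["c"]], "r30")
})

test_that("self-loop edges are never traversed", {
  g <- as_weighted_graph(list(
    nodes = c("a", "b"),
    edges = data.frame(from = c("a", "a"), to = c("a", "b"),
                       reaction = c("r_loop", "r_ab"), weight = c(100, 1))))
  hd <- heaviest_distances(g, "a", search_config(record_paths = TRUE))
  expect_equal(hd$distances[["b"]], 1)
  expect_equal(hd$paths[["b"]], "r_ab")
})

test_that("beam search lower-bounds the exact optimum and usually matches it", {
  set.seed(202)
  exact_cfg <- search_config(max_depth = 6, restrict_first_hop_to_de = FALSE)
  beam_cfg <- search_config(strategy = "beam", max_depth = 6, beam_width = 50,
                            restrict_first_hop_to_de = FALSE)
  match_frac <- numeric(0)
  for (i in 1:10) {
    g <- random_weighted_graph(30, edge_prob = 0.10)
    src <- g$nodes[1]
    wg <- as_weighted_graph(g)
    ex <- heaviest_distances(wg, src, exact_cfg)$distances
    bm <- heaviest_distances(wg, src, beam_cfg)$distances
    reached <- !is.na(ex)
    expect_true(all(is.na(bm[reached]) | bm[reached] <= ex[reached] + 1e-9))
    match_frac <- c(match_frac,
                    mean(!is.na(bm[reached]) & abs(bm[reached] - ex[reached]) < 1e-9))
  }
  expect_gte(mean(match_frac), 0.9)
})

test_that("adding an edge never decreases an exact bounded distance", {
  set.seed(303)
  cfg <- search_config(max_depth = 6, restrict_first_hop_to_de = FALSE)
  for (i in 1:20) {
    g <- random_weighted_graph(10)
    src <- g$nodes[1]
    base <- heaviest_distances(as_weighted_graph(g), src, cfg)$distances
    pair <- sample(g$nodes, 2)
    g$edges <- rbind(g$edges, data.frame(from = pair[1], to = pair[2],
                                         reaction = "r_new",
                                         weight = runif(1, 1, 20)))
    more <- heaviest_distances(as_weighted_graph(g), src, cfg)$distances
    ok <- is.na(base) | (!is.na(more) & more >= base - 1e-9)
    expect_true(all(ok))
  }
})

test_that("seed selection counts substrate roles in significant reactions", {
  # ATP feeds 7 significant reactions, H2O feeds 3
  df <- data.frame(
    from = c(rep("atp_c", 7), rep("h2o_c", 3)),
    to = sprintf("m%02d_c", 1:10))
  model <- edges_model(df)
  de <- data.frame(reaction = sprintf("r%02d", 1:10),
                   p = 1e-6, p_adjusted = 1e-4,
                   significant = TRUE)
  class(de) <- c("differential_reactions", "data.frame")
  seeds <- find_seeds(de, model, k = 5)
  expect_equal(seed_ids(seeds), "atp_c")
  expect_equal(seeds$count[seeds$metabolite == "atp_c"], 7L)
  expect_equal(seeds$count[seeds$metabolite == "h2o_c"], 3L)

  # threshold boundary: count == k selects, count == k - 1 does not
  expect_true("h2o_c" %in% seed_ids(find_seeds(de, model, k = 3)))
  expect_false("h2o_c" %in% seed_ids(find_seeds(de, model, k = 4)))
  expect_error(find_seeds(de, model, k = 0), "k must be")

  # reversible reactions count products as substrates too
  model$reactions$r01$reversible <- TRUE
  seeds_rev <- find_seeds(de, model, k = 1)
  expect_true("m01_c" %in% seeds_rev$metabolite)
})

test_that("target selection ranks by rank-sum p with lexicographic ties", {
  set.seed(1)
  samples <- sprintf("s%d", 1:6)
  labels <- setNames(rep(c("normal", "cancer"), each = 3), samples)
  dist_mat <- cbind(
    t_sep = c(1, 2, 3, 10, 11, 12),    # perfectly separated
    t_same = c(4, 5, 6, 4, 5, 6),      # identical distributions
    t_null = c(6, 4, 5, 5, 6, 4))      # identical values, tie case
  rownames(dist_mat) <- samples
  fs <- select_targets(dist_mat, labels, L = 3, seed_id = "seed")
  expect_equal(fs$targets$target[1], "t_sep")
  expect_equal(fs$targets$p[1], 2 / 20, tolerance = 1e-12)
  # equal p -> lexicographically smaller id first
  expect_equal(fs$targets$target[2:3], c("t_null", "t_same"))
  expect_equal(fs$targets$direction[1], "up_in_cancer")

  # reversed direction
  dist_rev <- dist_mat[, "t_sep", drop = FALSE][6:1, , drop = FALSE]
  rownames(dist_rev) <- samples
  fs2 <- select_targets(dist_rev, labels, L = 1, seed_id = "seed")
  expect_equal(fs2$targets$direction[1], "down_in_cancer")

  # L larger than eligible targets -> all returned with warning
  expect_warning(fs3 <- select_targets(dist_mat, labels, L = 10,
                                       seed_id = "seed"),
                 "eligible targets")
  expect_equal(nrow(fs3$targets), 3L)
})

test_that("coverage filter drops rarely reachable targets and 0-fills the rest", {
  samples <- sprintf("s%d", 1:10)
  labels <- setNames(rep(c("normal", "cancer"), each = 5), samples)
  dist_mat <- cbind(ok = c(1:4, NA, 6:10),          # 90% reachable
                    rare = c(NA, NA, NA, 4, NA, NA, NA, NA, 9, NA))
  rownames(dist_mat) <- samples
  fs <- suppressWarnings(select_targets(dist_mat, labels, L = 5,
                                        seed_id = "seed", coverage = 0.8))
  expect_equal(fs$targets$target, "ok")
  expect_equal(unname(fs$features[5, "ok"]), 0)  # unreachable -> 0 feature
  expect_true(fs$missing[5, "ok"])
  expect_error(select_targets(dist_mat[, "rare", drop = FALSE], labels,
                              L = 2, seed_id = "s"),
               "no eligible target")
})

test_that("feature discovery recovers the planted seed and its chains", {
  st <- planted_study(seed = 0L)
  planted <- attr(st$model, "planted")
  fsets <- build_features(st$model, st$graph, st$rxn, st$sim$labels)
  expect_true(planted$seed_metabolite %in% names(fsets))
  fs <- fsets[[planted$seed_metabolite]]
  expect_equal(nrow(fs$targets), 10L)
  expect_equal(dim(fs$features), c(100L, 10L))
  # all selected targets lie on the planted chains
  chain_nodes <- setdiff(unique(c(st$graph$edges$to[
    st$graph$edges$reaction %in% planted$reactions])), planted$seed_metabolite)
  expect_true(all(fs$targets$target %in% chain_nodes))
  expect_true(all(fs$targets$direction == "up_in_cancer"))
})

test_that("identical inputs give byte-identical feature sets", {
  st <- planted_study(seed = 3L, n_metabolites = 40L, n_reactions = 70L,
                      n_chains = 6L, n_normal = 15L, n_cancer = 15L)
  a <- build_features(st$model, st$graph, st$rxn, st$sim$labels, L = 5L)
  b <- build_features(st$model, st$graph, st$rxn, st$sim$labels, L = 5L)
  expect_identical(a, b)
})

test_that("realized paths are recorded and their reactions extracted", {
  st <- planted_study(seed = 1L, n_metabolites = 40L, n_reactions = 70L,
                      n_chains = 6L, n_normal = 20L, n_cancer = 20L)
  planted <- attr(st$model, "planted")
  cfg <- search_config(record_paths = TRUE)
  fsets <- build_features(st$model, st$graph, st$rxn, st$sim$labels,
                          L = 4L, cfg = cfg)
  pr <- extract_pathway_reactions(fsets)
  expect_true(all(c("seed", "target", "sample", "reactions") %in% names(pr)))
  un <- composite_reaction_union(pr)
  expect_true(length(un) > 0)
  expect_true(all(un %in% names(st$model$reactions)))
  # paths rooted at the planted seed start with a planted (DE) reaction
  first_rxn <- vapply(strsplit(pr$reactions[nzchar(pr$reactions)], ","),
                      `[[`, character(1), 1)
  expect_true(all(first_rxn %in% planted$reactions))

  cfg_off <- search_config(record_paths = FALSE)
  fs_off <- build_features(st$model, st$graph, st$rxn, st$sim$labels,
                           L = 4L, cfg = cfg_off)
  expect_error(extract_pathway_reactions(fs_off[[1]]), "record_paths")
})
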