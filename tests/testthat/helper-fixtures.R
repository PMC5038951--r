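# Small fixtures built in code: hand-sized metabolic models and weighted
# graphs with known heaviest paths.

# Three-metabolite, two-reaction JSON model text.
tiny_model_json <- function(path = tempfile(fileext = ".json")) {
  writeLines('{
  "metabolites": [
    {"id": "a_c", "name": "A", "compartment": "c"},
    {"id": "b_c", "name": "B", "compartment": "c"},
    {"id": "c_c", "name": "C", "compartment": "c"}
  ],
  "reactions": [
    {"id": "r1",
     "substrates": [{"metabolite": "a_c", "coefficient": 1}],
     "products": [{"metabolite": "b_c", "coefficient": 1}],
     "reversible": false, "gpr": "g1 and g2", "pathway": "PW1"},
    {"id": "r2",
     "substrates": [{"metabolite": "b_c", "coefficient": 1}],
     "products": [{"metabolite": "c_c", "coefficient": 2}],
     "reversible": true, "gpr": "(g1 and g3) or g4", "pathway": "PW2"}
  ]
}', path)
  path
}

# Build a metabolic_model directly from an edge description:
# data.frame(from, to, reversible, gene, pathway). One 1->1 reaction per
# row; reaction ids r01, r02, ...
edges_model <- function(df) {
  mets <- unique(c(df$from, df$to))
  reactions <- lapply(seq_len(nrow(df)), function(i) {
    gene <- if (!is.null(df$gene)) df$gene[i] else sprintf("g%02d", i)
    list(id = sprintf("r%02d", i),
         substrates = data.frame(metabolite = df$from[i], coefficient = 1),
         products = data.frame(metabolite = df$to[i], coefficient = 1),
         reversible = if (!is.null(df$reversible)) df$reversible[i] else FALSE,
         gpr = parse_gpr(gene), gpr_text = gene,
         pathway = if (!is.null(df$pathway)) df$pathway[i] else NA_character_)
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  json <- tempfile(fileext = ".json")
  model <- structure(list(
    metabolites = data.frame(id = mets, name = mets, compartment = "c"),
    reactions = reactions,
    genes = sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))),
    pathways = sort(unique(na.omit(vapply(reactions, `[[`, character(1),
                                          "pathway"))))),
    class = "metabolic_model")
  model
}

# Weighted graph fixture: diamond s->a->t (5+1) vs s->b->t (2+10).
diamond_graph <- function() {
  as_weighted_graph(list(
    nodes = c("s", "a", "b", "t"),
    edges = data.frame(
      from = c("s", "a", "s", "b"),
      to = c("a", "t", "b", "t"),
      reaction = c("r_sa", "r_at", "r_sb", "r_bt"),
      weight = c(5, 1, 2, 10))))
}

# Default planted simulation at reduced size used across tests (fast but
# faithful to the generator's structure).
planted_study <- function(seed = 0L, ...) {
  spec <- simulation_spec(seed = seed, ...)
  model <- make_toy_model(spec)
  sim <- simulate_expression(model, spec)
  graph <- to_digraph(model)
  ranked <- rank_transform(sim$expr)
  rxn <- reactions_from_genes(ranked, model)
  list(spec = spec, model = model, graph = graph, sim = sim,
       ranked = ranked, rxn = rxn)
}
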