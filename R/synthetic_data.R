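# Synthetic study generator: toy metabolic models with planted
# differential chains, two-group expression, score-coupled survival,
# noise injection and label-permutation nulls.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. `seed = NULL` uses (and
# advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic two-group metabolic study
#'
#' Defines the simulated conditions: a toy metabolic model containing a
#' planted seed metabolite feeding `n_chains` node-disjoint reaction
#' chains (the planted composite pathways), two-group expression in which
#' only planted-reaction genes shift, and survival times coupled to a
#' score. Defaults give 60 metabolites, 120 reactions, 10 chains of 3
#' reactions (so the planted seed is a substrate of 10 differential
#' reactions, comfortably above the seed threshold k = 5), a mean shift of
#' 3 baseline standard deviations, and 50 + 50 samples.
#'
#' @param n_metabolites,n_reactions Model size (defaults 60, 120).
#' @param n_pathway_labels Canonical labels assigned round-robin
#'   (default 8).
#' @param p_reversible Probability that a background reaction is
#'   reversible (default 0.2); planted chain reactions are irreversible.
#' @param n_chains Number of planted chains = candidate targets
#'   (default 10, matching L).
#' @param chain_length Reactions per planted chain (default 3, within the
#'   default search depth).
#' @param delta Expression shift of planted genes in cancer samples, in
#'   units of `sigma0` = 1 (default 3).
#' @param sigma0 Baseline within-gene noise standard deviation
#'   (default 1).
#' @param n_normal,n_cancer Group sizes (defaults 50, 50).
#' @param beta Log-hazard coefficient coupling survival to the
#'   standardized score (default 1).
#' @param censor_rate Target fraction of censored patients (default 0.2).
#' @param seed Master RNG seed (default 0).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_metabolites = 60L, n_reactions = 120L,
                            n_pathway_labels = 8L, p_reversible = 0.2,
                            n_chains = 10L, chain_length = 3L,
                            delta = 3, sigma0 = 1,
                            n_normal = 50L, n_cancer = 50L,
                            beta = 1, censor_rate = 0.2, seed = 0L) {
  spec <- list(n_metabolites = as.integer(n_metabolites),
               n_reactions = as.integer(n_reactions),
               n_pathway_labels = as.integer(n_pathway_labels),
               p_reversible = p_reversible,
               n_chains = as.integer(n_chains),
               chain_length = as.integer(chain_length),
               delta = delta, sigma0 = sigma0,
               n_normal = as.integer(n_normal),
               n_cancer = as.integer(n_cancer),
               beta = beta, censor_rate = censor_rate,
               seed = as.integer(seed))
  counts <- unlist(spec[c("n_metabolites", "n_reactions", "n_pathway_labels",
                          "n_chains", "chain_length", "n_normal", "n_cancer")])
  if (any(counts < 1L)) stop("all counts must be positive")
  structure(spec, class = "simulation_spec")
}

#' Generate a toy metabolic model with planted differential chains
#'
#' The planted seed metabolite is a substrate of `n_chains` irreversible
#' reactions, each opening a simple chain of `chain_length` reactions to a
#' distinct sink metabolite; chains are node-disjoint beyond the seed, so
#' the heaviest path to each sink is unambiguous. Every planted reaction
#' carries its own dedicated gene. Background metabolites are connected by
#' a random spanning tree (guaranteeing weak connectivity) plus random
#' extra reactions with 1-3-gene GPR rules. Pathway labels are assigned
#' round-robin.
#'
#' @param spec A [simulation_spec()].
#' @return A `metabolic_model` whose `"planted"` attribute records the
#'   seed metabolite, planted reaction/gene ids and sink metabolites.
#' @export
make_toy_model <- function(spec = simulation_spec()) {
  n_planted <- spec$n_chains * spec$chain_length
  n_chain_mets <- spec$n_chains * spec$chain_length  # interiors + one sink each
  n_bg <- spec$n_metabolites - 1L - n_chain_mets
  if (n_bg < 1L) {
    stop("infeasible spec: planted chains need ", n_chain_mets + 1L,
         " metabolites but n_metabolites = ", spec$n_metabolites)
  }
  n_bg_rxn <- spec$n_reactions - n_planted
  if (n_bg_rxn < n_bg + 1L) {
    stop("infeasible spec: need at least ", n_planted + n_bg + 1L,
         " reactions to connect the model")
  }
  with_seed(spec$seed, {
    seed_met <- "seedM_c"
    bg_mets <- sprintf("bg%02d_c", seq_len(n_bg))
    chain_mets <- lapply(seq_len(spec$n_chains), function(i) {
      c(sprintf("ch%02d_%d_c", i, seq_len(spec$chain_length - 1L)),
        sprintf("sink%02d_c", i))
    })
    mets <- c(seed_met, unlist(chain_mets), bg_mets)
    reactions <- list()
    planted_rxn <- character(0)
    planted_genes <- character(0)
    gi <- 0L
    for (i in seq_len(spec$n_chains)) {
      nodes <- c(seed_met, chain_mets[[i]])
      for (j in seq_len(spec$chain_length)) {
        gi <- gi + 1L
        rid <- sprintf("rp%02d_%d", i, j)
        gene <- sprintf("gp%03d", gi)
        reactions[[rid]] <- list(
          id = rid,
          substrates = data.frame(metabolite = nodes[j], coefficient = 1),
          products = data.frame(metabolite = nodes[j + 1L], coefficient = 1),
          reversible = FALSE, gpr = parse_gpr(gene), gpr_text = gene,
          pathway = NA_character_)
        planted_rxn <- c(planted_rxn, rid)
        planted_genes <- c(planted_genes, gene)
      }
    }
    # background: spanning tree over {seed, background mets}, then extras
    bg_nodes <- sample(c(seed_met, bg_mets))
    bg_gene_pool <- sprintf("gb%03d", seq_len(max(10L, n_bg_rxn)))
    make_bg_gpr <- function() {
      u <- stats::runif(1)
      gs <- sample(bg_gene_pool, if (u < 0.5) 1L else 2L)
      txt <- if (length(gs) == 1L) gs
             else paste(gs, collapse = if (u < 0.75) " and " else " or ")
      txt
    }
    bg_pairs <- list()
    for (i in seq_along(bg_nodes)[-1]) {
      bg_pairs[[length(bg_pairs) + 1L]] <-
        c(bg_nodes[sample.int(i - 1L, 1L)], bg_nodes[i])
    }
    pool <- c(seed_met, bg_mets)
    while (length(bg_pairs) < n_bg_rxn) {
      pr <- sample(pool, 2L)
      bg_pairs[[length(bg_pairs) + 1L]] <- pr
    }
    for (t in seq_along(bg_pairs)) {
      rid <- sprintf("rb%03d", t)
      txt <- make_bg_gpr()
      reactions[[rid]] <- list(
        id = rid,
        substrates = data.frame(metabolite = bg_pairs[[t]][1], coefficient = 1),
        products = data.frame(metabolite = bg_pairs[[t]][2], coefficient = 1),
        reversible = stats::runif(1) < spec$p_reversible,
        gpr = parse_gpr(txt), gpr_text = txt,
        pathway = NA_character_)
    }
    labels <- sprintf("PW%02d", seq_len(spec$n_pathway_labels))
    for (t in seq_along(reactions)) {
      reactions[[t]]$pathway <- labels[(t - 1L) %% length(labels) + 1L]
    }
    genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
    model <- new_metabolic_model(
      data.frame(id = mets, name = mets, compartment = "c"),
      reactions, genes, labels)
    validate_model(model)
    g <- to_digraph(model)
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        vertices = g$nodes)
    if (!igraph::is_connected(ig, mode = "weak")) {
      stop("generated model is not weakly connected; adjust the spec")
    }
    attr(model, "planted") <- list(
      seed_metabolite = seed_met,
      reactions = planted_rxn,
      genes = planted_genes,
      sinks = vapply(chain_mets, function(x) x[length(x)], character(1)))
    model
  })
}

#' Simulate two-group expression with planted differential reactions
#'
#' Baseline expression is log-scale Gaussian: gene baseline ~ N(8, 1),
#' per-sample noise N(0, `sigma0`). In cancer samples, only the genes of
#' the planted chain reactions are shifted by `+delta`; everything else is
#' exchangeable between groups.
#'
#' @param model A model from [make_toy_model()] (its `"planted"`
#'   attribute names the shifted genes).
#' @param spec The matching [simulation_spec()].
#' @param seed RNG seed (default `spec$seed + 1`).
#' @return List: `expr` (genes x samples), `labels` (named
#'   `"cancer"`/`"normal"`).
#' @export
simulate_expression <- function(model, spec = simulation_spec(),
                                seed = spec$seed + 1L) {
  planted <- attr(model, "planted")
  genes <- model$genes
  with_seed(seed, {
    samples <- c(sprintf("norm%03d", seq_len(spec$n_normal)),
                 sprintf("canc%03d", seq_len(spec$n_cancer)))
    labels <- stats::setNames(rep(c("normal", "cancer"),
                                  c(spec$n_normal, spec$n_cancer)), samples)
    base <- stats::rnorm(length(genes), mean = 8, sd = 1)
    expr <- base + matrix(stats::rnorm(length(genes) * length(samples),
                                       sd = spec$sigma0),
                          nrow = length(genes),
                          dimnames = list(genes, samples))
    if (!is.null(planted)) {
      shift_genes <- intersect(planted$genes, genes)
      expr[shift_genes, labels == "cancer"] <-
        expr[shift_genes, labels == "cancer"] + spec$delta
    }
    list(expr = expr, labels = labels)
  })
}

#' Simulate survival times coupled to a risk score
#'
#' Event times are exponential with hazard `lambda0 * exp(beta * z)`,
#' where `z` is the standardized score. Censoring is independent
#' Uniform(0, M) with M calibrated so the realized censoring fraction
#' approximates `censor_rate`.
#'
#' @param scores Named numeric risk scores (one patient each).
#' @param beta Log-hazard coefficient (default 1).
#' @param censor_rate Target censored fraction in \[0, 1) (default 0.2).
#' @param lambda0 Baseline hazard (default 0.1).
#' @param seed RNG seed.
#' @return Data frame: patient, time, event (1 = death observed).
#' @export
simulate_survival <- function(scores, beta = 1, censor_rate = 0.2,
                              lambda0 = 0.1, seed = NULL) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  z <- if (stats::sd(scores) > 0) as.numeric(scale(scores)) else rep(0, n)
  with_seed(seed, {
    tt <- stats::rexp(n, rate = lambda0 * exp(beta * z))
    if (censor_rate <= 0) {
      time <- tt; event <- rep(1L, n)
    } else {
      # E[censored fraction | M] = mean(min(T_i / M, 1)) decreases in M
      f <- function(M) mean(pmin(tt / M, 1)) - censor_rate
      M <- stats::uniroot(f, lower = min(tt) * 1e-3,
                          upper = max(tt) * 1e3)$root
      cens <- stats::runif(n, 0, M)
      time <- pmin(tt, cens)
      event <- as.integer(tt <= cens)
    }
    data.frame(patient = if (!is.null(names(scores))) names(scores)
               else sprintf("pt%04d", seq_len(n)),
               time = time, event = event)
  })
}

#' Add i.i.d. Gaussian noise to an expression matrix
#'
#' @param expr Genes x samples matrix.
#' @param sigma Noise scale; interpreted as a standard deviation by
#'   default.
#' @param seed RNG seed.
#' @param sigma_is_sd If `FALSE`, `sigma` is taken as a variance instead.
#' @return Perturbed matrix of the same shape.
#' @export
inject_noise <- function(expr, sigma, seed = NULL, sigma_is_sd = TRUE) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(expr)
  sd_ <- if (sigma_is_sd) sigma else sqrt(sigma)
  with_seed(seed,
    expr + matrix(stats::rnorm(length(expr), sd = sd_), nrow = nrow(expr),
                  dimnames = dimnames(expr)))
}

#' Class-size-preserving label permutations
#'
#' @param labels Named label vector.
#' @param n_permutations Number of permutations (default 200; a null
#'   frequency table over selected seeds is the typical use).
#' @param seed RNG seed.
#' @return List of named label vectors, each a uniform permutation of
#'   `labels` over the same sample ids.
#' @export
permute_labels <- function(labels, n_permutations = 200L, seed = NULL) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  with_seed(seed,
    lapply(seq_len(n_permutations), function(i)
      stats::setNames(sample(unname(labels)), names(labels))))
}
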