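# Metabolic network models: loading, validation, and the hypergraph ->
# digraph transformation used for composite-path search.

#' Parse a gene-protein-reaction (GPR) Boolean rule
#'
#' GPR rules link genes to reactions with `and` (enzyme complexes) and `or`
#' (isozymes), e.g. `"(g1 and g2) or g3"`. Connectives are case-insensitive;
#' identifiers may contain any non-whitespace characters except parentheses.
#'
#' @param rule_text Character scalar. An empty or all-whitespace string (or
#'   `NA`) denotes a reaction with no gene association and returns `NULL`.
#' @return A GPR expression tree: a leaf is `list(gene = <id>)`, an internal
#'   node is `list(op = "and"|"or", args = <list of subtrees>)`. `NULL` for
#'   the empty rule.
#' @examples
#' r <- parse_gpr("(g1 and g2) or g3")
#' gpr_genes(r)
#' @export
parse_gpr <- function(rule_text) {
  if (length(rule_text) != 1L) stop("rule_text must be a single string")
  if (is.na(rule_text) || !nzchar(trimws(rule_text))) return(NULL)
  toks <- regmatches(rule_text, gregexpr("\\(|\\)|[^()[:space:]]+", rule_text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() pos <<- pos + 1L
  is_conn <- function(tok, what) !is.na(tok) && tolower(tok) == what
  fail <- function(msg) {
    stop(sprintf("GPR parse error at token %d ('%s') in rule '%s': %s",
                 pos, ifelse(is.na(peek()), "<end>", peek()), rule_text, msg),
         call. = FALSE)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) fail("unexpected end of rule")
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(node)
    }
    if (tok == ")" || is_conn(tok, "and") || is_conn(tok, "or")) {
      fail("expected gene identifier or '('")
    }
    advance()
    list(gene = tok)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_conn(peek(), "and")) {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (is_conn(peek(), "or")) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  tree <- parse_or()
  if (!is.na(peek())) fail("trailing tokens")
  tree
}

is_gpr_leaf <- function(node) !is.null(node$gene)

#' Genes referenced by a GPR rule
#'
#' @param rule A GPR tree from [parse_gpr()] (or `NULL`).
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character())
  if (is_gpr_leaf(rule)) return(rule$gene)
  unique(unlist(lapply(rule$args, gpr_genes)))
}

#' Evaluate a GPR rule over numeric gene values
#'
#' Replaces `and` with `min` and `or` with `max`. Genes missing from
#' `values` are dropped at each node; a node none of whose leaves is
#' measured evaluates to `NA`, as does the empty rule.
#'
#' @param rule GPR tree or `NULL`.
#' @param values Named numeric vector of per-gene values (e.g. ranks).
#' @return Numeric scalar, `NA` if no leaf is measured.
#' @export
gpr_eval <- function(rule, values) {
  if (is.null(rule)) return(NA_real_)
  if (is_gpr_leaf(rule)) {
    v <- values[rule$gene]
    return(if (length(v) == 0L || is.na(v)) NA_real_ else unname(v))
  }
  vals <- vapply(rule$args, gpr_eval, numeric(1), values = values)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (rule$op == "and") min(vals) else max(vals)
}

#' Render a GPR tree back to rule text
#'
#' @param rule GPR tree or `NULL`.
#' @return Character scalar ("" for the empty rule).
#' @export
gpr_to_string <- function(rule) {
  if (is.null(rule)) return("")
  if (is_gpr_leaf(rule)) return(rule$gene)
  parts <- vapply(rule$args, function(a) {
    s <- gpr_to_string(a)
    if (!is_gpr_leaf(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

new_metabolic_model <- function(metabolites, reactions, genes, pathways) {
  structure(list(metabolites = metabolites, reactions = reactions,
                 genes = genes, pathways = pathways),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model: %d metabolites, %d reactions, %d genes, %d pathway labels\n",
              nrow(x$metabolites), length(x$reactions), length(x$genes),
              length(x$pathways)))
  invisible(x)
}

validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  for (rxn in model$reactions) {
    refs <- c(rxn$substrates$metabolite, rxn$products$metabolite)
    unknown <- setdiff(refs, mets$id)
    if (length(unknown) > 0L) {
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   rxn$id, paste(unknown, collapse = ", ")))
    }
    coefs <- c(rxn$substrates$coefficient, rxn$products$coefficient)
    if (length(coefs) && any(!is.finite(coefs) | coefs <= 0)) {
      stop(sprintf("reaction '%s' has non-positive stoichiometric coefficient",
                   rxn$id))
    }
  }
  leaf_genes <- sort(unique(unlist(lapply(model$reactions,
                                          function(r) gpr_genes(r$gpr)))))
  extra <- setdiff(leaf_genes, model$genes)
  if (length(extra) > 0L) {
    stop("GPR rule(s) reference gene(s) absent from the model gene list: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  invisible(model)
}

#' Is a reaction a boundary/exchange reaction?
#'
#' Exchange reactions have an empty substrate or product side; they are kept
#' in the model but contribute no metabolite-graph edges.
#' @param rxn A reaction entry of a `metabolic_model`.
#' @return Logical scalar.
#' @export
is_exchange <- function(rxn) {
  nrow(rxn$substrates) == 0L || nrow(rxn$products) == 0L
}

side_df <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(data.frame(metabolite = character(), coefficient = numeric()))
  }
  if (is.data.frame(x)) {
    data.frame(metabolite = as.character(x$metabolite),
               coefficient = as.numeric(x$coefficient))
  } else {
    data.frame(
      metabolite = vapply(x, function(e) as.character(e$metabolite), character(1)),
      coefficient = vapply(x, function(e) as.numeric(e$coefficient), numeric(1)))
  }
}

#' Load a metabolic network model
#'
#' Reads either the package's JSON model dialect (see
#' [write_model_json()] for the schema) or an SBML file (Level 2 with
#' `GENE_ASSOCIATION`/`SUBSYSTEM` notes, or Level 3 with the `fbc`
#' gene-product extension). GPR strings are parsed to expression trees and
#' the model is validated: every reaction must reference declared
#' metabolites, and declared gene lists must cover all GPR leaves.
#'
#' @param path File path.
#' @param format `"json"` (alias `"json_fixture"`) or `"sbml"`.
#' @param pathway_key For SBML: the notes key holding the canonical pathway
#'   label of a reaction (default `"SUBSYSTEM"`).
#' @return A `metabolic_model`: list with `metabolites` (data frame: id,
#'   name, compartment), `reactions` (list of id/substrates/products/
#'   reversible/gpr/pathway), `genes`, `pathways`.
#' @export
load_model <- function(path, format = c("json", "sbml", "json_fixture"),
                       pathway_key = "SUBSYSTEM") {
  format <- match.arg(format)
  if (format == "json_fixture") format <- "json"
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") load_model_json(path) else load_model_sbml(path, pathway_key)
}

load_model_json <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse model JSON '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(raw$metabolites) || is.null(raw$reactions)) {
    stop("model JSON must contain 'metabolites' and 'reactions' arrays")
  }
  mets <- data.frame(
    id = vapply(raw$metabolites, function(m) as.character(m$id), character(1)),
    name = vapply(raw$metabolites, function(m)
      as.character(if (is.null(m$name)) m$id else m$name), character(1)),
    compartment = vapply(raw$metabolites, function(m)
      as.character(if (is.null(m$compartment)) "" else m$compartment), character(1)))
  reactions <- lapply(raw$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without 'id' in model JSON")
    gpr_text <- if (is.null(r$gpr)) "" else as.character(r$gpr)
    list(id = as.character(r$id),
         substrates = side_df(r$substrates),
         products = side_df(r$products),
         reversible = isTRUE(r$reversible),
         gpr = parse_gpr(gpr_text),
         gpr_text = gpr_text,
         pathway = if (is.null(r$pathway) || is.na(r$pathway)) NA_character_
                   else as.character(r$pathway))
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  leaf_genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
  genes <- if (!is.null(raw$genes)) {
    as.character(unlist(raw$genes))
  } else leaf_genes
  pathways <- sort(unique(stats::na.omit(
    vapply(reactions, `[[`, character(1), "pathway"))))
  model <- new_metabolic_model(mets, reactions, genes, pathways)
  validate_model(model)
}

sbml_notes_field <- function(node, key) {
  notes <- xml2::xml_find_first(node, ".//*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return(NA_character_)
  # scan individual text nodes: adjacent <p> contents must not concatenate
  lines <- xml2::xml_text(xml2::xml_find_all(notes, ".//text()"))
  hits <- grep(paste0("^\\s*", key, ":"), lines, value = TRUE)
  if (length(hits) == 0L) return(NA_character_)
  val <- trimws(sub(paste0("^\\s*", key, ":\\s*"), "", hits[1]))
  if (nzchar(val)) val else NA_character_
}

sbml_fbc_gpr <- function(rxn_node, gp_labels) {
  assoc <- xml2::xml_find_first(rxn_node,
    ".//*[local-name()='geneProductAssociation']")
  if (inherits(assoc, "xml_missing")) return(NA_character_)
  render <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      id <- xml2::xml_attr(node, "geneProduct")
      if (!is.na(id) && id %in% names(gp_labels)) gp_labels[[id]] else id
    } else if (nm %in% c("and", "or")) {
      kids <- xml2::xml_children(node)
      paste0("(", paste(vapply(kids, render, character(1)),
                        collapse = paste0(" ", nm, " ")), ")")
    } else {
      kids <- xml2::xml_children(node)
      if (length(kids) == 1L) render(kids[[1]]) else NA_character_
    }
  }
  kids <- xml2::xml_children(assoc)
  if (length(kids) == 0L) return(NA_character_)
  render(kids[[1]])
}

load_model_sbml <- function(path, pathway_key = "SUBSYSTEM") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e)))
  species <- xml2::xml_find_all(doc,
    "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(species) == 0L) stop("SBML file declares no species")
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"))
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  boundary_ids <- mets$id[boundary]
  # fbc gene products (SBML L3): map internal ids to labels
  gps <- xml2::xml_find_all(doc, "//*[local-name()='geneProduct']")
  gp_labels <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           xml2::xml_attr(gps, "id"), xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))
  rxn_nodes <- xml2::xml_find_all(doc,
    "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- lapply(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    rev_attr <- xml2::xml_attr(rn, "reversible")
    side <- function(tag) {
      refs <- xml2::xml_find_all(rn, sprintf(
        ".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      sto <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
      df <- data.frame(metabolite = xml2::xml_attr(refs, "species"),
                       coefficient = ifelse(is.na(sto), 1, sto))
      df[!(df$metabolite %in% boundary_ids), , drop = FALSE]
    }
    gpr_text <- sbml_notes_field(rn, "GENE_ASSOCIATION")
    if (is.na(gpr_text)) gpr_text <- sbml_fbc_gpr(rn, gp_labels)
    if (is.na(gpr_text)) gpr_text <- ""
    list(id = id,
         substrates = side("listOfReactants"),
         products = side("listOfProducts"),
         # SBML reactions are reversible unless declared otherwise
         reversible = is.na(rev_attr) || rev_attr == "true",
         gpr = parse_gpr(gpr_text),
         gpr_text = gpr_text,
         pathway = sbml_notes_field(rn, pathway_key))
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  mets <- mets[!boundary, , drop = FALSE]
  rownames(mets) <- NULL
  genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
  pathways <- sort(unique(stats::na.omit(
    vapply(reactions, `[[`, character(1), "pathway"))))
  model <- new_metabolic_model(mets, reactions, genes, pathways)
  validate_model(model)
}

#' Write a model in the package's JSON dialect
#'
#' Schema: top-level `metabolites` (id, name, compartment), `reactions`
#' (id, substrates/products as arrays of \{metabolite, coefficient\},
#' `reversible`, `gpr` rule string, `pathway`), and `genes`.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  side_list <- function(df) {
    lapply(seq_len(nrow(df)), function(i)
      list(metabolite = df$metabolite[i], coefficient = df$coefficient[i]))
  }
  out <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i], name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, substrates = side_list(r$substrates),
           products = side_list(r$products), reversible = r$reversible,
           gpr = gpr_to_string(r$gpr),
           pathway = if (is.na(r$pathway)) NULL else r$pathway)),
    genes = as.list(model$genes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Transform the metabolic hypergraph into a metabolite digraph
#'
#' Each reaction contributes one directed edge per (substrate, product)
#' pair, labeled by the reaction id; reversible reactions contribute both
#' directions. Exchange reactions (one empty side) contribute no edges.
#' Parallel edges from distinct reactions are retained. Self-loop edges
#' (substrate equals product) are emitted but never traversed by the path
#' search.
#'
#' @param model A `metabolic_model`.
#' @return A `metabolite_graph`: list with `nodes` (metabolite ids) and
#'   `edges` (data frame: from, to, reaction).
#' @export
to_digraph <- function(model) {
  edge_list <- lapply(model$reactions, function(r) {
    if (is_exchange(r)) return(NULL)
    fwd <- expand.grid(from = r$substrates$metabolite,
                       to = r$products$metabolite,
                       stringsAsFactors = FALSE)
    fwd$reaction <- r$id
    if (r$reversible) {
      bwd <- data.frame(from = fwd$to, to = fwd$from, reaction = r$id)
      fwd <- rbind(fwd, bwd)
    }
    fwd
  })
  edges <- do.call(rbind, c(edge_list, list(
    data.frame(from = character(), to = character(), reaction = character()))))
  rownames(edges) <- NULL
  structure(list(nodes = model$metabolites$id, edges = edges),
            class = "metabolite_graph")
}

#' @export
print.metabolite_graph <- function(x, ...) {
  cat(sprintf("Metabolite digraph: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (!is.null(x$edges$weight)) " (weighted)" else ""))
  invisible(x)
}

#' Per-reaction structural summary of a model
#'
#' @param model A `metabolic_model`.
#' @return Data frame: reaction, n_substrates, n_products, reversible,
#'   pathway.
#' @export
model_summary <- function(model) {
  data.frame(
    reaction = vapply(model$reactions, `[[`, character(1), "id"),
    n_substrates = vapply(model$reactions, function(r) nrow(r$substrates), integer(1)),
    n_products = vapply(model$reactions, function(r) nrow(r$products), integer(1)),
    reversible = vapply(model$reactions, `[[`, logical(1), "reversible"),
    pathway = vapply(model$reactions, `[[`, character(1), "pathway"),
    row.names = NULL)
}
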