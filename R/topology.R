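#' Structural dead-end compounds
#'
#' A dead-end compound cannot be both produced and consumed, so no
#' steady-state flux can pass through it. Detection is purely structural
#' (sign pattern of the stoichiometric matrix and the current bounds):
#' a reversible reaction can serve either role, and a reaction pinned to
#' zero (`lb = ub = 0`) serves neither. Compounds touching no reaction are
#' dead ends.
#'
#' @param model A `sigflux_model`.
#' @param tol Bounds within `tol` of zero count as closed.
#' @return Character vector of dead-end compound ids.
#' @export
find_dead_ends <- function(model, tol = 1e-9) {
  producible <- consumable <- stats::setNames(
    rep(FALSE, nrow(model$compounds)), model$compounds$id)
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoich[[j]]
    fwd <- model$reactions$ub[j] > tol
    bwd <- model$reactions$lb[j] < -tol
    if (!fwd && !bwd) next
    prod_ids <- names(st)[(st > 0 & fwd) | (st < 0 & bwd)]
    cons_ids <- names(st)[(st < 0 & fwd) | (st > 0 & bwd)]
    producible[prod_ids] <- TRUE
    consumable[cons_ids] <- TRUE
  }
  names(producible)[!(producible & consumable)]
}

#' Blocked reactions
#'
#' A reaction is blocked when its feasible flux range is numerically zero;
#' ranges come from [fva()], so — unlike dead-end detection — this is a
#' flux-based diagnosis that also catches reactions stalled behind
#' dead-ends elsewhere in their pathway.
#'
#' @param model A `sigflux_model`.
#' @param tol Classification tolerance on the FVA interval (flux units).
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, tol = 1e-6) {
  rng <- fva(model)
  rng$id[abs(rng$min_flux) <= tol & abs(rng$max_flux) <= tol]
}

#' Patch dead-end compounds with exchange reactions
#'
#' Adds one reversible exchange reaction (`EX_<compound id>`, bounds
#' `[-1000, 1000]`) per selected dead-end compound, the standard repair
#' for boundary compounds such as extracellular ligands that a network
#' consumes but never produces. Patching can only unblock reactions, never
#' block them, and is idempotent.
#'
#' @param model A `sigflux_model`.
#' @param selector Either a compartment code (default `"e"`: extracellular
#'   dead ends) or a function taking the compounds tibble and returning a
#'   logical vector selecting which dead ends to patch.
#' @return A list with `model` (patched) and `added` (new reaction ids).
#' @export
add_exchanges_for_dead_ends <- function(model, selector = "e") {
  dead <- find_dead_ends(model)
  keep <- if (is.function(selector)) {
    cps <- model$compounds[match(dead, model$compounds$id), ]
    dead[selector(cps)]
  } else {
    dead[model$compounds$compartment[match(dead, model$compounds$id)] %in% selector]
  }
  keep <- setdiff(keep, sub("^EX_", "", intersect(paste0("EX_", keep),
                                                  model$reactions$id)))
  if (length(keep) == 0) return(list(model = model, added = character()))
  add <- tibble::tibble(
    id = paste0("EX_", keep),
    stoich = lapply(keep, function(cid) stats::setNames(-1, cid)),
    lb = -FLUX_BIG, ub = FLUX_BIG, gpr = "",
    gpr_ast = vector("list", length(keep)),
    rclass = "exchange")
  model$reactions <- dplyr::bind_rows(model$reactions, add)
  list(model = model, added = add$id)
}

#' Compound connectivity
#'
#' Degree is the number of distinct reactions touching a compound
#' (stoichiometric multiplicity is not counted); the ratio normalises the
#' degree by the number of compounds in the same entity, which makes
#' connectivity comparable between a sub-network and its parent model.
#'
#' @param x A `sigflux_model` or `sigflux_subnetwork`.
#' @return A tibble with `compound_id`, `degree`, `ratio`, sorted by
#'   decreasing degree.
#' @export
connectivity <- function(x) {
  if (inherits(x, "sigflux_subnetwork")) {
    stoich <- x$stoich
    cps <- x$compound_ids
  } else {
    stoich <- x$reactions$stoich
    cps <- x$compounds$id
  }
  touched <- unlist(lapply(stoich, names), use.names = FALSE)
  deg <- table(factor(touched, levels = cps))
  out <- tibble::tibble(compound_id = cps,
                        degree = as.integer(deg),
                        ratio = as.integer(deg) / length(cps))
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$compound_id)
}

#' Extract the sub-network induced by a gene set
#'
#' Collects every reaction whose GPR mentions at least one of the genes
#' (association, not rule satisfaction — see [reactions_for_genes()]),
#' together with all compounds those reactions touch. This is the
#' regulated-gene sub-network construction: mapping, say, the up-regulated
#' genes of a stimulation experiment yields the portion of the signaling
#' network those genes act on.
#'
#' @param model A `sigflux_model`.
#' @param genes Character vector of inducing gene ids.
#' @param outputs Optional character vector of output reaction ids; the
#'   result records which of them the sub-network contains.
#' @return A `sigflux_subnetwork`: list with `parent_model_id`,
#'   `reaction_ids`, `compound_ids`, `inducing_genes`, `includes_outputs`
#'   and the induced `stoich` list.
#' @export
extract_subnetwork <- function(model, genes, outputs = character()) {
  rids <- reactions_for_genes(model, genes)
  idx <- match(rids, model$reactions$id)
  stoich <- model$reactions$stoich[idx]
  cps <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  structure(list(parent_model_id = model$id,
                 reaction_ids = rids,
                 compound_ids = cps %||% character(),
                 inducing_genes = genes,
                 includes_outputs = intersect(outputs, rids),
                 stoich = stats::setNames(stoich, rids)),
            class = "sigflux_subnetwork")
}

#' @export
print.sigflux_subnetwork <- function(x, ...) {
  cat("<sigflux_subnetwork> of ", x$parent_model_id, "\n",
      "  reactions: ", length(x$reaction_ids),
      "  compounds: ", length(x$compound_ids),
      "  inducing genes: ", length(x$inducing_genes), "\n", sep = "")
  if (length(x$includes_outputs) > 0) {
    cat("  outputs included: ", paste(x$includes_outputs, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Bipartite compound-reaction graph
#'
#' Builds the bipartite graph with one node per compound and one per
#' reaction and an edge for every nonzero stoichiometric entry. Node order
#' is deterministic (compounds then reactions, each in the entity's own
#' order), so exports are byte-stable.
#'
#' @param x A `sigflux_model` or `sigflux_subnetwork`.
#' @return An [igraph][igraph::graph_from_data_frame] graph with vertex
#'   attribute `type` (`"compound"`/`"reaction"`) and edge attribute
#'   `coefficient`.
#' @export
as_bipartite_graph <- function(x) {
  if (inherits(x, "sigflux_subnetwork")) {
    stoich <- x$stoich
    cps <- x$compound_ids
    rids <- x$reaction_ids
  } else {
    stoich <- stats::setNames(x$reactions$stoich, x$reactions$id)
    cps <- x$compounds$id
    rids <- x$reactions$id
  }
  edges <- purrr::imap_dfr(stoich, function(st, rid) {
    tibble::tibble(from = names(st), to = rid, coefficient = unname(st))
  })
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            coefficient = numeric())
  }
  vertices <- tibble::tibble(name = c(cps, rids),
                             type = rep(c("compound", "reaction"),
                                        c(length(cps), length(rids))))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Export a model or sub-network as GraphML
#'
#' @param x A `sigflux_model` or `sigflux_subnetwork`.
#' @param path Output file path (`.graphml`).
#' @return Invisibly, `path`.
#' @export
export_graph <- function(x, path) {
  g <- as_bipartite_graph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
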