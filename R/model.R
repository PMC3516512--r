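#' Stoichiometric signaling model
#'
#' A `sigflux_model` bundles the three tables of the tabular model dialect:
#'
#' * `compounds`: tibble with `id` (unique, carries a bracketed compartment
#'   suffix such as `"atp[c]"`), `name`, `compartment` (`e`, `c`, `n`, `v`)
#'   and `role` (`receptor`, `kinase`, `phosphatase`, `protein`, `ligand`,
#'   `metabolite`, `complex`).
#' * `reactions`: tibble with `id` (unique), `stoich` (list column of named
#'   numeric vectors, compound id to signed coefficient), `lb`, `ub`
#'   (flux bounds), `gpr` (rule text, see [parse_gpr()]), `gpr_ast`
#'   (cached parse tree) and `rclass` (`core`, `transport`, `binding`,
#'   `exchange`, `demand`, `sink`).
#' * `genes`: tibble with `gene_id`, `symbol`, `description` (the gene
#'   index).
#'
#' The implied stoichiometric matrix S (one row per compound, one column
#' per reaction) is available through [stoich_matrix()]. Steady-state flux
#' analysis constrains fluxes v to `S v = 0` with `lb <= v <= ub`.
#'
#' @param compounds,reactions,genes Data frames as described above.
#'   `reactions$stoich` may be given instead as a `formula` character column
#'   (see [parse_reaction_formula()]); `gpr_ast` is derived from `gpr`.
#' @param id Optional model identifier.
#' @return A `sigflux_model` object.
#' @export
new_model <- function(compounds, reactions, genes = NULL, id = "model") {
  compounds <- tibble::as_tibble(compounds)
  reactions <- tibble::as_tibble(reactions)
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = character(), symbol = character(),
                            description = character())
  }
  genes <- tibble::as_tibble(genes)
  if (!"name" %in% names(compounds)) compounds$name <- compounds$id
  if (!"role" %in% names(compounds)) compounds$role <- "protein"
  if (!"compartment" %in% names(compounds)) {
    compounds$compartment <- compartment_of(compounds$id)
  }
  if (!"stoich" %in% names(reactions)) {
    if (!"formula" %in% names(reactions)) {
      stop("reactions need either a 'stoich' list column or a 'formula' column",
           call. = FALSE)
    }
    parsed <- lapply(reactions$formula, parse_reaction_formula)
    reactions$stoich <- lapply(parsed, `[[`, "stoich")
    rev <- vapply(parsed, `[[`, logical(1), "reversible")
    if (!"lb" %in% names(reactions)) reactions$lb <- ifelse(rev, -FLUX_BIG, 0)
    if (!"ub" %in% names(reactions)) reactions$ub <- FLUX_BIG
  }
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (!"rclass" %in% names(reactions)) reactions$rclass <- "core"
  if (!"gpr_ast" %in% names(reactions)) {
    reactions$gpr_ast <- lapply(reactions$gpr, parse_gpr)
  }
  reactions <- reactions[, c("id", "stoich", "lb", "ub", "gpr", "gpr_ast",
                             "rclass")]
  structure(list(id = id, compounds = compounds, reactions = reactions,
                 genes = genes),
            class = "sigflux_model")
}

# conventional finite stand-in for an unconstrained flux bound
FLUX_BIG <- 1000

compartment_of <- function(id) {
  hit <- grepl("\\[[^]]+\\]$", id)
  out <- rep(NA_character_, length(id))
  out[hit] <- sub("^.*\\[([^]]+)\\]$", "\\1", id[hit])
  out
}

#' @export
print.sigflux_model <- function(x, ...) {
  cat("<sigflux_model> ", x$id, "\n", sep = "")
  cat("  compounds: ", nrow(x$compounds),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", length(genes_of(x)), "\n", sep = "")
  cls <- table(x$reactions$rclass)
  cat("  classes:  ", paste(names(cls), cls, sep = ":", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `sigflux_model`.
#' @return A dense numeric matrix S with one row per compound and one
#'   column per reaction, dimnames set to compound and reaction ids.
#' @export
stoich_matrix <- function(model) {
  cps <- model$compounds$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(cps), ncol = length(rxns),
              dimnames = list(cps, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoich[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Genes referenced by any reaction of a model
#'
#' @param model A `sigflux_model`.
#' @return Character vector: the union of GPR leaves over all reactions.
#' @export
genes_of <- function(model) {
  unique(unlist(lapply(model$reactions$gpr_ast, gpr_genes), use.names = FALSE))
}

#' Reactions associated with a gene set
#'
#' Association is membership: a reaction belongs to the set as soon as its
#' GPR mentions at least one of the genes, regardless of whether the rule
#' would be satisfied. This is the induction rule used for sub-network
#' extraction from regulated gene sets.
#'
#' @param model A `sigflux_model`.
#' @param genes Character vector of gene ids.
#' @return Character vector of reaction ids.
#' @export
reactions_for_genes <- function(model, genes) {
  if (length(genes) == 0) return(character())
  hit <- vapply(model$reactions$gpr_ast,
                function(g) length(intersect(gpr_genes(g), genes)) > 0,
                logical(1))
  model$reactions$id[hit]
}

#' Validate model invariants
#'
#' Checks id uniqueness, resolution of stoichiometry keys against the
#' compound table, resolution of GPR leaves against the gene index, bound
#' ordering, non-empty stoichiometries, the single-compound rule for
#' exchange/demand/sink reactions, and agreement between each compound's
#' bracketed id suffix and its `compartment` field.
#'
#' @param model A `sigflux_model`.
#' @return A tibble of violations with columns `kind`, `where`, `message`;
#'   zero rows when all invariants hold.
#' @export
validate_model <- function(model) {
  bad <- list()
  note <- function(kind, where, message) {
    bad[[length(bad) + 1]] <<- tibble::tibble(kind = kind, where = where,
                                              message = message)
  }
  dup <- unique(model$compounds$id[duplicated(model$compounds$id)])
  for (d in dup) note("duplicate_compound", d, "compound id not unique")
  dup <- unique(model$reactions$id[duplicated(model$reactions$id)])
  for (d in dup) note("duplicate_reaction", d, "reaction id not unique")
  suf <- compartment_of(model$compounds$id)
  off <- which(!is.na(suf) & suf != model$compounds$compartment)
  for (i in off) {
    note("compartment_mismatch", model$compounds$id[i],
         paste0("id suffix [", suf[i], "] != compartment '",
                model$compounds$compartment[i], "'"))
  }
  known_cp <- model$compounds$id
  known_gene <- model$genes$gene_id
  for (j in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[j]
    st <- model$reactions$stoich[[j]]
    if (length(st) == 0) note("empty_stoichiometry", rid, "no participants")
    if (any(st == 0)) note("zero_coefficient", rid, "zero stoichiometric coefficient")
    miss <- setdiff(names(st), known_cp)
    for (m in miss) note("unknown_compound", rid, paste0("compound '", m, "' not in compound table"))
    if (model$reactions$lb[j] > model$reactions$ub[j]) {
      note("bound_order", rid,
           paste0("lb (", model$reactions$lb[j], ") > ub (",
                  model$reactions$ub[j], ")"))
    }
    if (model$reactions$rclass[j] %in% c("exchange", "demand", "sink") &&
        length(st) != 1) {
      note("boundary_arity", rid,
           paste0(model$reactions$rclass[j], " reaction must touch exactly one compound"))
    }
    if (length(known_gene) > 0) {
      mg <- setdiff(gpr_genes(model$reactions$gpr_ast[[j]]), known_gene)
      for (g in mg) note("unknown_gene", rid, paste0("gene '", g, "' not in gene index"))
    }
  }
  if (length(bad) == 0) {
    tibble::tibble(kind = character(), where = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Read or change flux bounds
#'
#' @param model A `sigflux_model`.
#' @param rxn_ids Reaction ids to modify.
#' @param lb,ub New bounds (recycled); `NULL` leaves the bound unchanged.
#' @return `set_bounds()` returns the modified model; `get_bounds()` a
#'   tibble with `id`, `lb`, `ub`.
#' @export
set_bounds <- function(model, rxn_ids, lb = NULL, ub = NULL) {
  idx <- match(rxn_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ",
         paste(rxn_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (!is.null(lb)) model$reactions$lb[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$reactions$ub[idx] <- rep_len(ub, length(idx))
  model
}

#' @rdname set_bounds
#' @export
get_bounds <- function(model, rxn_ids = NULL) {
  r <- model$reactions[, c("id", "lb", "ub")]
  if (!is.null(rxn_ids)) r <- r[match(rxn_ids, r$id), ]
  tibble::as_tibble(r)
}

rxn_index <- function(model, rxn_id) {
  i <- match(rxn_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", rxn_id, call. = FALSE)
  i
}
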