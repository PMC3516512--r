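#' Read a model from the tabular dialect
#'
#' The canonical on-disk form of a model is a triple of UTF-8 TSV files
#' (lines starting with `#` are comments):
#'
#' * reactions: columns `id`, `formula`, `lb`, `ub`, `gpr`, `rclass`
#'   (`lb`/`ub` may be empty; they then default from the formula arrow),
#' * compounds: columns `id`, `name`, `compartment`, `role`,
#' * genes: columns `gene_id`, `symbol`, `description` (optional file).
#'
#' @param reactions_path,compounds_path,genes_path File paths;
#'   `genes_path` may be `NULL`.
#' @param id Model identifier (defaults to the reactions file stem).
#' @return A validated `sigflux_model`; malformed input is an error naming
#'   the offending rows.
#' @export
read_model <- function(reactions_path, compounds_path, genes_path = NULL,
                       id = NULL) {
  rx <- read_dialect_tsv(reactions_path,
                         c("id", "formula", "lb", "ub", "gpr", "rclass"))
  cp <- read_dialect_tsv(compounds_path,
                         c("id", "name", "compartment", "role"))
  gn <- if (is.null(genes_path)) NULL else {
    read_dialect_tsv(genes_path, c("gene_id", "symbol", "description"))
  }
  parsed <- lapply(rx$formula, parse_reaction_formula)
  rx$stoich <- lapply(parsed, `[[`, "stoich")
  rev <- vapply(parsed, `[[`, logical(1), "reversible")
  rx$lb <- ifelse(is.na(rx$lb), ifelse(rev, -FLUX_BIG, 0), rx$lb)
  rx$ub <- ifelse(is.na(rx$ub), FLUX_BIG, rx$ub)
  model <- new_model(cp, rx[, setdiff(names(rx), "formula")], gn,
                     id = id %||% sub("\\.[^.]*$", "", basename(reactions_path)))
  issues <- validate_model(model)
  issues <- issues[issues$kind != "unknown_gene", , drop = FALSE]
  if (nrow(issues) > 0) {
    stop("model failed validation:\n",
         paste0("  [", issues$kind, "] ", issues$where, ": ", issues$message,
                collapse = "\n"),
         call. = FALSE)
  }
  model
}

read_dialect_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  missing <- setdiff(required, names(df))
  # lb/ub columns are optional in reaction files
  missing <- setdiff(missing, c("lb", "ub"))
  if (length(missing) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c("lb", "ub"), required)) {
    df[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  }
  df
}

#' Write a model in the tabular dialect
#'
#' Inverse of [read_model()]: `read_model()` on the written triple
#' reproduces the model (id-level equality, including bounds zeroed by
#' tailoring).
#'
#' @param model A `sigflux_model`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem; files are `<stem>_reactions.tsv`,
#'   `<stem>_compounds.tsv`, `<stem>_genes.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_model <- function(model, dir, stem = model$id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stem, "_", c("reactions", "compounds", "genes"),
                                 ".tsv"))
  rx <- model$reactions
  formula <- mapply(function(st, lb) render_reaction_formula(st, lb < 0),
                    rx$stoich, rx$lb)
  readr::write_tsv(tibble::tibble(id = rx$id, formula = formula,
                                  lb = rx$lb, ub = rx$ub, gpr = rx$gpr,
                                  rclass = rx$rclass),
                   paths[1])
  readr::write_tsv(model$compounds[, c("id", "name", "compartment", "role")],
                   paths[2])
  readr::write_tsv(model$genes, paths[3])
  invisible(paths)
}

#' Export a model as SBML Level 3 with the FBC extension
#'
#' Species, reactions, flux bounds and gene-product associations are
#' written so that a third-party SBML+FBC reader preserves the compound,
#' reaction and gene counts. Ids that are not SBML-SId-safe (the bracketed
#' compartment suffixes, slashes, leading digits) are sanitised; the
#' mapping is recorded in `<path>.idmap.tsv` when any id changed.
#'
#' @param model A `sigflux_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_sbml <- function(model, path) {
  sid <- function(x) {
    y <- gsub("[^A-Za-z0-9_]", "_", x)
    ifelse(grepl("^[0-9]", y), paste0("x_", y), y)
  }
  cp_id <- sid(paste0("M_", model$compounds$id))
  rx_id <- sid(paste0("R_", model$reactions$id))
  gn_all <- genes_of(model)
  gn_id <- sid(paste0("G_", gn_all))
  if (anyDuplicated(c(cp_id, rx_id, gn_id))) {
    stop("id sanitisation produced duplicates; rename model ids", call. = FALSE)
  }
  idmap <- tibble::tibble(
    original = c(model$compounds$id, model$reactions$id, gn_all),
    sbml = c(cp_id, rx_id, gn_id))
  if (any(idmap$original != sub("^[MRG]_", "", idmap$sbml))) {
    readr::write_tsv(idmap, paste0(path, ".idmap.tsv"))
  }

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sid(model$id),
                             "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in unique(model$compounds$compartment)) {
    xml2::xml_add_child(lc, "compartment", id = sid(cmp), constant = "true")
  }

  # every distinct bound value becomes a shared parameter, as fbc requires
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bkey <- function(x) sprintf("%.15g", x)
  bid <- stats::setNames(sid(paste0("fb_", seq_along(bounds))), bkey(bounds))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(lp, "parameter", id = bid[[i]],
                        value = bkey(bounds[i]),
                        constant = "true")
  }

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$compounds))) {
    xml2::xml_add_child(ls, "species", id = cp_id[i],
                        name = model$compounds$name[i],
                        compartment = sid(model$compounds$compartment[i]),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (i in seq_along(gn_all)) {
    xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = gn_id[i],
                        "fbc:label" = gn_all[i])
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    lbv <- model$reactions$lb[j]
    ubv <- model$reactions$ub[j]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = rx_id[j],
      reversible = tolower(lbv < 0), fast = "false",
      "fbc:lowerFluxBound" = bid[[bkey(lbv)]],
      "fbc:upperFluxBound" = bid[[bkey(ubv)]])
    st <- model$reactions$stoich[[j]]
    subs <- st[st < 0]
    prods <- st[st > 0]
    if (length(subs) > 0) {
      n <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(subs)) {
        xml2::xml_add_child(n, "speciesReference",
                            species = cp_id[match(names(subs)[k], model$compounds$id)],
                            stoichiometry = format(-subs[[k]]), constant = "true")
      }
    }
    if (length(prods) > 0) {
      n <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(prods)) {
        xml2::xml_add_child(n, "speciesReference",
                            species = cp_id[match(names(prods)[k], model$compounds$id)],
                            stoichiometry = format(prods[[k]]), constant = "true")
      }
    }
    ast <- model$reactions$gpr_ast[[j]]
    if (!is.null(ast)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_add_gpr(ga, ast, gn_all, gn_id)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_add_gpr <- function(parent, ast, gn_all, gn_id) {
  if (!is.null(ast$gene)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = gn_id[match(ast$gene, gn_all)])
    return(invisible())
  }
  node <- xml2::xml_add_child(parent, if (ast$op == "and") "fbc:and" else "fbc:or")
  for (ch in ast$children) sbml_add_gpr(node, ch, gn_all, gn_id)
  invisible()
}

#' Basic SBML+FBC import
#'
#' Reads back documents written by [export_sbml()] (and plain SBML L3+FBC
#' documents using the same subset): species, reactions with stoichiometry
#' and flux-bound parameters, and gene-product associations. The tabular
#' dialect remains the canonical format; this importer exists for
#' round-trip checks and interoperability.
#'
#' @param path SBML file path.
#' @return A `sigflux_model` (compartments and GPRs preserved; compound
#'   roles default to `protein`, reaction classes to `core`).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  par_nodes <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gp_nodes, "fbc:label", ns = ns),
                            xml2::xml_attr(gp_nodes, "fbc:id", ns = ns))
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  cp <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    role = "protein")
  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  rx <- tibble::tibble(
    id = xml2::xml_attr(rx_nodes, "id"),
    stoich = lapply(rx_nodes, function(rn) {
      take <- function(xp, sign) {
        refs <- xml2::xml_find_all(rn, xp, ns)
        stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                        xml2::xml_attr(refs, "species"))
      }
      c(take(".//s:listOfReactants/s:speciesReference", -1),
        take(".//s:listOfProducts/s:speciesReference", 1))
    }),
    lb = unname(pars[xml2::xml_attr(rx_nodes, "fbc:lowerFluxBound", ns = ns)]),
    ub = unname(pars[xml2::xml_attr(rx_nodes, "fbc:upperFluxBound", ns = ns)]),
    gpr = vapply(rx_nodes, function(rn) {
      ga <- xml2::xml_find_first(rn, ".//fbc:geneProductAssociation/*", ns)
      if (inherits(ga, "xml_missing")) "" else render_gpr(sbml_read_gpr(ga, ns, glabel))
    }, character(1)),
    rclass = "core")
  new_model(cp, rx, id = xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id"))
}

sbml_read_gpr <- function(node, ns, glabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "fbc:geneProduct", ns = ns)
    lab <- glabel[[gid]]
    return(list(gene = if (is.null(lab) || is.na(lab)) gid else lab))
  }
  list(op = nm,
       children = lapply(xml2::xml_children(node), sbml_read_gpr,
                         ns = ns, glabel = glabel))
}

#' Read a probe-level expression table
#'
#' Expected TSV columns: `probe_id`, `gene_id`, `sample_id`, `group`
#' (`control`/`treated`), `detection_p` (in `[0, 1]`), `intensity`
#' (non-negative). Detection p-values are consumed as precomputed by the
#' upstream microarray pipeline; this package does not recompute them.
#'
#' @param path TSV file path.
#' @return A tibble; duplicate `(probe_id, sample_id)` pairs or detection
#'   p-values outside `[0, 1]` are errors.
#' @export
read_expression <- function(path) {
  df <- read_dialect_tsv(path, c("probe_id", "gene_id", "sample_id", "group",
                                 "detection_p", "intensity"))
  df$detection_p <- as.numeric(df$detection_p)
  df$intensity <- as.numeric(df$intensity)
  key <- paste(df$probe_id, df$sample_id)
  if (anyDuplicated(key)) {
    stop("duplicate (probe_id, sample_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(df$detection_p) | df$detection_p < 0 | df$detection_p > 1)
  if (length(bad) > 0) {
    stop("detection_p outside [0, 1] in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  badg <- setdiff(unique(df$group), c("control", "treated"))
  if (length(badg) > 0) {
    stop("group must be 'control' or 'treated'; got: ",
         paste(badg, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a differential-expression table
#'
#' Expected TSV columns: `gene_id`, `probe_id`, `log2_fc`, `fdr_p`.
#' One row per probe set; genes may have several probe sets.
#'
#' @param path TSV file path.
#' @return A tibble; duplicate `(gene_id, probe_id)` pairs are errors.
#' @export
read_diffexpr <- function(path) {
  df <- read_dialect_tsv(path, c("gene_id", "probe_id", "log2_fc", "fdr_p"))
  df$log2_fc <- as.numeric(df$log2_fc)
  df$fdr_p <- as.numeric(df$fdr_p)
  key <- paste(df$gene_id, df$probe_id)
  if (anyDuplicated(key)) {
    stop("duplicate (gene_id, probe_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$fdr_p) | df$fdr_p < 0 | df$fdr_p > 1)) {
    stop("fdr_p outside [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
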