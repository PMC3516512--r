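#' Pipeline runners
#'
#' Thin orchestration functions behind the command-line interface in
#' `inst/cli/sigflux.R`: each reads its inputs, delegates to the analysis
#' functions, writes deterministic TSV outputs into `out_dir` and appends
#' a run manifest (`manifest.tsv`: inputs, key parameters, package
#' version). Re-running with identical inputs reproduces byte-identical
#' tables.
#'
#' @param model A `sigflux_model`.
#' @param out_dir Output directory (created if needed).
#' @return Each runner invisibly returns its main result object.
#' @name pipeline
NULL

write_manifest <- function(out_dir, command, params) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(
    tibble::tibble(command = command,
                   parameter = names(params),
                   value = vapply(params, function(v) paste(format(v), collapse = ","),
                                  character(1)),
                   package_version = as.character(utils::packageVersion("sigflux"))),
    file.path(out_dir, "manifest.tsv"))
}

#' @rdname pipeline
#' @export
run_validate <- function(model, out_dir) {
  report <- validate_model(model)
  write_manifest(out_dir, "validate", list(model = model$id))
  readr::write_tsv(report, file.path(out_dir, "validation.tsv"))
  invisible(report)
}

#' @rdname pipeline
#' @param expression Expression tibble (see [read_expression()]).
#' @param cutoff,cutoff2 Detection p-value cutoff(s); when `cutoff2` is
#'   given the run also emits a side-by-side comparison of the tailoring
#'   statistics under both cutoffs.
#' @export
run_tailor <- function(model, expression, cutoff, cutoff2 = NULL, out_dir) {
  one <- function(cf) {
    calls <- presence_calls(expression, cf)
    tailor_model(model, calls)
  }
  t1 <- one(cutoff)
  readr::write_tsv(tibble::tibble(id = t1$disabled_reactions),
                   file.path(out_dir, "disabled_reactions.tsv"))
  stats <- dplyr::mutate(glance(t1), cutoff = cutoff, .before = 1)
  if (!is.null(cutoff2)) {
    t2 <- one(cutoff2)
    stats <- dplyr::bind_rows(
      stats, dplyr::mutate(glance(t2), cutoff = cutoff2, .before = 1))
  }
  write_manifest(out_dir, "tailor",
                 list(model = model$id, cutoff = cutoff,
                      cutoff2 = cutoff2 %||% NA))
  readr::write_tsv(stats, file.path(out_dir, "tailoring_stats.tsv"))
  write_model(t1$tailored, out_dir, stem = paste0(model$id, "_tailored"))
  invisible(t1)
}

#' @rdname pipeline
#' @param pairs List of [io_pair()] stimulations.
#' @param outputs Output reaction ids.
#' @param energy Energy scenario for [configure_io()].
#' @export
run_iomatrix <- function(model, pairs, outputs, energy = "sensitivity",
                         out_dir) {
  mat <- output_capability_matrix(model, pairs, outputs, energy = energy)
  write_manifest(out_dir, "iomatrix",
                 list(model = model$id, energy = energy,
                      n_pairs = length(pairs), n_outputs = length(outputs)))
  readr::write_tsv(tibble::as_tibble(mat), file.path(out_dir, "io_matrix.tsv"))
  invisible(mat)
}

#' @rdname pipeline
#' @param pair A single [io_pair()].
#' @param energy_exchange `"atp"` or `"gtp"`.
#' @param n_points Grid size.
#' @export
run_sensitivity <- function(model, pair, energy_exchange = "atp",
                            n_points = 50, out_dir) {
  curve <- sensitivity_analysis(model, pair, energy_exchange,
                                n_points = n_points)
  write_manifest(out_dir, "sensitivity",
                 list(model = model$id, input = pair$input_id,
                      output = pair$output_rxn, energy = energy_exchange,
                      n_points = n_points,
                      classification = attr(curve, "classification")))
  readr::write_tsv(tibble::as_tibble(curve),
                   file.path(out_dir, "sensitivity_curve.tsv"))
  invisible(curve)
}

#' @rdname pipeline
#' @param genes Inducing gene ids for sub-network extraction.
#' @export
run_subnet <- function(model, genes, outputs = character(), out_dir) {
  sub <- extract_subnetwork(model, genes, outputs = outputs)
  write_manifest(out_dir, "subnet",
                 list(model = model$id, n_genes = length(genes)))
  readr::write_tsv(tidy(sub), file.path(out_dir, "subnetwork_reactions.tsv"))
  readr::write_tsv(connectivity(sub), file.path(out_dir, "subnetwork_connectivity.tsv"))
  export_graph(sub, file.path(out_dir, "subnetwork.graphml"))
  invisible(sub)
}
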