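#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux solution
#'
#' @param x A `sigflux_flux`.
#' @param ... Unused.
#' @return A tibble with `id` and `flux` (empty unless the solve was
#'   optimal).
#' @method tidy sigflux_flux
#' @export
tidy.sigflux_flux <- function(x, ...) x$fluxes

#' @rdname tidy.sigflux_flux
#' @return `glance()` returns a one-row tibble with `status`,
#'   `objective_rxn`, `sense`, `objective_value`.
#' @method glance sigflux_flux
#' @export
glance.sigflux_flux <- function(x, ...) {
  tibble::tibble(status = x$status, objective_rxn = x$objective_rxn,
                 sense = x$sense, objective_value = x$objective_value)
}

#' Tidy a tailoring result
#'
#' @param x A `sigflux_tailoring`.
#' @param ... Unused.
#' @return One row per disabled reaction (`id`).
#' @method tidy sigflux_tailoring
#' @export
tidy.sigflux_tailoring <- function(x, ...) {
  tibble::tibble(id = x$disabled_reactions)
}

#' @rdname tidy.sigflux_tailoring
#' @return `glance()` returns the tailoring statistics row
#'   (`n_deleted_genes`, `n_constrained_reactions`, `n_blocked`,
#'   `n_dead_ends`).
#' @method glance sigflux_tailoring
#' @export
glance.sigflux_tailoring <- function(x, ...) x$stats

#' Tidy a regulation set
#'
#' @param x A `sigflux_regulation`.
#' @param ... Unused.
#' @return A tibble with `gene_id`, `direction`
#'   (`up`/`down`/`subthreshold`) and `fold_change` (`NA` for
#'   subthreshold genes).
#' @method tidy sigflux_regulation
#' @export
tidy.sigflux_regulation <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(gene_id = names(x$up), direction = "up",
                   fold_change = unname(x$up)),
    tibble::tibble(gene_id = names(x$down), direction = "down",
                   fold_change = unname(x$down)),
    tibble::tibble(gene_id = x$subthreshold, direction = "subthreshold",
                   fold_change = NA_real_))
}

#' Tidy a sub-network
#'
#' @param x A `sigflux_subnetwork`.
#' @param ... Unused.
#' @return One row per induced reaction with its compound count.
#' @method tidy sigflux_subnetwork
#' @export
tidy.sigflux_subnetwork <- function(x, ...) {
  tibble::tibble(id = x$reaction_ids,
                 n_compounds = lengths(x$stoich),
                 is_output = x$reaction_ids %in% x$includes_outputs)
}

#' @rdname tidy.sigflux_subnetwork
#' @return `glance()` returns one row with `n_reactions`, `n_compounds`,
#'   `n_inducing_genes`, `n_outputs_included`.
#' @method glance sigflux_subnetwork
#' @export
glance.sigflux_subnetwork <- function(x, ...) {
  tibble::tibble(n_reactions = length(x$reaction_ids),
                 n_compounds = length(x$compound_ids),
                 n_inducing_genes = length(x$inducing_genes),
                 n_outputs_included = length(x$includes_outputs))
}

#' Plot a robustness / sensitivity curve
#'
#' Maximal output flux against the scanned energy-exchange lower bound.
#' The x axis is flipped to energy *availability* (`-control_lb`) so that
#' supply increases to the right.
#'
#' @param object A `sigflux_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sigflux_curve
#' @export
autoplot.sigflux_curve <- function(object, ...) {
  lab <- attr(object, "classification")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = -.data$control_lb, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = paste0("availability through ", attr(object, "control_rxn"),
                 " (flux units)"),
      y = paste0("max ", attr(object, "objective_rxn"), " flux"),
      title = paste0(attr(object, "input_id") %||% "",
                     if (!is.null(lab)) paste0(" (", lab, ")") else "")) +
    ggplot2::theme_minimal()
}

#' Plot an output capability matrix
#'
#' Heat map of stimulation effect beyond baseline (`delta_over_baseline`)
#' per input/output cell.
#'
#' @param object A `sigflux_iomatrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sigflux_iomatrix
#' @export
autoplot.sigflux_iomatrix <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$input_id != "baseline")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$output_id, y = .data$input_id,
                                   fill = .data$delta_over_baseline)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "output reaction", y = "input",
                  fill = "max flux\nover baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
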