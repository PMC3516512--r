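#' Describe an input/output relationship
#'
#' An I/O relationship pairs a receptor stimulation protocol with one
#' output reaction. Stimulation fixes each listed ligand exchange at an
#' uptake of one flux unit (`lb = ub = -1`; uptake is negative by the
#' usual exchange sign convention) and each listed receptor binding
#' reaction at one unit (`lb = ub = 1`). Outputs that require engagement
#' of two receptors (the IRF7-style rule) are expressed by nesting a
#' second pair as `co_stimulation`, which is applied recursively — so
#' arbitrary stimulation combinations compose.
#'
#' @param input_id Label for the stimulation (e.g. the receptor name).
#' @param exchange_rxns Ligand exchange reaction ids (non-empty).
#' @param binding_rxns Receptor binding reaction ids (non-empty).
#' @param output_rxn The output reaction id of the relationship.
#' @param co_stimulation Optional second `sigflux_io_pair`.
#' @return A `sigflux_io_pair`.
#' @export
io_pair <- function(input_id, exchange_rxns, binding_rxns, output_rxn,
                    co_stimulation = NULL) {
  stopifnot(length(exchange_rxns) > 0, length(binding_rxns) > 0,
            length(output_rxn) == 1)
  if (!is.null(co_stimulation)) stopifnot(inherits(co_stimulation, "sigflux_io_pair"))
  structure(list(input_id = input_id,
                 exchange_rxns = exchange_rxns,
                 binding_rxns = binding_rxns,
                 output_rxn = output_rxn,
                 co_stimulation = co_stimulation),
            class = "sigflux_io_pair")
}

#' Configure a model for an I/O simulation
#'
#' Applies the stimulation protocol: first *all* ligand exchange reactions
#' (exchanges whose compound has role `ligand`) and all binding-class
#' reactions are closed to zero, then the pair's exchanges are fixed at
#' `lb = ub = -1` and its binding reactions at `lb = ub = 1`
#' (co-stimulations recursively). Energy availability is set per scenario:
#'
#' * `"sensitivity"`: ATP and GTP exchanges at `lb = -25, ub = 0`, the
#'   window used for energy robustness scans;
#' * `"quantitative"`: ATP at `lb = -100`, GTP at `lb = -50`, `ub = 0`,
#'   the more generous supply used when mapping expression fold changes;
#' * `"none"`: energy exchanges untouched.
#'
#' The input model is never modified; configuring is side-effect-free.
#'
#' @param model A `sigflux_model`.
#' @param pair A `sigflux_io_pair`, or `NULL` for the baseline
#'   configuration (all inputs closed).
#' @param energy Energy scenario, see above.
#' @param energy_exchanges Named list/vector mapping `atp` and `gtp` to
#'   their exchange reaction ids; by default they are found by matching
#'   exchange reactions whose compound id starts with `atp[` / `gtp[`.
#' @return The configured model.
#' @export
configure_io <- function(model, pair = NULL,
                         energy = c("sensitivity", "quantitative", "none"),
                         energy_exchanges = NULL) {
  energy <- match.arg(energy)
  ligand_cps <- model$compounds$id[model$compounds$role == "ligand"]
  is_exch <- model$reactions$rclass == "exchange"
  exch_cp <- vapply(model$reactions$stoich,
                    function(st) if (length(st) == 1) names(st) else NA_character_,
                    character(1))
  lig_ex <- model$reactions$id[is_exch & exch_cp %in% ligand_cps]
  bindings <- model$reactions$id[model$reactions$rclass == "binding"]
  model <- set_bounds(model, c(lig_ex, bindings), lb = 0, ub = 0)
  apply_pair <- function(m, p) {
    if (is.null(p)) return(m)
    m <- set_bounds(m, p$exchange_rxns, lb = -1, ub = -1)
    m <- set_bounds(m, p$binding_rxns, lb = 1, ub = 1)
    apply_pair(m, p$co_stimulation)
  }
  model <- apply_pair(model, pair)
  if (energy != "none") {
    ex <- energy_exchanges %||% find_energy_exchanges(model)
    lbs <- if (energy == "sensitivity") c(atp = -25, gtp = -25) else
      c(atp = -100, gtp = -50)
    for (sp in intersect(names(ex), names(lbs))) {
      model <- set_bounds(model, ex[[sp]], lb = lbs[[sp]], ub = 0)
    }
  }
  model
}

find_energy_exchanges <- function(model) {
  is_exch <- model$reactions$rclass == "exchange"
  out <- list()
  for (sp in c("atp", "gtp")) {
    hit <- is_exch & vapply(model$reactions$stoich, function(st) {
      length(st) == 1 && startsWith(names(st), paste0(sp, "["))
    }, logical(1))
    if (any(hit)) out[[sp]] <- model$reactions$id[hit]
  }
  out
}

#' Enumerate input/output relationships
#'
#' Full Cartesian product of the input labels and output reaction ids, in
#' deterministic (input-major) order.
#'
#' @param inputs Character vector of input labels (or a list of
#'   `sigflux_io_pair` templates, whose `input_id`s are used).
#' @param outputs Character vector of output reaction ids.
#' @return A tibble with `input_id` and `output_id`, one row per
#'   relationship.
#' @export
enumerate_io_relationships <- function(inputs, outputs) {
  if (is.list(inputs) && !is.character(inputs)) {
    inputs <- vapply(inputs, `[[`, character(1), "input_id")
  }
  tidyr::expand_grid(input_id = inputs, output_id = outputs)
}

#' Output capability matrix over I/O relationships
#'
#' For every stimulation pair, configures the model, runs FVA on all
#' output reactions, and tabulates the flux ranges together with the
#' baseline (all inputs closed) and the stimulation effect beyond
#' baseline. Internal loops can sustain baseline flux through output
#' reactions even without stimulation; subtracting the baseline maximum
#' isolates what stimulation adds.
#'
#' @param model A `sigflux_model`.
#' @param pairs List of `sigflux_io_pair` stimulations.
#' @param outputs Character vector of output reaction ids.
#' @param energy Energy scenario passed to [configure_io()].
#' @return A tibble (class `sigflux_iomatrix`): `input_id` (`"baseline"`
#'   for the unstimulated row), `output_id`, `fva_min`, `fva_max`,
#'   `delta_over_baseline` (`fva_max` minus the baseline `fva_max`;
#'   `NA` for the baseline row itself). Infeasible cells are `NA`.
#' @export
output_capability_matrix <- function(model, pairs, outputs,
                                     energy = "sensitivity") {
  run_one <- function(m, label) {
    rng <- tryCatch(fva(m, outputs), error = function(e) NULL)
    if (is.null(rng)) {
      return(tibble::tibble(input_id = label, output_id = outputs,
                            fva_min = NA_real_, fva_max = NA_real_))
    }
    tibble::tibble(input_id = label, output_id = rng$id,
                   fva_min = rng$min_flux, fva_max = rng$max_flux)
  }
  base <- run_one(configure_io(model, NULL, energy = energy), "baseline")
  rows <- purrr::map_dfr(pairs, function(p) {
    run_one(configure_io(model, p, energy = energy), p$input_id)
  })
  base_max <- stats::setNames(base$fva_max, base$output_id)
  rows$delta_over_baseline <- rows$fva_max - unname(base_max[rows$output_id])
  base$delta_over_baseline <- NA_real_
  out <- dplyr::bind_rows(base, rows)
  class(out) <- c("sigflux_iomatrix", class(out))
  out
}

#' Energy sensitivity of an I/O relationship
#'
#' Configures the model for the stimulation (energy scenario
#' `"sensitivity"`) and sweeps the chosen energy exchange's lower bound
#' across `lb_range`, recording the maximal output flux at each grid point
#' (see [robustness_scan()]). The curve is classified `"dependent"` when
#' the response varies across the grid by more than `tol` flux units, and
#' `"independent"` otherwise.
#'
#' @param model A `sigflux_model`.
#' @param pair A `sigflux_io_pair`.
#' @param energy_exchange `"atp"` or `"gtp"` (resolved via
#'   [configure_io()]'s detection), or an explicit exchange reaction id.
#' @param n_points,lb_range Grid, defaults 50 points over `[-25, 0]`.
#' @param tol Classification tolerance (flux units).
#' @return A `sigflux_curve` (tibble `control_lb`, `response`) with
#'   attributes `classification`, `control_rxn`, `objective_rxn`,
#'   `input_id`.
#' @export
sensitivity_analysis <- function(model, pair, energy_exchange = c("atp", "gtp"),
                                 n_points = 50, lb_range = c(-25, 0),
                                 tol = 1e-6) {
  cfg <- configure_io(model, pair, energy = "sensitivity")
  if (is.character(energy_exchange) &&
      all(energy_exchange %in% c("atp", "gtp"))) {
    sp <- match.arg(energy_exchange)
    ex <- find_energy_exchanges(cfg)[[sp]]
    if (is.null(ex)) stop("no ", sp, " exchange reaction found", call. = FALSE)
  } else {
    ex <- energy_exchange
  }
  curve <- robustness_scan(cfg, ex, pair$output_rxn,
                           n_points = n_points, lb_range = lb_range)
  resp <- curve$response[!is.na(curve$response)]
  attr(curve, "classification") <-
    if (length(resp) > 1 && diff(range(resp)) > tol) "dependent" else "independent"
  attr(curve, "input_id") <- pair$input_id
  curve
}
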