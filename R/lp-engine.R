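#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through one reaction over the
#' steady-state flux cone `\{v : S v = 0, lb <= v <= ub\}`.
#'
#' @param model A `sigflux_model`.
#' @param objective_rxn Reaction id to optimize.
#' @param sense `"max"` (default) or `"min"`.
#' @return A `sigflux_flux` object: list with `status` (`optimal` /
#'   `infeasible`), `objective_value`, and `fluxes` (tibble `id`, `flux`;
#'   empty when not optimal). [tidy()][generics::tidy] extracts the flux
#'   table, [glance()][generics::glance] the one-row summary.
#' @export
fba <- function(model, objective_rxn, sense = c("max", "min")) {
  sense <- match.arg(sense)
  S <- stoich_matrix(model)
  iobj <- rxn_index(model, objective_rxn)
  cvec <- rep(0, ncol(S))
  cvec[iobj] <- 1
  sol <- lp_solve(cvec, S, rep(0, nrow(S)), model$reactions$lb,
                  model$reactions$ub, sense = sense)
  flux_result(model, sol, objective_rxn, sense)
}

flux_result <- function(model, sol, objective_rxn, sense) {
  fluxes <- if (sol$status == "optimal") {
    tibble::tibble(id = model$reactions$id, flux = sol$x)
  } else {
    tibble::tibble(id = character(), flux = numeric())
  }
  structure(list(status = sol$status,
                 objective_value = sol$objval,
                 objective_rxn = objective_rxn,
                 sense = sense,
                 fluxes = fluxes),
            class = "sigflux_flux")
}

#' @export
print.sigflux_flux <- function(x, ...) {
  cat("<sigflux_flux> ", x$sense, " ", x$objective_rxn,
      ": status=", x$status, sep = "")
  if (x$status == "optimal") cat(", objective=", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Parsimonious (minimum L1-norm) flux balance analysis
#'
#' First optimizes the objective flux as [fba()], then — holding the
#' objective at its optimum — minimizes the total flux magnitude
#' `sum(|v_i|)`. The L1 norm is linearised by splitting each flux into
#' non-negative forward and reverse parts, so the whole computation stays
#' within the LP solver. Minimum-norm solutions suppress futile cycling:
#' internal loops that carry no net objective flux are driven to zero.
#'
#' @inheritParams fba
#' @return A `sigflux_flux` object whose `objective_value` is the optimal
#'   objective flux (not the norm) and whose `fluxes` have minimal L1 norm
#'   among objective-optimal flux vectors.
#' @export
fba_min_norm <- function(model, objective_rxn, sense = c("max", "min")) {
  sense <- match.arg(sense)
  first <- fba(model, objective_rxn, sense)
  if (first$status != "optimal") return(first)
  zstar <- first$objective_value
  S <- stoich_matrix(model)
  n <- ncol(S)
  m <- nrow(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  # v = p - q with p, q >= 0; bounds chosen so that p - q spans [lb, ub]
  plb <- pmax(lb, 0); pub <- pmax(ub, 0)
  qlb <- pmax(-ub, 0); qub <- pmax(-lb, 0)
  iobj <- rxn_index(model, objective_rxn)
  crow <- rep(0, n); crow[iobj] <- 1
  A <- rbind(cbind(S, -S), c(crow, -crow))
  b <- c(rep(0, m), zstar)
  sol <- lp_solve(rep(-1, 2 * n), A, b, c(plb, qlb), c(pub, qub),
                  sense = "max")
  if (sol$status != "optimal") {
    # the pinned optimum can sit on a numerical edge; fall back to plain FBA
    return(first)
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  flux_result(model, list(status = "optimal", x = v, objval = zstar),
              objective_rxn, sense)
}

#' Flux variability analysis
#'
#' Computes, for each requested reaction, the minimum and maximum feasible
#' flux over the full constraint set (two LPs per reaction). No objective
#' is fixed by default: the reported ranges are the raw capability of the
#' network under its current bounds, which is how output capacities are
#' read off stimulated models.
#'
#' @param model A `sigflux_model`.
#' @param reactions Reaction ids to analyse (default: all).
#' @return A tibble (class `sigflux_fva`) with columns `id`, `min_flux`,
#'   `max_flux`.
#' @export
fva <- function(model, reactions = NULL) {
  reactions <- reactions %||% model$reactions$id
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  b <- rep(0, nrow(S))
  res <- purrr::map_dfr(reactions, function(rid) {
    i <- rxn_index(model, rid)
    cvec <- rep(0, ncol(S))
    cvec[i] <- 1
    lo <- lp_solve(cvec, S, b, lb, ub, sense = "min")
    hi <- lp_solve(cvec, S, b, lb, ub, sense = "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("model infeasible during FVA (reaction ", rid, ")", call. = FALSE)
    }
    tibble::tibble(id = rid, min_flux = lo$objval, max_flux = hi$objval)
  })
  class(res) <- c("sigflux_fva", class(res))
  res
}

#' Robustness scan of an objective against a control bound
#'
#' Sweeps the lower bound of a control (exchange) reaction over a grid and
#' records the maximal achievable objective flux at each grid point, with
#' the control's upper bound held at 0 (pure uptake). The input model is
#' not modified. Grid points at which the model is infeasible are recorded
#' as `NA` rather than aborting the scan.
#'
#' @param model A `sigflux_model`.
#' @param control_rxn Exchange reaction whose lower bound is scanned.
#' @param objective_rxn Reaction whose maximum flux is recorded.
#' @param n_points Number of grid points (default 50).
#' @param lb_range Range of the control lower bound, default `c(-25, 0)`:
#'   uptake is negative flux, so the leftmost point is the most permissive.
#' @return A `sigflux_curve`: tibble with `control_lb` and `response`,
#'   attributes `control_rxn` and `objective_rxn`.
#' @export
robustness_scan <- function(model, control_rxn, objective_rxn,
                            n_points = 50, lb_range = c(-25, 0)) {
  stopifnot(n_points >= 2, length(lb_range) == 2, lb_range[1] != lb_range[2])
  grid <- seq(lb_range[1], lb_range[2], length.out = n_points)
  response <- vapply(grid, function(g) {
    m2 <- set_bounds(model, control_rxn, lb = g, ub = 0)
    sol <- fba(m2, objective_rxn, "max")
    if (sol$status == "optimal") sol$objective_value else NA_real_
  }, numeric(1))
  out <- tibble::tibble(control_lb = grid, response = response)
  attr(out, "control_rxn") <- control_rxn
  attr(out, "objective_rxn") <- objective_rxn
  class(out) <- c("sigflux_curve", class(out))
  out
}
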