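#' Presence/absence calls from detection p-values
#'
#' Converts probe-level detection p-values into per-gene present/absent
#' calls. For genes measured by several probes, only the probe with the
#' highest mean intensity in the *control* group is used — the rationale
#' being that the best-responding probe is the most trustworthy reporter,
#' and that this biases the procedure toward presence: it is more likely
#' to call an absent gene present than the reverse, which is the safe
#' direction when absent calls delete reactions.
#'
#' @param data Expression tibble as from [read_expression()] or
#'   [generate_expression_data()].
#' @param cutoff Detection p-value cutoff in `(0, 1)`; a probe detects its
#'   gene in a sample when `detection_p < cutoff`.
#' @param group Which sample group to call (`"control"` or `"treated"`).
#'   Probe selection always uses control intensities.
#' @param aggregate How per-sample detections combine into one call:
#'   `"majority"` (default; present when more than half the group's
#'   samples detect the gene), `"any"`, or `"all"`.
#' @return A call map: tibble with `gene_id` and `call`
#'   (`"present"`/`"absent"`). Genes with no probes are simply not listed;
#'   downstream evaluation treats unlisted genes as present.
#' @export
presence_calls <- function(data, cutoff, group = c("control", "treated"),
                           aggregate = c("majority", "any", "all")) {
  group <- match.arg(group)
  aggregate <- match.arg(aggregate)
  stopifnot(is.numeric(cutoff), cutoff > 0, cutoff < 1)
  sel <- data |>
    dplyr::filter(.data$group == "control") |>
    dplyr::summarise(mean_int = mean(.data$intensity),
                     .by = c("gene_id", "probe_id")) |>
    dplyr::slice_max(.data$mean_int, n = 1, by = "gene_id",
                     with_ties = FALSE)
  grp <- if (group == "control") "control" else "treated"
  agg_fun <- switch(aggregate,
                    majority = function(d) mean(d) > 0.5,
                    any = any,
                    all = all)
  data |>
    dplyr::filter(.data$group == grp) |>
    dplyr::semi_join(sel, by = c("gene_id", "probe_id")) |>
    dplyr::summarise(present = agg_fun(.data$detection_p < cutoff),
                     .by = "gene_id") |>
    dplyr::transmute(gene_id = .data$gene_id,
                     call = ifelse(.data$present, "present", "absent"))
}

#' Tailor a model to presence/absence calls
#'
#' Disables (pins to `lb = ub = 0`) every reaction whose GPR evaluates to
#' false under the calls: a reaction survives as long as at least one of
#' its isoforms is present, and reactions without gene association are
#' never touched. The returned statistics mirror the standard tailoring
#' report: absent genes, constrained reactions, and the blocked-reaction
#' and dead-end counts of the tailored network.
#'
#' @param model A `sigflux_model`.
#' @param calls A call map (tibble `gene_id`/`call`, or named vector; see
#'   [evaluate_gpr()]). Genes not listed default to present.
#' @param compute_stats Set `FALSE` to skip the (FVA-based) blocked count.
#' @return A `sigflux_tailoring`: list with `tailored` (model),
#'   `disabled_reactions`, `absent_genes`, and `stats` (one-row tibble:
#'   `n_deleted_genes`, `n_constrained_reactions`, `n_blocked`,
#'   `n_dead_ends`).
#' @export
tailor_model <- function(model, calls, compute_stats = TRUE) {
  present <- calls_as_logical(calls)
  pv <- unlist(present)
  absent <- if (length(pv) > 0) names(pv)[!pv] else character()
  active <- vapply(model$reactions$gpr_ast, gpr_eval_rec, logical(1),
                   present = present, default = TRUE)
  disabled <- model$reactions$id[!active]
  tailored <- model
  tailored$reactions$lb[!active] <- 0
  tailored$reactions$ub[!active] <- 0
  tailoring_result(tailored, disabled, absent, model, compute_stats)
}

tailoring_result <- function(tailored, disabled, absent, parent, compute_stats) {
  absent_in_model <- intersect(absent, genes_of(parent))
  stats <- tibble::tibble(
    n_deleted_genes = length(absent_in_model),
    n_constrained_reactions = length(disabled),
    n_blocked = if (compute_stats) length(find_blocked_reactions(tailored)) else NA_integer_,
    n_dead_ends = length(find_dead_ends(tailored)))
  structure(list(tailored = tailored,
                 disabled_reactions = disabled,
                 absent_genes = absent,
                 stats = stats),
            class = "sigflux_tailoring")
}

#' @export
print.sigflux_tailoring <- function(x, ...) {
  cat("<sigflux_tailoring> ", x$tailored$id, "\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Tailor an already-tailored model to a second condition
#'
#' Condition-specific tailoring on top of a cell-type-specific base model.
#' Genes that the condition newly reports as present but that are absent
#' from the base model stay excluded — once removed from the cell-type
#' model they are no longer part of it — while genes newly absent under
#' the condition disable their reactions exactly as in [tailor_model()].
#' Equivalently, the effective absent set is the union of the base and
#' condition absent sets.
#'
#' @param base A `sigflux_tailoring` (the cell-type model), or a model
#'   plus an explicit `base_absent` gene vector.
#' @param calls_condition Call map for the condition.
#' @param base_absent Absent genes of the base model (only needed when
#'   `base` is a bare model).
#' @param compute_stats As in [tailor_model()].
#' @return A `sigflux_tailoring` for the condition-specific model; its
#'   `absent_genes` is the union described above.
#' @export
condition_tailor <- function(base, calls_condition, base_absent = NULL,
                             compute_stats = TRUE) {
  if (inherits(base, "sigflux_tailoring")) {
    base_absent <- base$absent_genes
    base_model <- base$tailored
  } else {
    stopifnot(!is.null(base_absent))
    base_model <- base
  }
  present_cond <- calls_as_logical(calls_condition)
  pv <- unlist(present_cond)
  cond_absent <- if (length(pv) > 0) names(pv)[!pv] else character()
  eff_absent <- union(base_absent, cond_absent)
  eff_calls <- stats::setNames(rep("absent", length(eff_absent)), eff_absent)
  tailor_model(base_model, eff_calls, compute_stats = compute_stats)
}

#' Call differentially expressed genes from probe-level statistics
#'
#' A probe set is regulated when its absolute fold change reaches
#' `fc_thresh` and its FDR-adjusted p-value is below `fdr`; a gene is
#' up- (down-) regulated when at least `probe_fraction` of its probe sets
#' are regulated in that direction. Genes with some regulated probe sets
#' that do not reach the fraction are reported as *subthreshold* — they
#' carry a hint of regulation but are excluded from downstream flux
#' mapping. A gene whose probes qualify in both directions is demoted to
#' subthreshold with a warning.
#'
#' @param table Differential-expression tibble as from [read_diffexpr()]:
#'   `gene_id`, `probe_id`, `log2_fc`, `fdr_p`.
#' @param fc_thresh Linear fold-change threshold (default 2: twofold).
#' @param fdr FDR-adjusted p-value threshold (default 0.05).
#' @param probe_fraction Minimum fraction of a gene's probe sets that must
#'   be regulated (default 0.5).
#' @return A `sigflux_regulation`: list with `up` and `down` (named
#'   numeric vectors of linear fold-change magnitudes `> 1`, the mean over
#'   each gene's regulated probe sets) and `subthreshold` (gene ids).
#' @export
call_differential_expression <- function(table, fc_thresh = 2, fdr = 0.05,
                                         probe_fraction = 0.5) {
  stopifnot(fc_thresh > 0, fdr > 0, probe_fraction > 0)
  per_gene <- table |>
    dplyr::mutate(regulated = abs(.data$log2_fc) >= log2(fc_thresh) &
                    .data$fdr_p < fdr) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      n_up = sum(.data$regulated & .data$log2_fc > 0),
      n_down = sum(.data$regulated & .data$log2_fc < 0),
      fc_up = mean(2^.data$log2_fc[.data$regulated & .data$log2_fc > 0]),
      fc_down = mean(2^(-.data$log2_fc[.data$regulated & .data$log2_fc < 0])),
      .by = "gene_id")
  mixed <- per_gene$gene_id[per_gene$n_up > 0 & per_gene$n_down > 0]
  if (length(mixed) > 0) {
    warning("gene(s) with probes regulated in both directions demoted to ",
            "subthreshold: ", paste(mixed, collapse = ", "), call. = FALSE)
  }
  clean <- per_gene[!per_gene$gene_id %in% mixed, ]
  up_hit <- clean$n_up / clean$n_probes >= probe_fraction
  down_hit <- clean$n_down / clean$n_probes >= probe_fraction
  sub <- clean$gene_id[(clean$n_up > 0 | clean$n_down > 0) &
                         !up_hit & !down_hit]
  structure(list(
    up = stats::setNames(clean$fc_up[up_hit], clean$gene_id[up_hit]),
    down = stats::setNames(clean$fc_down[down_hit], clean$gene_id[down_hit]),
    subthreshold = c(sub, mixed)),
    class = "sigflux_regulation")
}

#' @export
print.sigflux_regulation <- function(x, ...) {
  cat("<sigflux_regulation> up: ", length(x$up),
      "  down: ", length(x$down),
      "  subthreshold: ", length(x$subthreshold), "\n", sep = "")
  invisible(x)
}

#' Map gene fold changes onto reactions
#'
#' Every reaction associated with at least one regulated gene receives a
#' reaction fold change `FCrxn`: the arithmetic mean of its regulated
#' genes' fold-change magnitudes. The data set's largest up- and
#' down-regulation serve as the reference fold changes (`FC-up`,
#' `FC-down`) against which `FCrxn` is later scaled when bounds are
#' adjusted. Reactions associated with both up- and down-regulated genes
#' are excluded with a warning (the scaling rule is directional).
#'
#' @param model A `sigflux_model`.
#' @param reg A `sigflux_regulation` from [call_differential_expression()].
#' @return A `sigflux_rxn_fc`: list with `table` (tibble `id`,
#'   `direction` (`up`/`down`), `fc_rxn`), `reference_up`, `reference_down`.
#' @export
reaction_fold_changes <- function(model, reg) {
  rows <- purrr::map_dfr(seq_len(nrow(model$reactions)), function(j) {
    gs <- gpr_genes(model$reactions$gpr_ast[[j]])
    ug <- intersect(gs, names(reg$up))
    dg <- intersect(gs, names(reg$down))
    if (length(ug) == 0 && length(dg) == 0) return(NULL)
    if (length(ug) > 0 && length(dg) > 0) {
      return(tibble::tibble(id = model$reactions$id[j], direction = "mixed",
                            fc_rxn = NA_real_))
    }
    if (length(ug) > 0) {
      tibble::tibble(id = model$reactions$id[j], direction = "up",
                     fc_rxn = mean(reg$up[ug]))
    } else {
      tibble::tibble(id = model$reactions$id[j], direction = "down",
                     fc_rxn = mean(reg$down[dg]))
    }
  })
  if (nrow(rows) > 0 && any(rows$direction == "mixed")) {
    warning("reaction(s) with both up- and down-regulated genes excluded ",
            "from fold-change mapping: ",
            paste(rows$id[rows$direction == "mixed"], collapse = ", "),
            call. = FALSE)
    rows <- rows[rows$direction != "mixed", ]
  }
  structure(list(table = rows,
                 reference_up = if (length(reg$up) > 0) max(reg$up) else NA_real_,
                 reference_down = if (length(reg$down) > 0) max(reg$down) else NA_real_),
            class = "sigflux_rxn_fc")
}

#' Adjust flux bounds to mimic differential expression
#'
#' Translates reaction fold changes into flux bounds around a reference
#' flux distribution (a parsimonious FBA solution for the same I/O
#' configuration). Up-regulation *enforces* flux: a reaction carrying
#' reference flux `v_ref > 0` gets its lower bound raised to
#' `(FCrxn / FC-up) * v_ref`, so the reaction with the data set's maximal
#' fold change is pinned at its full reference flux and weaker regulation
#' scales proportionally (mirrored on the upper bound for `v_ref < 0`).
#' Down-regulation *caps* flux: the bound on the reference-flux side is
#' scaled by `(1 - FCrxn / FC-down)`, reaching a hard shut-off for the
#' maximally down-regulated reaction. Reactions with zero reference flux
#' are left untouched — the data cannot say in which direction to push
#' them.
#'
#' @param model A `sigflux_model` (already I/O-configured).
#' @param rfc A `sigflux_rxn_fc` from [reaction_fold_changes()].
#' @param reference_flux A `sigflux_flux` from [fba_min_norm()] on the
#'   same configuration.
#' @param tol Reference fluxes within `tol` of zero count as zero.
#' @return The model with adjusted bounds; the per-reaction adjustment log
#'   is attached as attribute `"fc_log"` (tibble: `id`, `direction`,
#'   `fc_rxn`, `v_ref`, `lb`, `ub`). Bounds are clipped (with a warning)
#'   in the rare case an adjustment would cross `lb > ub`.
#' @export
apply_fold_change_bounds <- function(model, rfc, reference_flux, tol = 1e-9) {
  stopifnot(inherits(rfc, "sigflux_rxn_fc"),
            inherits(reference_flux, "sigflux_flux"))
  if (reference_flux$status != "optimal") {
    stop("reference flux distribution is not optimal", call. = FALSE)
  }
  vref <- stats::setNames(reference_flux$fluxes$flux, reference_flux$fluxes$id)
  log <- list()
  clipped <- character()
  for (k in seq_len(nrow(rfc$table))) {
    rid <- rfc$table$id[k]
    dirn <- rfc$table$direction[k]
    fcr <- rfc$table$fc_rxn[k]
    i <- rxn_index(model, rid)
    v <- vref[[rid]]
    if (is.null(v) || is.na(v) || abs(v) <= tol) {
      log[[k]] <- tibble::tibble(id = rid, direction = dirn, fc_rxn = fcr,
                                 v_ref = if (is.null(v)) NA_real_ else v,
                                 lb = model$reactions$lb[i],
                                 ub = model$reactions$ub[i])
      next
    }
    if (dirn == "up") {
      scale <- fcr / rfc$reference_up
      if (v > 0) {
        model$reactions$lb[i] <- max(model$reactions$lb[i], scale * v)
      } else {
        model$reactions$ub[i] <- min(model$reactions$ub[i], scale * v)
      }
    } else {
      scale <- 1 - fcr / rfc$reference_down
      if (v > 0) {
        model$reactions$ub[i] <- scale * model$reactions$ub[i]
      } else {
        model$reactions$lb[i] <- scale * model$reactions$lb[i]
      }
    }
    if (model$reactions$lb[i] > model$reactions$ub[i]) {
      clipped <- c(clipped, rid)
      if (dirn == "up") {
        model$reactions$ub[i] <- model$reactions$lb[i]
      } else {
        model$reactions$lb[i] <- model$reactions$ub[i]
      }
    }
    log[[k]] <- tibble::tibble(id = rid, direction = dirn, fc_rxn = fcr,
                               v_ref = v, lb = model$reactions$lb[i],
                               ub = model$reactions$ub[i])
  }
  if (length(clipped) > 0) {
    warning("bound adjustment clipped to keep lb <= ub for: ",
            paste(clipped, collapse = ", "), call. = FALSE)
  }
  attr(model, "fc_log") <- dplyr::bind_rows(log)
  model
}

#' Diagnose broken input/output pathways in a tailored model
#'
#' Compares the *participating* reaction set of a reference model — the
#' reactions able to carry nonzero flux while the relationship's output is
#' forced to a positive level — with the reactions still active in a
#' tailored draft. Reactions that participate in the reference but are
#' inactive in the draft are the missing links; the absent genes appearing
#' in their GPRs are the candidate genes whose reintroduction may repair
#' the output.
#'
#' @param reference The untailored `sigflux_model` (output must be
#'   feasible here; otherwise an error).
#' @param draft The tailored draft: a `sigflux_tailoring` or a model (then
#'   supply `absent_genes`).
#' @param io An [io_pair()] describing the stimulation and output.
#' @param absent_genes Absent genes of the draft (taken from a
#'   `sigflux_tailoring` automatically).
#' @param level Output flux level to force in the reference (default 1).
#' @param tol Activity tolerance.
#' @return A list with `missing_reactions` and `candidate_genes`.
#' @export
diagnose_io_gaps <- function(reference, draft, io, absent_genes = NULL,
                             level = 1, tol = 1e-6) {
  if (inherits(draft, "sigflux_tailoring")) {
    absent_genes <- draft$absent_genes
    draft <- draft$tailored
  }
  ref_cfg <- configure_io(reference, io, energy = "sensitivity")
  iout <- rxn_index(ref_cfg, io$output_rxn)
  ref_forced <- ref_cfg
  ref_forced$reactions$lb[iout] <- level
  ref_forced$reactions$ub[iout] <- max(ref_forced$reactions$ub[iout], level)
  part <- tryCatch(fva(ref_forced),
                   error = function(e) {
                     stop("output ", io$output_rxn,
                          " is infeasible in the reference model", call. = FALSE)
                   })
  participating <- part$id[abs(part$min_flux) > tol | abs(part$max_flux) > tol]
  draft_cfg <- configure_io(draft, io, energy = "sensitivity")
  act <- fva(draft_cfg)
  active <- act$id[abs(act$min_flux) > tol | abs(act$max_flux) > tol]
  missing <- setdiff(participating, active)
  gene_pool <- unique(unlist(
    lapply(model_gpr_for(reference, missing), gpr_genes), use.names = FALSE))
  list(missing_reactions = missing,
       candidate_genes = intersect(absent_genes %||% character(), gene_pool))
}

model_gpr_for <- function(model, rxn_ids) {
  model$reactions$gpr_ast[match(rxn_ids, model$reactions$id)]
}

#' Probe candidate genes by single-gene reintroduction
#'
#' For each candidate gene, re-tailors the reference model with that gene
#' restored to present (all other absent genes unchanged) and records the
#' maximal achievable flux through each output. Comparing these recoveries
#' against the draft shows which single gene repairs which output;
#' restoring an isoform of a gene that is already present changes nothing.
#'
#' @param draft A `sigflux_tailoring` (defines the absent set).
#' @param reference The untailored `sigflux_model`.
#' @param candidates Gene ids to probe (must be genes of the reference).
#' @param outputs Output reaction ids.
#' @param io Optional [io_pair()]; when given, each probe is run under
#'   that stimulation (energy scenario `"sensitivity"`).
#' @return A tibble with `gene_id`, `output_id`, `max_flux`.
#' @export
test_gene_reintroduction <- function(draft, reference, candidates, outputs,
                                     io = NULL) {
  stopifnot(inherits(draft, "sigflux_tailoring"))
  bad <- setdiff(candidates, genes_of(reference))
  if (length(bad) > 0) {
    stop("candidate gene(s) not in the reference model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(candidates, function(g) {
    absent <- setdiff(draft$absent_genes, g)
    calls <- stats::setNames(rep("absent", length(absent)), absent)
    t2 <- tailor_model(reference, calls, compute_stats = FALSE)
    m2 <- if (is.null(io)) t2$tailored else {
      configure_io(t2$tailored, io, energy = "sensitivity")
    }
    rng <- fva(m2, outputs)
    tibble::tibble(gene_id = g, output_id = rng$id, max_flux = rng$max_flux)
  })
}
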