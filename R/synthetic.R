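#' Generate a TLR-like toy signaling network with recorded ground truth
#'
#' Builds a receptor -> adaptor/kinase cascade -> transcription-factor
#' output network in the style of stoichiometric TLR signaling models:
#' each receptor has an extracellular ligand, a reversible ligand exchange
#' and a binding reaction gated by a single receptor gene; cascade steps
#' are gated by `OR` rules over isozymes and a configurable fraction of
#' them consume ATP; outputs are nuclear demand reactions fed by
#' `AND`-gated (two-gene complex) output reactions. Receptors are wired to
#' random non-empty output subsets, and the wiring is recorded as the
#' reachability ground truth. Optional planted features: orphan
#' extracellular ligands (dead ends feeding blocked binding reactions) and
#' isolated internal 2-cycles (loops).
#'
#' Stoichiometric coefficients are restricted to 1 and 2 so that expected
#' yields are exact rationals: with every input fixed at one flux unit,
#' the expected yield of a reachable output is 1, except for the second
#' output (when present), whose complex-formation step consumes two units
#' of its hub compound and therefore yields 0.5.
#'
#' @param n_receptors,cascade_depth,isozyme_multiplicity,n_outputs Network
#'   shape (all `>= 1`).
#' @param energy_coupling Fraction of cascade steps consuming ATP.
#' @param dead_end_fraction Orphan ligands planted per receptor (rounded).
#' @param loop_count Number of isolated internal 2-cycles.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list with `model` (a `sigflux_model`) and `truth`: a list
#'   holding `reachability` (tibble `input_id`, `output_id`, `reachable`),
#'   `expected_yields` (same grid with `yield`), `receptor_genes`,
#'   `isozyme_genes` (per-step gene lists), `essential_genes_per_output`
#'   (the `AND`-gated complex genes of each output), `orphan_ligands`,
#'   `orphan_bindings`, `loop_reactions`, `outputs` (demand reaction ids)
#'   and `io_pairs` (ready-made [io_pair()] list, one per
#'   receptor-output relationship).
#' @export
generate_toy_network <- function(n_receptors = 3, cascade_depth = 3,
                                 isozyme_multiplicity = 2, n_outputs = 3,
                                 energy_coupling = 0.5,
                                 dead_end_fraction = 0.3, loop_count = 1,
                                 seed = 1) {
  stopifnot(n_receptors >= 1, cascade_depth >= 1, isozyme_multiplicity >= 1,
            n_outputs >= 1, energy_coupling >= 0, energy_coupling <= 1,
            dead_end_fraction >= 0, dead_end_fraction <= 1, loop_count >= 0)
  rng <- local_rng(seed)

  cp <- list()
  rx <- list()
  gn <- list()
  add_cp <- function(id, role) {
    cp[[length(cp) + 1]] <<- tibble::tibble(id = id, name = id, role = role)
  }
  add_rx <- function(id, stoich, lb, ub, gpr, rclass) {
    rx[[length(rx) + 1]] <<- tibble::tibble(
      id = id, stoich = list(stoich), lb = lb, ub = ub, gpr = gpr,
      rclass = rclass)
  }
  add_gene <- function(gid, symbol) {
    gn[[length(gn) + 1]] <<- tibble::tibble(gene_id = gid, symbol = symbol,
                                            description = symbol)
  }

  add_cp("atp[c]", "metabolite"); add_cp("adp[c]", "metabolite")
  add_rx("EX_atp", c("atp[c]" = -1), -FLUX_BIG, FLUX_BIG, "", "exchange")
  add_rx("EX_adp", c("adp[c]" = -1), -FLUX_BIG, FLUX_BIG, "", "exchange")

  # energy coupling pattern: deterministic draw per (receptor, step)
  coupled <- matrix(rng$runif(n_receptors * cascade_depth) < energy_coupling,
                    n_receptors, cascade_depth)
  out_coupled <- rng$runif(n_outputs) < energy_coupling

  receptor_genes <- character(n_receptors)
  isozyme_genes <- list()
  for (i in seq_len(n_receptors)) {
    lig <- sprintf("lig%d[e]", i)
    add_cp(lig, "ligand")
    add_cp(sprintf("sig%d_0[c]", i), "protein")
    rgene <- sprintf("1%02d", i)
    receptor_genes[i] <- rgene
    add_gene(rgene, sprintf("RCPT%d", i))
    add_rx(sprintf("EX_lig%d", i), stats::setNames(-1, lig),
           -FLUX_BIG, FLUX_BIG, "", "exchange")
    add_rx(sprintf("BIND_R%d", i),
           stats::setNames(c(-1, 1), c(lig, sprintf("sig%d_0[c]", i))),
           0, FLUX_BIG, rgene, "binding")
    # escape sink so that a pinned binding flux never strands the signal
    add_rx(sprintf("SK_sig%d_0", i),
           stats::setNames(-1, sprintf("sig%d_0[c]", i)),
           0, FLUX_BIG, "", "sink")
    for (d in seq_len(cascade_depth)) {
      prev <- sprintf("sig%d_%d[c]", i, d - 1)
      cur <- sprintf("sig%d_%d[c]", i, d)
      add_cp(cur, "kinase")
      genes <- sprintf("%d%02d%d", 2 + d, i, seq_len(isozyme_multiplicity))
      isozyme_genes[[sprintf("r%d_step%d", i, d)]] <- genes
      for (g in genes) add_gene(g, sprintf("KIN%d_%d_%s", i, d, g))
      st <- stats::setNames(c(-1, 1), c(prev, cur))
      if (coupled[i, d]) st <- c(st, c("atp[c]" = -1, "adp[c]" = 1))
      add_rx(sprintf("CASC_R%d_S%d", i, d), st, 0, FLUX_BIG,
             paste(genes, collapse = " or "), "core")
    }
  }

  # wiring: each receptor reaches a random non-empty subset of outputs
  wiring <- matrix(FALSE, n_receptors, n_outputs)
  for (i in seq_len(n_receptors)) {
    k <- rng$sample(n_outputs, 1)
    wiring[i, rng$sample(n_outputs, k)] <- TRUE
  }

  essential <- list()
  outputs <- character(n_outputs)
  for (j in seq_len(n_outputs)) {
    hub <- sprintf("hub%d[c]", j)
    tf <- sprintf("tf%d[n]", j)
    add_cp(hub, "protein")
    add_cp(tf, "complex")
    ga <- sprintf("9%02d1", j); gb <- sprintf("9%02d2", j)
    add_gene(ga, sprintf("TF%da", j)); add_gene(gb, sprintf("TF%db", j))
    essential[[sprintf("DM_out%d", j)]] <- c(ga, gb)
    hub_coef <- if (j == 2) 2 else 1
    st <- stats::setNames(c(-hub_coef, 1), c(hub, tf))
    if (out_coupled[j]) st <- c(st, c("atp[c]" = -1, "adp[c]" = 1))
    add_rx(sprintf("OUT%d", j), st, 0, FLUX_BIG,
           paste(ga, "and", gb), "core")
    outputs[j] <- sprintf("DM_out%d", j)
    add_rx(outputs[j], stats::setNames(-1, tf), 0, FLUX_BIG, "", "demand")
  }
  for (i in seq_len(n_receptors)) {
    top <- sprintf("sig%d_%d[c]", i, cascade_depth)
    for (j in which(wiring[i, ])) {
      add_rx(sprintf("BR_R%d_O%d", i, j),
             stats::setNames(c(-1, 1), c(top, sprintf("hub%d[c]", j))),
             0, FLUX_BIG, "", "core")
    }
  }

  orphan_ligands <- orphan_bindings <- character()
  n_orphans <- round(dead_end_fraction * n_receptors)
  for (t in seq_len(n_orphans)) {
    lig <- sprintf("orphan%d[e]", t)
    add_cp(lig, "ligand")
    ogene <- sprintf("7%02d", t)
    add_gene(ogene, sprintf("ORPH%d", t))
    tgt <- sprintf("sig%d_0[c]", 1 + (t - 1) %% n_receptors)
    add_rx(sprintf("BIND_ORPH%d", t),
           stats::setNames(c(-1, 1), c(lig, tgt)),
           0, FLUX_BIG, ogene, "binding")
    orphan_ligands <- c(orphan_ligands, lig)
    orphan_bindings <- c(orphan_bindings, sprintf("BIND_ORPH%d", t))
  }

  loop_reactions <- character()
  for (t in seq_len(loop_count)) {
    a <- sprintf("loopx%d[c]", t); bcp <- sprintf("loopy%d[c]", t)
    add_cp(a, "protein"); add_cp(bcp, "protein")
    add_rx(sprintf("LOOPF%d", t), stats::setNames(c(-1, 1), c(a, bcp)),
           0, FLUX_BIG, "", "core")
    add_rx(sprintf("LOOPR%d", t), stats::setNames(c(-1, 1), c(bcp, a)),
           0, FLUX_BIG, "", "core")
    loop_reactions <- c(loop_reactions, sprintf("LOOPF%d", t),
                        sprintf("LOOPR%d", t))
  }

  model <- new_model(dplyr::bind_rows(cp), dplyr::bind_rows(rx),
                     dplyr::bind_rows(gn),
                     id = sprintf("toy_seed%d", seed))

  grid <- tidyr::expand_grid(input_id = sprintf("R%d", seq_len(n_receptors)),
                             output_id = outputs)
  reach <- wiring[cbind(match(grid$input_id, sprintf("R%d", seq_len(n_receptors))),
                        match(grid$output_id, outputs))]
  yields <- ifelse(reach, ifelse(grid$output_id == "DM_out2", 0.5, 1), 0)
  io_pairs <- purrr::pmap(grid, function(input_id, output_id) {
    i <- as.integer(sub("^R", "", input_id))
    io_pair(input_id, sprintf("EX_lig%d", i), sprintf("BIND_R%d", i),
            output_id)
  })

  truth <- list(
    reachability = dplyr::mutate(grid, reachable = reach),
    expected_yields = dplyr::mutate(grid, yield = yields),
    receptor_genes = stats::setNames(receptor_genes,
                                     sprintf("R%d", seq_len(n_receptors))),
    isozyme_genes = isozyme_genes,
    essential_genes_per_output = essential,
    orphan_ligands = orphan_ligands,
    orphan_bindings = orphan_bindings,
    loop_reactions = loop_reactions,
    outputs = outputs,
    io_pairs = io_pairs)
  list(model = model, truth = truth)
}

# deterministic generator-local RNG that never touches the global stream
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(f) {
    function(...) {
      prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(prev)) rm(".Random.seed", envir = globalenv()) else
          assign(".Random.seed", prev, globalenv())
      })
      f(...)
    }
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       rlnorm = with_state(stats::rlnorm),
       sample = with_state(function(x, size) sample(x, size)))
}

#' Generate probe-level expression data with planted absent genes
#'
#' Emulates the detection-p-value input of presence/absence calling:
#' a chosen fraction of the model's genes is planted absent; present genes
#' get detection p-values near 0 and high intensities, absent genes
#' p-values near 1 and low intensities. `noise` widens both p-value
#' distributions toward 0.5 (at `noise = 0` they are exactly 0 and 1, so
#' any cutoff in `(0, 1)` recovers the planted truth). A fraction of genes
#' gets a second, lower-intensity probe so the probe-selection rule is
#' exercised.
#'
#' @param model A `sigflux_model` (genes taken from its GPRs).
#' @param absent_fraction Fraction of genes planted absent.
#' @param noise In `[0, 1)`: half-width of the detection-p spread.
#' @param n_samples Samples per group (both `control` and `treated` sample
#'   groups are emitted, sharing the planted truth).
#' @param multi_probe_fraction Fraction of genes with two probes.
#' @param seed Integer seed.
#' @return A list with `data` (expression tibble as [read_expression()]
#'   returns) and `absent_genes` (the planted truth).
#' @export
generate_expression_data <- function(model, absent_fraction = 0.2, noise = 0,
                                     n_samples = 3, multi_probe_fraction = 0.3,
                                     seed = 1) {
  stopifnot(absent_fraction >= 0, absent_fraction <= 1, noise >= 0, noise < 1,
            n_samples >= 1)
  genes <- sort(genes_of(model))
  rng <- local_rng(seed)
  n_absent <- round(absent_fraction * length(genes))
  absent <- if (n_absent > 0) sort(genes[rng$sample(length(genes), n_absent)]) else character()
  samples <- tidyr::expand_grid(group = c("control", "treated"),
                                rep = seq_len(n_samples))
  samples$sample_id <- paste0(samples$group, "_", samples$rep)
  rows <- purrr::map_dfr(genes, function(g) {
    is_abs <- g %in% absent
    n_probes <- 1 + (rng$runif(1) < multi_probe_fraction)
    purrr::map_dfr(seq_len(n_probes), function(p) {
      base_int <- if (is_abs) 50 else 500
      # later probes report weaker signal; the calling rule must pick probe 1
      probe_int <- base_int / p
      tibble::tibble(
        probe_id = sprintf("%s_at%d", g, p),
        gene_id = g,
        sample_id = samples$sample_id,
        group = samples$group,
        detection_p = if (is_abs) 1 - rng$runif(nrow(samples)) * noise
                      else rng$runif(nrow(samples)) * noise,
        intensity = probe_int * exp(rng$rnorm(nrow(samples)) * 0.1))
    })
  })
  list(data = rows, absent_genes = absent)
}

#' Generate a differential-expression table with known regulation
#'
#' Plants `n_up` up- and `n_down` down-regulated genes (fold changes drawn
#' uniformly from `fc_range`, identical across each gene's probes, FDR
#' p-values well below threshold) among null genes whose probes fail both
#' the fold-change and the significance criterion.
#'
#' @param model A `sigflux_model`.
#' @param n_up,n_down Numbers of regulated genes (`n_up + n_down` at most
#'   the model's gene count).
#' @param fc_range Linear fold-change range for regulated genes.
#' @param n_probes Probe sets per gene.
#' @param seed Integer seed.
#' @return A list with `table` (tibble `gene_id`, `probe_id`, `log2_fc`,
#'   `fdr_p`) and `truth` (a `sigflux_regulation` with the planted sets).
#' @export
generate_regulation <- function(model, n_up = 4, n_down = 2,
                                fc_range = c(2, 8), n_probes = 2, seed = 1) {
  genes <- sort(genes_of(model))
  stopifnot(n_up + n_down <= length(genes))
  rng <- local_rng(seed)
  picked <- if (n_up + n_down > 0) genes[rng$sample(length(genes), n_up + n_down)] else character()
  up <- picked[seq_len(n_up)]
  down <- picked[n_up + seq_len(n_down)]
  fc_of <- function(n) fc_range[1] + rng$runif(n) * diff(fc_range)
  up_fc <- stats::setNames(fc_of(length(up)), up)
  down_fc <- stats::setNames(fc_of(length(down)), down)
  tab <- purrr::map_dfr(genes, function(g) {
    l2 <- if (g %in% up) log2(up_fc[[g]])
          else if (g %in% down) -log2(down_fc[[g]])
          else rng$runif(1) * 1.6 - 0.8
    p <- if (g %in% picked) 1e-4 else 0.2 + rng$runif(1) * 0.8
    tibble::tibble(gene_id = g,
                   probe_id = sprintf("%s_at%d", g, seq_len(n_probes)),
                   log2_fc = l2, fdr_p = p)
  })
  truth <- structure(list(up = up_fc, down = down_fc,
                          subthreshold = character()),
                     class = "sigflux_regulation")
  list(table = tab, truth = truth)
}
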