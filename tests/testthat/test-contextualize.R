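make_expr <- function(df) {
  # expand per-sample rows from a compact spec:
  # gene, probe, p_control, int_control
  purrr::pmap_dfr(df, function(gene, probe, p, int) {
    tibble::tibble(probe_id = probe, gene_id = gene,
                   sample_id = paste0("control_", 1:3), group = "control",
                   detection_p = p, intensity = int)
  })
}

test_that("presence calling follows the highest-intensity probe", {
  # single confident probe
  d1 <- make_expr(tibble::tibble(gene = "g1", probe = "p1", p = 0.001,
                                 int = 500))
  expect_equal(presence_calls(d1, 0.02),
               tibble::tibble(gene_id = "g1", call = "present"))
  # two probes: the high-intensity probe is absent, the low one present;
  # the call must follow the high-intensity probe
  d2 <- make_expr(tibble::tibble(gene = "g1", probe = c("hi", "lo"),
                                 p = c(0.9, 0.001), int = c(800, 50)))
  expect_equal(presence_calls(d2, 0.02)$call, "absent")
  # majority aggregation across replicates
  d3 <- tibble::tibble(probe_id = "p1", gene_id = "g1",
                       sample_id = paste0("control_", 1:3), group = "control",
                       detection_p = c(0.001, 0.9, 0.9), intensity = 100)
  expect_equal(presence_calls(d3, 0.02)$call, "absent")
  expect_equal(presence_calls(d3, 0.02, aggregate = "any")$call, "present")
  expect_equal(presence_calls(d3, 0.02, aggregate = "all")$call, "absent")
  expect_error(presence_calls(d3, 1.2), "cutoff")
})

test_that("treated-group calls use control intensities for probe selection", {
  d <- dplyr::bind_rows(
    make_expr(tibble::tibble(gene = "g1", probe = c("hi", "lo"),
                             p = c(0.001, 0.001), int = c(800, 50))),
    tibble::tibble(probe_id = rep(c("hi", "lo"), 3), gene_id = "g1",
                   sample_id = rep(paste0("treated_", 1:3), each = 2),
                   group = "treated",
                   detection_p = rep(c(0.9, 0.001), 3),
                   intensity = rep(c(10, 900), 3)))
  # in the treated group the high-control-intensity probe reads absent
  expect_equal(presence_calls(d, 0.02, group = "treated")$call, "absent")
  expect_equal(presence_calls(d, 0.02, group = "control")$call, "present")
})

test_that("tailoring disables only reactions whose whole isoform set is absent", {
  m <- mini_tlr()
  all_present <- tailor_model(m, call_map(absent = character()),
                              compute_stats = FALSE)
  expect_length(all_present$disabled_reactions, 0)
  # one adaptor isozyme absent: OR rule keeps the reactions active
  one_iso <- tailor_model(m, call_map(absent = "201"), compute_stats = FALSE)
  expect_length(one_iso$disabled_reactions, 0)
  both_iso <- tailor_model(m, call_map(absent = c("201", "202")))
  expect_setequal(both_iso$disabled_reactions,
                  c("ADAPT_A", "ADAPT_B", "ADAPT_C"))
  expect_equal(get_bounds(both_iso$tailored, "ADAPT_A")$ub, 0)
  # one subunit of an AND complex suffices to disable
  sub <- tailor_model(m, call_map(absent = "402"), compute_stats = FALSE)
  expect_equal(sub$disabled_reactions, "KIN2")
  # stats are reproducible from the tailored model
  expect_equal(both_iso$stats$n_constrained_reactions, 3)
  expect_equal(both_iso$stats$n_deleted_genes, 2)
  expect_equal(both_iso$stats$n_blocked,
               length(find_blocked_reactions(both_iso$tailored)))
  expect_equal(both_iso$stats$n_dead_ends,
               length(find_dead_ends(both_iso$tailored)))
})

test_that("tailoring is monotone in the absent set and idempotent", {
  set.seed(9)
  for (rep in 1:4) {
    net <- generate_toy_network(seed = rep)
    genes <- genes_of(net$model)
    small <- sample(genes, length(genes) %/% 4)
    large <- union(small, sample(genes, length(genes) %/% 3))
    t_small <- tailor_model(net$model, call_map(absent = small),
                            compute_stats = FALSE)
    t_large <- tailor_model(net$model, call_map(absent = large),
                            compute_stats = FALSE)
    # larger absent set => active set is a subset
    active <- function(t) setdiff(t$tailored$reactions$id, t$disabled_reactions)
    expect_true(all(active(t_large) %in% active(t_small)))
    # idempotence
    t_again <- tailor_model(t_small$tailored, call_map(absent = small),
                            compute_stats = FALSE)
    expect_equal(t_again$tailored$reactions$lb, t_small$tailored$reactions$lb)
    expect_equal(t_again$tailored$reactions$ub, t_small$tailored$reactions$ub)
  }
})

test_that("condition tailoring never re-adds genes absent from the base", {
  m <- mini_tlr()
  base <- tailor_model(m, call_map(absent = c("104", "105")),
                       compute_stats = FALSE)
  # identical condition: no change
  same <- condition_tailor(base, call_map(absent = c("104", "105")),
                           compute_stats = FALSE)
  expect_equal(same$tailored$reactions$lb, base$tailored$reactions$lb)
  # gene newly present in the condition stays excluded
  readd <- condition_tailor(base, call_map(absent = "105",
                                           present = "104"),
                            compute_stats = FALSE)
  expect_true("104" %in% readd$absent_genes)
  expect_equal(get_bounds(readd$tailored, "BIND_O1")$ub, 0)
  # genes newly absent disable exactly their reactions
  lps <- condition_tailor(base, call_map(absent = c("504", "505")),
                          compute_stats = FALSE)
  expect_setequal(setdiff(lps$disabled_reactions, base$disabled_reactions),
                  c("TF_CREB", "TF_IRF"))
})

test_that("differential-expression calling applies the probe-fraction rule", {
  tab <- tibble::tibble(
    gene_id = c("u1", "u1", "half", "half", "sub", "sub", "sub",
                 "null", "dn"),
    probe_id = c("a", "b", "a", "b", "a", "b", "c", "a", "a"),
    log2_fc = c(log2(3), log2(3), log2(4), 0.1, log2(5), 0.2, 0.1,
                 0.4, -log2(6)),
    fdr_p = c(0.01, 0.01, 0.01, 0.8, 0.001, 0.5, 0.9, 0.9, 0.001))
  reg <- call_differential_expression(tab)
  expect_equal(reg$up, c(u1 = 3, half = 4))     # 1 of 2 meets the 50% rule
  expect_equal(reg$down, c(dn = 6))
  expect_equal(reg$subthreshold, "sub")          # 1 of 3 probes is below 50%
  expect_equal(tidy(reg)$direction,
               c("up", "up", "down", "subthreshold"))
  # mixed-direction gene demoted with a warning
  mixed <- tibble::tibble(gene_id = "mx", probe_id = c("a", "b"),
                          log2_fc = c(2, -2), fdr_p = 0.01)
  expect_warning(regm <- call_differential_expression(mixed), "both directions")
  expect_equal(regm$subthreshold, "mx")
  expect_length(regm$up, 0)
})

test_that("reaction fold changes average regulated genes and set references", {
  m <- mini_tlr()
  reg <- structure(list(up = c(`502` = 2, `503` = 6, `501` = 8),
                        down = c(`504` = 3), subthreshold = character()),
                   class = "sigflux_regulation")
  rfc <- reaction_fold_changes(m, reg)
  expect_equal(rfc$reference_up, 8)
  expect_equal(rfc$reference_down, 3)
  tab <- rfc$table
  # mean rule: genes FC 2 and 6 on one reaction give FCrxn 4
  expect_equal(tab$fc_rxn[tab$id == "TF_AP1"], 4)
  expect_equal(tab$fc_rxn[tab$id == "TF_NFKB"], 8)
  expect_equal(tab$direction[tab$id == "TF_CREB"], "down")
  # no regulated genes: empty mapping
  empty <- reaction_fold_changes(m, structure(
    list(up = numeric(), down = numeric(), subthreshold = character()),
    class = "sigflux_regulation"))
  expect_equal(nrow(empty$table), 0)
  # mixed regulation on one reaction excluded with a warning
  regmx <- structure(list(up = c(`401` = 2), down = c(`402` = 2),
                          subthreshold = character()),
                     class = "sigflux_regulation")
  expect_warning(out <- reaction_fold_changes(m, regmx), "excluded")
  expect_false("KIN2" %in% out$table$id)
})

test_that("fold-change bounds enforce and cap flux around the reference", {
  m <- mini_tlr()
  io <- mini_tlr_io()
  cfg <- configure_io(m, io$pairs$RA, energy = "sensitivity")
  ref <- fba_min_norm(cfg, "DM_nfkb")
  vref <- stats::setNames(ref$fluxes$flux, ref$fluxes$id)
  expect_equal(unname(vref["TF_NFKB"]), 1)
  # FCrxn = FC-up pins the reaction at its reference flux
  reg <- structure(list(up = c(`501` = 4), down = numeric(),
                        subthreshold = character()),
                   class = "sigflux_regulation")
  rfc <- reaction_fold_changes(m, reg)
  adj <- apply_fold_change_bounds(cfg, rfc, ref)
  expect_equal(get_bounds(adj, "TF_NFKB")$lb, unname(vref["TF_NFKB"]))
  expect_equal(fva(adj, "TF_NFKB")$min_flux, unname(vref["TF_NFKB"]))
  # half the reference fold change enforces half the reference flux
  reg2 <- structure(list(up = c(`501` = 2, `201` = 4), down = numeric(),
                         subthreshold = character()),
                    class = "sigflux_regulation")
  adj2 <- apply_fold_change_bounds(cfg, reaction_fold_changes(m, reg2), ref)
  expect_equal(get_bounds(adj2, "TF_NFKB")$lb, 0.5 * unname(vref["TF_NFKB"]))
  # FCrxn = FC-down forces the capacity to zero
  reg3 <- structure(list(up = numeric(), down = c(`501` = 5),
                         subthreshold = character()),
                    class = "sigflux_regulation")
  adj3 <- apply_fold_change_bounds(cfg, reaction_fold_changes(m, reg3), ref)
  expect_equal(get_bounds(adj3, "TF_NFKB")$ub, 0)
  expect_equal(fva(adj3, "DM_nfkb")$max_flux, 0)
  # zero-reference reactions are untouched (IRF path carries no flux here)
  reg4 <- structure(list(up = c(`505` = 4), down = numeric(),
                         subthreshold = character()),
                    class = "sigflux_regulation")
  adj4 <- apply_fold_change_bounds(cfg, reaction_fold_changes(m, reg4), ref)
  expect_equal(get_bounds(adj4, "TF_IRF"), get_bounds(cfg, "TF_IRF"))
  log <- attr(adj4, "fc_log")
  expect_equal(log$v_ref, 0)
})

test_that("gap diagnosis recovers planted missing links and candidate genes", {
  m <- mini_tlr()
  io <- mini_tlr_io()
  draft <- tailor_model(m, call_map(absent = c("401", "104", "105")),
                        compute_stats = FALSE)
  gaps <- diagnose_io_gaps(m, draft, io$pairs$RA)
  expect_true("KIN2" %in% gaps$missing_reactions)
  expect_equal(gaps$candidate_genes, "401")
  # draft identical to reference: nothing missing
  full <- tailor_model(m, call_map(absent = character()),
                       compute_stats = FALSE)
  none <- diagnose_io_gaps(m, full, io$pairs$RA)
  expect_length(none$missing_reactions, 0)
  expect_length(none$candidate_genes, 0)
  # an infeasible reference output is an error
  dead <- set_bounds(m, "TF_NFKB", lb = 0, ub = 0)
  expect_error(diagnose_io_gaps(dead, draft, io$pairs$RA), "infeasible")
})

test_that("single-gene reintroduction recovers outputs; spare isoforms do not", {
  m <- mini_tlr()
  io <- mini_tlr_io()
  draft <- tailor_model(m, call_map(absent = c("401", "301", "302", "303")),
                        compute_stats = FALSE)
  cfg_draft <- configure_io(draft$tailored, io$pairs$RA,
                            energy = "sensitivity")
  expect_equal(fva(cfg_draft, "DM_nfkb")$max_flux, 0)
  rec <- test_gene_reintroduction(draft, m, c("301", "401"), "DM_nfkb",
                                  io = io$pairs$RA)
  # restoring one kinase-1 isozyme re-opens the cascade (401 still absent
  # blocks it; 301 alone cannot because the complex stays broken)
  expect_equal(rec$max_flux[rec$gene_id == "301"], 0)
  expect_equal(rec$max_flux[rec$gene_id == "401"], 0)
  draft2 <- tailor_model(m, call_map(absent = c("301", "302", "303")),
                         compute_stats = FALSE)
  rec2 <- test_gene_reintroduction(draft2, m, c("301", "504"), "DM_nfkb",
                                   io = io$pairs$RA)
  expect_equal(rec2$max_flux[rec2$gene_id == "301"], 1)
  # reintroducing an isoform of a present gene changes nothing
  draft3 <- tailor_model(m, call_map(absent = "201"), compute_stats = FALSE)
  rec3 <- test_gene_reintroduction(draft3, m, "201", "DM_nfkb",
                                   io = io$pairs$RA)
  cfg3 <- configure_io(draft3$tailored, io$pairs$RA, energy = "sensitivity")
  expect_equal(rec3$max_flux, fva(cfg3, "DM_nfkb")$max_flux)
  # empty candidate set: empty table
  expect_equal(nrow(test_gene_reintroduction(draft, m, character(),
                                             "DM_nfkb")), 0)
  expect_error(test_gene_reintroduction(draft, m, "nope", "DM_nfkb"),
               "not in the reference")
})
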