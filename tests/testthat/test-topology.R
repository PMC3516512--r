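test_that("dead-end detection accounts for reversibility and closed bounds", {
  # C produced but never consumed
  m <- quick_model(c("r1", "r2"), c("A[c] <=> B[c]", "B[c] -> C[c]"))
  expect_true("C[c]" %in% find_dead_ends(m))
  expect_false("B[c]" %in% find_dead_ends(m))
  # a compound on a reversible exchange is not a dead end
  m2 <- quick_model(c("EX", "r"), c("A[e] <=>", "A[e] -> B[c]"),
                    rclass = c("exchange", "core"))
  expect_false("A[e]" %in% find_dead_ends(m2))
  expect_true("B[c]" %in% find_dead_ends(m2))
  # pinning the exchange closed turns A into a dead end too
  m3 <- set_bounds(m2, "EX", lb = 0, ub = 0)
  expect_setequal(find_dead_ends(m3), c("A[e]", "B[c]"))
  # miniTLR ships with exactly the two planted orphan ligands
  expect_setequal(find_dead_ends(mini_tlr()), c("orphan1[e]", "orphan2[e]"))
})

test_that("blocked reactions are exactly the zero-FVA-interval set", {
  m <- mini_tlr()
  expect_setequal(find_blocked_reactions(m), c("BIND_O1", "BIND_O2"))
  # open chain: nothing blocked
  expect_length(find_blocked_reactions(chain_model()), 0)
  # cross-check against the enumeration oracle on random networks
  set.seed(5)
  for (rep in 1:5) {
    rn <- random_network()
    want <- oracle_fva(rn)
    expect_setequal(find_blocked_reactions(rn),
                    want$id[abs(want$min_flux) <= 1e-6 &
                              abs(want$max_flux) <= 1e-6])
  }
  # disabling the only kinase-2 complex blocks the whole downstream branch
  t1 <- tailor_model(m, call_map(absent = c("401")), compute_stats = FALSE)
  blocked <- find_blocked_reactions(t1$tailored)
  expect_true(all(c("KIN2", "TF_NFKB", "TF_AP1", "TF_CREB", "NFKB_TRANS",
                    "AP1_TRANS", "DM_nfkb", "DM_ap1") %in% blocked))
  expect_false("ROS_SYN" %in% blocked)  # branches off upstream of kinase 2
})

test_that("patching dead-end ligands with exchanges unblocks their bindings", {
  m <- mini_tlr()
  patched <- add_exchanges_for_dead_ends(m)
  expect_setequal(patched$added, c("EX_orphan1[e]", "EX_orphan2[e]"))
  expect_length(find_blocked_reactions(patched$model), 0)
  expect_length(find_dead_ends(patched$model), 0)
  # idempotent: nothing further to add
  again <- add_exchanges_for_dead_ends(patched$model)
  expect_length(again$added, 0)
  expect_equal(nrow(again$model$reactions), nrow(patched$model$reactions))
  # no dead ends: model unchanged
  none <- add_exchanges_for_dead_ends(chain_model())
  expect_length(none$added, 0)
  # selector restricts the patched compartment
  cytn <- add_exchanges_for_dead_ends(
    quick_model("r", "A[c] -> B[n]"), selector = "n")
  expect_equal(cytn$added, "EX_B[n]")
})

test_that("patching never increases the blocked set", {
  set.seed(17)
  for (rep in 1:5) {
    net <- generate_toy_network(n_receptors = 2, dead_end_fraction = 1,
                                seed = rep)
    before <- find_blocked_reactions(net$model)
    res <- add_exchanges_for_dead_ends(net$model)
    after <- find_blocked_reactions(res$model)
    expect_true(all(after %in% before))
  }
})

test_that("connectivity reports degrees and entity-relative ratios", {
  m <- quick_model(c("r1", "r2", "r3"),
                   c("A[c] -> B[c]", "A[c] -> C[c]", "A[c] -> D[c]"))
  con <- connectivity(m)
  expect_equal(con$degree[con$compound_id == "A[c]"], 3)
  expect_equal(con$ratio[con$compound_id == "A[c]"], 3 / 4)
  # isolated compound: degree zero
  m$compounds <- dplyr::bind_rows(m$compounds,
                                  tibble::tibble(id = "Z[c]", name = "Z",
                                                 compartment = "c",
                                                 role = "protein"))
  expect_equal(connectivity(m)$degree[connectivity(m)$compound_id == "Z[c]"], 0)
  # ATP is a maximally connected currency compound of the miniTLR fixture
  con_m <- connectivity(mini_tlr())
  expect_equal(con_m$degree[con_m$compound_id == "atp[c]"], max(con_m$degree))
  # sum of degrees equals the number of nonzero stoichiometric entries
  expect_equal(sum(connectivity(mini_tlr())$degree),
               sum(stoich_matrix(mini_tlr()) != 0))
})

test_that("gene-set sub-networks collect associated reactions and compounds", {
  m <- mini_tlr()
  empty <- extract_subnetwork(m, character())
  expect_length(empty$reaction_ids, 0)
  expect_length(empty$compound_ids, 0)
  one <- extract_subnetwork(m, "504")
  expect_equal(one$reaction_ids, "TF_CREB")
  expect_setequal(one$compound_ids, c("kin2[c]", "tfCREB[c]"))
  # a 4-gene up-set, hand-enumerated
  up <- extract_subnetwork(m, c("201", "501", "502", "503"),
                           outputs = c("TF_NFKB", "DM_ap1"))
  expect_setequal(up$reaction_ids,
                  c("ADAPT_A", "ADAPT_B", "ADAPT_C", "TF_NFKB", "TF_AP1"))
  expect_equal(glance(up)$n_compounds, 9)
  expect_equal(up$includes_outputs, "TF_NFKB")
  # sub-network connectivity uses its own compound count as denominator
  con <- connectivity(up)
  expect_equal(con$ratio, con$degree / 9)
})

test_that("graph export is bipartite, deterministic and component-faithful", {
  m <- mini_tlr()
  g <- as_bipartite_graph(m)
  expect_equal(igraph::vcount(g), nrow(m$compounds) + nrow(m$reactions))
  expect_equal(igraph::ecount(g), sum(stoich_matrix(m) != 0))
  # single reaction A -> B: 2 compound nodes, 1 reaction node, 2 edges
  g1 <- as_bipartite_graph(quick_model("r", "A[c] -> B[c]"))
  expect_equal(igraph::vcount(g1), 3)
  expect_equal(igraph::ecount(g1), 2)
  # empty sub-network gives an empty graph
  g0 <- as_bipartite_graph(extract_subnetwork(m, character()))
  expect_equal(igraph::vcount(g0), 0)
  # disconnected regulated modules are recoverable as components:
  # genes on the ROS branch and on the isolated loop induce 2 modules
  sub <- extract_subnetwork(m, c("601", "701"))
  comp <- igraph::components(as_bipartite_graph(sub))
  expect_equal(comp$no, 2)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(sub, path)
  reread <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(reread), igraph::vcount(as_bipartite_graph(sub)))
  # byte-identical on re-export
  path2 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(sub, path2)
  expect_identical(readLines(path), readLines(path2))
})
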