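test_that("FBA solves conservation-limited chains and closed networks", {
  m <- chain_model(uptake = 1)
  sol <- fba(m, "DM_B")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1)
  expect_equal(tidy(sol)$flux, c(-1, 1, 1))
  expect_equal(glance(sol)$objective_rxn, "DM_B")
  # closed exchanges, loop-free: nothing can flow
  closed <- set_bounds(m, "EX_A", lb = 0, ub = 0)
  expect_equal(fba(closed, "DM_B")$objective_value, 0)
  # infeasible: uptake forced but no consumer open
  broken <- set_bounds(m, "EX_A", lb = -1, ub = -1)
  broken <- set_bounds(broken, "R1", lb = 0, ub = 0)
  res <- fba(broken, "DM_B")
  expect_equal(res$status, "infeasible")
  expect_equal(nrow(res$fluxes), 0)
})

test_that("optimal flux vectors satisfy steady state and bounds", {
  set.seed(11)
  for (rep in 1:10) {
    m <- random_network()
    sol <- fba(m, sample(m$reactions$id, 1))
    expect_equal(sol$status, "optimal")  # v = 0 is always feasible here
    v <- tidy(sol)$flux
    expect_lt(max(abs(stoich_matrix(m) %*% v)), 1e-6)
    expect_true(all(v >= m$reactions$lb - 1e-6))
    expect_true(all(v <= m$reactions$ub + 1e-6))
  }
})

test_that("FBA and FVA agree with the vertex-enumeration oracle", {
  set.seed(23)
  for (rep in 1:12) {
    m <- random_network()
    want <- oracle_fva(m)
    got <- fva(m)
    expect_equal(got$min_flux, want$min_flux, tolerance = 1e-6)
    expect_equal(got$max_flux, want$max_flux, tolerance = 1e-6)
    # FVA max of any reaction equals its FBA max
    for (rid in m$reactions$id) {
      expect_equal(fba(m, rid, "max")$objective_value,
                   got$max_flux[got$id == rid], tolerance = 1e-6)
    }
  }
})

test_that("minimum-norm FBA picks single paths and kills pure loops", {
  # redundant parallel path: one-step route must win over the two-step one
  m <- quick_model(
    c("EX_A", "P2", "P1a", "P1b", "DM_B"),
    c("A[c] <=>", "A[c] -> B[c]", "A[c] -> C[c]", "C[c] -> B[c]", "B[c] ->"),
    rclass = c("exchange", rep("core", 3), "demand"))
  m <- set_bounds(m, "EX_A", lb = -1, ub = 0)
  mn <- fba_min_norm(m, "DM_B")
  v <- stats::setNames(tidy(mn)$flux, tidy(mn)$id)
  expect_equal(mn$objective_value, 1)
  expect_equal(unname(v["P2"]), 1)
  expect_equal(unname(v[c("P1a", "P1b")]), c(0, 0))
  expect_lt(sum(abs(v)), 3 + 1e-9)
  # loop-free chain: identical to the plain FBA solution
  ch <- chain_model()
  expect_equal(tidy(fba_min_norm(ch, "DM_B")), tidy(fba(ch, "DM_B")))
  # internal 2-cycle with closed exchanges: all-zero flux
  loop <- quick_model(c("L1", "L2"), c("X[c] -> Y[c]", "Y[c] -> X[c]"))
  ln <- fba_min_norm(loop, "L1", "min")
  expect_equal(tidy(ln)$flux, c(0, 0))
})

test_that("reversible loops carry bounded-only flux under closed exchanges", {
  loop <- quick_model(c("L1", "L2"),
                      c("X[c] <=> Y[c]", "Y[c] <=> X[c]"),
                      lb = c(-10, -10), ub = c(10, 10))
  rng <- fva(loop)
  expect_equal(rng$min_flux, c(-10, -10))
  expect_equal(rng$max_flux, c(10, 10))
})

test_that("robustness scans trace the energy-limited response", {
  # 1 ATP per output unit: response = min(availability, ligand supply)
  m <- quick_model(
    c("EX_L", "EX_atp", "EX_adp", "B1", "DM_O"),
    c("L[e] <=>", "atp[c] <=>", "adp[c] <=>",
      "L[e] + atp[c] -> O[n] + adp[c]", "O[n] ->"),
    rclass = c("exchange", "exchange", "exchange", "binding", "demand"))
  m <- set_bounds(m, "EX_L", lb = -40, ub = 0)
  sc <- robustness_scan(m, "EX_atp", "DM_O", n_points = 26,
                        lb_range = c(-50, 0))
  expect_equal(nrow(sc), 26)
  expect_equal(sc$control_lb, seq(-50, 0, length.out = 26))
  expect_equal(sc$response, pmin(-sc$control_lb, 40), tolerance = 1e-8)
  # default grid size follows the standard 50-point protocol
  sc50 <- robustness_scan(m, "EX_atp", "DM_O")
  expect_equal(nrow(sc50), 50)
  # energy-independent objective gives a flat curve
  m2 <- quick_model(c("EX_L", "B1", "DM_O"),
                    c("L[e] <=>", "L[e] -> O[n]", "O[n] ->"),
                    rclass = c("exchange", "binding", "demand"))
  m2 <- set_bounds(m2, "EX_L", lb = -3, ub = 0)
  ex <- quick_model("EX_atp", "atp[c] <=>", rclass = "exchange")
  m2$reactions <- dplyr::bind_rows(m2$reactions, ex$reactions)
  m2$compounds <- dplyr::bind_rows(m2$compounds, ex$compounds)
  flat <- robustness_scan(m2, "EX_atp", "DM_O", n_points = 10)
  expect_equal(diff(range(flat$response)), 0)
})

test_that("relaxing a bound never shrinks FVA intervals", {
  set.seed(31)
  for (rep in 1:6) {
    m <- random_network()
    before <- fva(m)
    j <- sample(nrow(m$reactions), 1)
    relaxed <- set_bounds(m, m$reactions$id[j],
                          lb = m$reactions$lb[j] - 5,
                          ub = m$reactions$ub[j] + 5)
    after <- fva(relaxed)
    expect_true(all(after$min_flux <= before$min_flux + 1e-7))
    expect_true(all(after$max_flux >= before$max_flux - 1e-7))
  }
})
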