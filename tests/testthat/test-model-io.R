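test_that("tabular model triple round-trips through write/read", {
  m <- mini_tlr()
  dir <- withr::local_tempdir()
  write_model(m, dir, stem = "rt")
  m2 <- read_model(file.path(dir, "rt_reactions.tsv"),
                   file.path(dir, "rt_compounds.tsv"),
                   file.path(dir, "rt_genes.tsv"))
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$ub, m$reactions$ub)
  expect_equal(m2$reactions$gpr, m$reactions$gpr)
  expect_equal(m2$reactions$rclass, m$reactions$rclass)
  expect_equal(m2$compounds, m$compounds)
  expect_equal(m2$genes, m$genes)
  for (j in seq_len(nrow(m$reactions))) {
    st <- m$reactions$stoich[[j]]
    st2 <- m2$reactions$stoich[[j]]
    expect_equal(st2[order(names(st2))], st[order(names(st))])
  }
  # bounds zeroed by tailoring survive the round-trip
  t1 <- tailor_model(m, call_map(absent = c("104", "105")),
                     compute_stats = FALSE)
  write_model(t1$tailored, dir, stem = "rt2")
  m3 <- read_model(file.path(dir, "rt2_reactions.tsv"),
                   file.path(dir, "rt2_compounds.tsv"))
  expect_equal(get_bounds(m3, c("BIND_O1", "BIND_O2"))$ub, c(0, 0))
})

test_that("the packaged miniTLR TSV triple equals the in-code builder", {
  base <- system.file("extdata/minitlr", package = "sigflux")
  m <- read_model(file.path(base, "minitlr_reactions.tsv"),
                  file.path(base, "minitlr_compounds.tsv"),
                  file.path(base, "minitlr_genes.tsv"))
  ref <- mini_tlr()
  expect_equal(m$reactions$id, ref$reactions$id)
  expect_equal(m$reactions$lb, ref$reactions$lb)
  expect_equal(m$reactions$gpr, ref$reactions$gpr)
  expect_equal(m$compounds$id, ref$compounds$id)
})

test_that("reader rejects malformed files with named diagnostics", {
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "c.tsv")
  rx <- file.path(dir, "r.tsv")
  readr::write_tsv(tibble::tibble(id = "A[c]", name = "A", compartment = "c",
                                  role = "protein"), cp)
  readr::write_tsv(tibble::tibble(id = "r1", formula = "A[c] -> ghost[c]",
                                  gpr = "", rclass = "core"), rx)
  expect_error(read_model(rx, cp), "ghost")
  readr::write_tsv(tibble::tibble(id = c("r1", "r1"),
                                  formula = c("A[c] ->", "A[c] ->"),
                                  gpr = "", rclass = "demand"), rx)
  expect_error(read_model(rx, cp), "duplicate_reaction")
  readr::write_tsv(tibble::tibble(id = "r1", gpr = "", rclass = "core"), rx)
  expect_error(read_model(rx, cp), "formula")
})

test_that("SBML export preserves counts, bounds and GPRs on re-import", {
  m <- mini_tlr()
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, path)
  m2 <- import_sbml(path)
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  expect_equal(nrow(m2$compounds), nrow(m$compounds))
  expect_setequal(genes_of(m2), genes_of(m))
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$ub, m$reactions$ub)
  # gene association logic survives (compare truth tables on a sample rule)
  j <- match("KIN1", m$reactions$id)
  j2 <- match(grep("KIN1", m2$reactions$id, value = TRUE), m2$reactions$id)
  for (mask in 0:7) {
    vals <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    calls <- stats::setNames(ifelse(vals, "present", "absent"),
                             c("301", "302", "303"))
    expect_equal(evaluate_gpr(m2$reactions$gpr_ast[[j2]], calls),
                 evaluate_gpr(m$reactions$gpr_ast[[j]], calls))
  }
  # stoichiometry preserved up to the id sanitisation
  s1 <- sort(abs(unlist(m$reactions$stoich)))
  s2 <- sort(abs(unlist(m2$reactions$stoich)))
  expect_equal(unname(s2), unname(s1))
})

test_that("expression and DE table readers validate their input", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "expr.tsv")
  ok <- tibble::tibble(probe_id = c("p1", "p2"), gene_id = "g1",
                       sample_id = "s1", group = "control",
                       detection_p = c(0.01, 0.2), intensity = c(100, 50))
  readr::write_tsv(ok, f)
  expect_equal(nrow(read_expression(f)), 2)
  readr::write_tsv(ok[c(1, 1), ], f)
  expect_error(read_expression(f), "duplicate")
  bad <- ok; bad$detection_p[1] <- 1.5
  readr::write_tsv(bad, f)
  expect_error(read_expression(f), "\\[0, 1\\]")
  readr::write_tsv(ok[, -6], f)
  expect_error(read_expression(f), "intensity")

  d <- file.path(dir, "de.tsv")
  de <- tibble::tibble(gene_id = "g1", probe_id = c("p1", "p2"),
                       log2_fc = c(1.5, 2), fdr_p = c(0.01, 0.2))
  readr::write_tsv(de, d)
  expect_equal(nrow(read_diffexpr(d)), 2)
  readr::write_tsv(de[c(1, 1), ], d)
  expect_error(read_diffexpr(d), "duplicate")
})
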