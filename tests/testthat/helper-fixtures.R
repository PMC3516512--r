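# Small fixture builders shared across test files.

# model from formula strings; compounds inferred from the formulas
quick_model <- function(ids, formulas, lb = NULL, ub = NULL, gpr = NULL,
                        rclass = NULL, roles = NULL, id = "fixture") {
  rx <- tibble::tibble(id = ids, formula = formulas)
  if (!is.null(lb)) rx$lb <- lb
  if (!is.null(ub)) rx$ub <- ub
  rx$gpr <- gpr %||% ""
  rx$rclass <- rclass %||% "core"
  cps <- unique(unlist(lapply(formulas, function(f) {
    names(parse_reaction_formula(f)$stoich)
  })))
  cp <- tibble::tibble(id = cps, role = "protein")
  if (!is.null(roles)) cp$role[match(names(roles), cp$id)] <- unname(roles)
  new_model(cp, rx, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear chain: EX_A (uptake 1) -> R1 -> DM_B
chain_model <- function(uptake = 1) {
  m <- quick_model(
    c("EX_A", "R1", "DM_B"),
    c("A[c] <=>", "A[c] -> B[c]", "B[c] ->"),
    rclass = c("exchange", "core", "demand"))
  set_bounds(m, "EX_A", lb = -uptake, ub = 0)
}

call_map <- function(absent, present = character()) {
  tibble::tibble(gene_id = c(absent, present),
                 call = rep(c("absent", "present"),
                            c(length(absent), length(present))))
}

expectations_table <- function() {
  readr::read_tsv(system.file("extdata/minitlr/expectations.tsv",
                              package = "sigflux"),
                  show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}
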