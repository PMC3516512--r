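# Independent oracles used to cross-check the implementation.
# They deliberately share no code with the package: GPR rules are rewritten
# into R logical expressions and evaluated by R's own parser; LP questions
# are answered by exhaustive vertex enumeration over the bounded flux
# polytope (every vertex fixes at least n - rank(S) variables at bounds).

oracle_eval_gpr <- function(text, assignment) {
  if (is.null(text) || grepl("^\\s*$", text)) return(TRUE)
  expr <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  for (g in names(assignment)) {
    expr <- gsub(paste0("(?<![\\w.])", g, "(?![\\w.])"),
                 if (assignment[[g]]) "TRUE" else "FALSE", expr, perl = TRUE)
  }
  eval(parse(text = expr))
}

oracle_vertices <- function(S, lb, ub, tol = 1e-6) {
  n <- ncol(S)
  rnk <- if (nrow(S) > 0) qr(S)$rank else 0L
  verts <- list()
  for (k in 0:min(rnk, n)) {
    fsets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
    for (fr in fsets) {
      if (k > 0 && qr(S[, fr, drop = FALSE])$rank < k) next
      act <- setdiff(seq_len(n), fr)
      na <- length(act)
      for (mask in 0:(2^na - 1)) {
        at_ub <- bitwAnd(mask, 2^(seq_len(na) - 1L)) > 0
        v <- numeric(n)
        v[act] <- ifelse(at_ub, ub[act], lb[act])
        if (k > 0) {
          rhs <- if (na > 0) -as.vector(S[, act, drop = FALSE] %*% v[act]) else numeric(nrow(S))
          vf <- tryCatch(qr.solve(S[, fr, drop = FALSE], rhs),
                         error = function(e) NULL)
          if (is.null(vf)) next
          v[fr] <- vf
        }
        if (max(abs(S %*% v)) > tol) next
        if (any(v < lb - tol) || any(v > ub + tol)) next
        verts[[length(verts) + 1]] <- pmin(pmax(v, lb), ub)
      }
    }
  }
  verts
}

oracle_fva <- function(model, tol = 1e-6) {
  S <- stoich_matrix(model)
  verts <- oracle_vertices(S, model$reactions$lb, model$reactions$ub, tol)
  if (length(verts) == 0) stop("oracle: infeasible model")
  vm <- do.call(rbind, verts)
  tibble::tibble(id = model$reactions$id,
                 min_flux = apply(vm, 2, min),
                 max_flux = apply(vm, 2, max))
}

# random GPR trees (as rule text) with bounded leaf count
random_gpr_text <- function(genes, max_leaves = 10) {
  leaves_left <- sample(seq_len(max_leaves), 1)
  build <- function(budget, depth) {
    if (budget <= 1 || depth > 3 || stats::runif(1) < 0.35) {
      return(list(text = sample(genes, 1), used = 1L))
    }
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    used <- 0L
    parts <- character()
    for (i in seq_len(k)) {
      child <- build(max(1, (budget - used) %/% (k - i + 1L)), depth + 1L)
      used <- used + child$used
      parts <- c(parts, if (grepl(" ", child$text)) paste0("(", child$text, ")") else child$text)
    }
    list(text = paste(parts, collapse = paste0(" ", op, " ")), used = used)
  }
  build(leaves_left, 1L)$text
}

# random small flux networks for LP cross-checks
random_network <- function(n_rxns = sample(3:6, 1), n_cps = sample(2:4, 1)) {
  repeat {
    stoich <- lapply(seq_len(n_rxns), function(j) {
      k <- sample(1:min(2, n_cps), 1)
      cps <- sample(sprintf("m%d[c]", seq_len(n_cps)), k)
      stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE), cps)
    })
    if (length(unique(unlist(lapply(stoich, names)))) > 0) break
  }
  rev <- stats::runif(n_rxns) < 0.5
  rx <- tibble::tibble(
    id = sprintf("r%d", seq_len(n_rxns)),
    stoich = stoich,
    lb = ifelse(rev, -10, 0),
    ub = 10,
    gpr = "", rclass = "core")
  cp <- tibble::tibble(id = sprintf("m%d[c]", seq_len(n_cps)))
  new_model(cp, rx, id = "random")
}
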