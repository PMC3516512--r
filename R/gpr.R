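#' Gene-reaction association (GPR) rules
#'
#' A GPR rule links a reaction to the genes whose products make it
#' available: `AND` joins obligate partners (protein complexes, multi-protein
#' steps), `OR` joins functional isoforms. Rules are stored as small parse
#' trees: a gene leaf, an operator node with two or more children, or the
#' empty rule (no gene association, always active).
#'
#' The rule grammar is case-insensitive `and` / `or` with parentheses.
#' A single run of one operator may be written flat
#' (`"815 or 816 or 817"`); mixing `and` with `or` at the same nesting
#' level requires parentheses, so that precedence is always explicit.
#'
#' @param text Rule string, e.g. `"(815 or 816) and 1147"`. Empty or
#'   whitespace-only text yields the empty rule (`NULL`).
#' @return `parse_gpr()` returns a GPR tree: `NULL` for the empty rule, or a
#'   list with `$op` (`"and"`/`"or"`) and `$children`, or `$gene` for a leaf.
#' @examples
#' parse_gpr("(815 or 816 or 817 or 818) and 1147")
#' evaluate_gpr(parse_gpr("815 or 816"), c(`815` = "absent", `816` = "present"))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  stopifnot(is.character(text), length(text) == 1)
  toks <- gpr_tokenize(text)
  if (nrow(toks) == 0) return(NULL)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_expr(st, text)
  if (st$pos <= nrow(st$toks)) {
    stop("GPR parse error at position ", st$toks$at[st$pos],
         ": unexpected '", st$toks$tok[st$pos], "' in rule \"", text, "\"",
         call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(), at = integer()))
  data.frame(tok = regmatches(text, gregexpr(pat, text))[[1]],
             at = as.integer(m), stringsAsFactors = FALSE)
}

gpr_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$tok[st$pos] else NA_character_

gpr_parse_expr <- function(st, text) {
  terms <- list(gpr_parse_primary(st, text))
  op <- NULL
  repeat {
    nxt <- gpr_peek(st)
    if (is.na(nxt) || nxt == ")") break
    low <- tolower(nxt)
    if (!low %in% c("and", "or")) {
      stop("GPR parse error at position ", st$toks$at[st$pos],
           ": expected 'and'/'or', got '", nxt, "' in rule \"", text, "\"",
           call. = FALSE)
    }
    if (is.null(op)) {
      op <- low
    } else if (op != low) {
      stop("GPR parse error at position ", st$toks$at[st$pos],
           ": cannot mix 'and' and 'or' without parentheses in rule \"",
           text, "\"", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    terms <- c(terms, list(gpr_parse_primary(st, text)))
  }
  if (is.null(op)) terms[[1]] else list(op = op, children = terms)
}

gpr_parse_primary <- function(st, text) {
  tok <- gpr_peek(st)
  if (is.na(tok)) {
    stop("GPR parse error: dangling operator at end of rule \"", text, "\"",
         call. = FALSE)
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_expr(st, text)
    if (!identical(gpr_peek(st), ")")) {
      stop("GPR parse error: unbalanced parentheses in rule \"", text, "\"",
           call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")") {
    stop("GPR parse error at position ", st$toks$at[st$pos],
         ": unbalanced ')' in rule \"", text, "\"", call. = FALSE)
  }
  if (tolower(tok) %in% c("and", "or")) {
    stop("GPR parse error at position ", st$toks$at[st$pos],
         ": dangling operator '", tok, "' in rule \"", text, "\"",
         call. = FALSE)
  }
  st$pos <- st$pos + 1L
  list(gene = tok)
}

#' @rdname parse_gpr
#' @param gpr A GPR tree as returned by [parse_gpr()].
#' @return `render_gpr()` returns the rule as a string (`""` for the empty
#'   rule); `parse_gpr(render_gpr(x))` is logically equivalent to `x`.
#' @export
render_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (!is.null(gpr$gene)) return(gpr$gene)
  parts <- vapply(gpr$children, function(ch) {
    s <- render_gpr(ch)
    if (is.null(ch$gene)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' @rdname parse_gpr
#' @param calls Presence/absence calls: a tibble with columns `gene_id` and
#'   `call` (`"present"`/`"absent"`), or a named character vector of calls,
#'   or a named logical vector (`TRUE` = present).
#' @param default_call Call assumed for genes not covered by `calls`.
#'   Defaults to `"present"`: reactions are only disabled on evidence of
#'   absence, so genes that the expression platform does not cover never
#'   silently delete reactions.
#' @return `evaluate_gpr()` returns `TRUE` if the rule is satisfied (the
#'   reaction is available). The empty rule is always satisfied; an `OR`
#'   rule fails only when every isoform is absent.
#' @export
evaluate_gpr <- function(gpr, calls, default_call = "present") {
  present <- calls_as_logical(calls)
  default <- identical(default_call, "present")
  gpr_eval_rec(gpr, present, default)
}

gpr_eval_rec <- function(gpr, present, default) {
  if (is.null(gpr)) return(TRUE)
  if (!is.null(gpr$gene)) {
    v <- present[[gpr$gene]]
    return(if (is.null(v) || is.na(v)) default else v)
  }
  vals <- vapply(gpr$children, gpr_eval_rec, logical(1),
                 present = present, default = default)
  if (gpr$op == "and") all(vals) else any(vals)
}

calls_as_logical <- function(calls) {
  if (is.null(calls)) return(list())
  if (is.data.frame(calls)) {
    stopifnot(all(c("gene_id", "call") %in% names(calls)))
    out <- as.list(calls$call == "present")
    names(out) <- calls$gene_id
    return(out)
  }
  if (is.logical(calls)) return(as.list(calls))
  if (is.character(calls)) {
    bad <- setdiff(unique(calls), c("present", "absent"))
    if (length(bad) > 0) {
      stop("calls must be 'present' or 'absent'; got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    return(as.list(calls == "present"))
  }
  stop("unsupported calls representation", call. = FALSE)
}

#' Genes referenced by a GPR tree
#'
#' @param gpr A GPR tree.
#' @return Character vector of distinct gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (!is.null(gpr$gene)) return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes), use.names = FALSE))
}
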