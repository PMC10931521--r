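#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `and`
#' joins subunits of a complex and `or` joins isozymes, with the usual
#' convention that `and` binds tighter than `or` and parentheses override
#' precedence. Operators are matched case-insensitively; any other
#' whitespace-delimited token (excluding parentheses) is a gene identifier.
#'
#' @param text GPR rule as a single string. An empty or all-whitespace
#'   string denotes the absence of a GPR and returns `NULL`.
#' @return A `GPRExpression` (nested list with nodes of kind `"gene"`,
#'   `"and"` or `"or"`; internal nodes have two or more children), or `NULL`
#'   for an empty rule.
#' @examples
#' parseGPR("(g1 and g2) or g3")
#' @export
parseGPR <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gprTokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gprParseOr(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error at token ", st$pos, " ('",
         st$toks[[st$pos]]$value, "'): unexpected trailing input in '",
         text, "'")
  }
  expr
}

gprTokenize <- function(text) {
  # insert spaces around parentheses, then split on whitespace
  padded <- gsub("([()])", " \\1 ", text)
  raw <- strsplit(trimws(padded), "\\s+")[[1]]
  lapply(seq_along(raw), function(i) {
    v <- raw[i]
    kind <- if (v == "(") "lparen"
    else if (v == ")") "rparen"
    else if (tolower(v) == "and") "and"
    else if (tolower(v) == "or") "or"
    else "gene"
    list(kind = kind, value = v, index = i)
  })
}

gprPeek <- function(st) {
  if (st$pos > length(st$toks)) NULL else st$toks[[st$pos]]
}

gprParseOr <- function(st) {
  children <- list(gprParseAnd(st))
  while (!is.null(tk <- gprPeek(st)) && tk$kind == "or") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gprParseAnd(st)))
  }
  if (length(children) == 1L) children[[1]] else gprNode("or", children)
}

gprParseAnd <- function(st) {
  children <- list(gprParsePrimary(st))
  while (!is.null(tk <- gprPeek(st)) && tk$kind == "and") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gprParsePrimary(st)))
  }
  if (length(children) == 1L) children[[1]] else gprNode("and", children)
}

gprParsePrimary <- function(st) {
  tk <- gprPeek(st)
  if (is.null(tk)) {
    stop("GPR parse error at end of input: expected a gene or '('",
         " (dangling operator)")
  }
  if (tk$kind == "gene") {
    st$pos <- st$pos + 1L
    return(gprLeaf(tk$value))
  }
  if (tk$kind == "lparen") {
    st$pos <- st$pos + 1L
    inner <- gprParseOr(st)
    closing <- gprPeek(st)
    if (is.null(closing) || closing$kind != "rparen") {
      stop("GPR parse error at token ", tk$index, ": unbalanced '('")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  stop("GPR parse error at token ", tk$index, " ('", tk$value,
       "'): expected a gene or '('")
}

gprLeaf <- function(gene) {
  structure(list(kind = "gene", gene = gene), class = "GPRExpression")
}

gprNode <- function(kind, children) {
  # flatten same-kind children so associativity is normalized
  flat <- list()
  for (ch in children) {
    if (!is.null(ch$kind) && ch$kind == kind) {
      flat <- c(flat, ch$children)
    } else {
      flat <- c(flat, list(ch))
    }
  }
  structure(list(kind = kind, children = flat), class = "GPRExpression")
}

#' Render a GPR expression back to rule text
#'
#' `parseGPR(renderGPR(x))` reproduces `x` up to whitespace and
#' associativity normalization.
#'
#' @param expr A `GPRExpression` or `NULL`.
#' @return A single string; `""` for `NULL`.
#' @export
renderGPR <- function(expr) {
  if (is.null(expr)) return("")
  switch(expr$kind,
    gene = expr$gene,
    and = paste(vapply(expr$children, function(ch) {
      s <- renderGPR(ch)
      if (!is.null(ch$kind) && ch$kind == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    or = paste(vapply(expr$children, renderGPR, character(1)),
               collapse = " or "),
    stop("unknown GPR node kind: ", expr$kind)
  )
}

#' @export
print.GPRExpression <- function(x, ...) {
  cat("<GPR> ", renderGPR(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR expression
#'
#' @param expr A `GPRExpression` or `NULL`.
#' @return Character vector of unique gene identifiers (empty for `NULL`).
#' @export
gprGenes <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (expr$kind == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gprGenes)))
}

## ---- weight propagation -------------------------------------------------

# Signed-weight propagation through a GPR tree, vectorized over columns of
# a gene x k weight matrix. AND picks the child of minimum |value| (weakest
# subunit), OR the child of maximum |value| (strongest isozyme signal);
# ties of equal magnitude resolve toward the positive value, then to the
# leftmost child. Values keep their sign throughout.
evalGPRWeightMatrix <- function(expr, W, missing_action = c("zero", "error")) {
  missing_action <- match.arg(missing_action)
  k <- ncol(W)
  rec <- function(node) {
    if (node$kind == "gene") {
      if (node$gene %in% rownames(W)) return(W[node$gene, ])
      if (missing_action == "error") stop("gene not in weight table: ",
                                          node$gene)
      return(rep(0, k))
    }
    vals <- lapply(node$children, rec)
    acc <- vals[[1]]
    pick_new <- if (node$kind == "and") {
      function(cur, new) abs(new) < abs(cur) |
        (abs(new) == abs(cur) & new > 0 & cur < 0)
    } else {
      function(cur, new) abs(new) > abs(cur) |
        (abs(new) == abs(cur) & new > 0 & cur < 0)
    }
    for (i in seq_along(vals)[-1]) {
      repl <- pick_new(acc, vals[[i]])
      acc[repl] <- vals[[i]][repl]
    }
    acc
  }
  rec(expr)
}

#' Propagate signed gene weights to a reaction value
#'
#' Combines per-gene signed weights (log2 fold changes of significant genes,
#' zero otherwise) through the reaction's GPR rule: an `and` node takes the
#' child value of minimum absolute magnitude (a complex is only as perturbed
#' as its least-perturbed subunit), an `or` node the child value of maximum
#' absolute magnitude (any isozyme's change can change the reaction). Ties
#' in magnitude resolve toward the positive value, then to the leftmost
#' child, so the result is deterministic. Genes absent from `weights` get
#' weight 0; the number of such genes is attached as attribute
#' `n_missing_genes`.
#'
#' @param expr A `GPRExpression` (see [parseGPR()]); `NULL` returns `NA`.
#' @param weights Named numeric vector of per-gene signed weights, or a
#'   [GeneWeightTable-class] object.
#' @return Signed scalar reaction weight (with attribute `n_missing_genes`),
#'   or `NA_real_` when `expr` is `NULL`.
#' @seealso [reactionAbundance()] for the nonnegative transcript-abundance
#'   analogue.
#' @export
reactionWeight <- function(expr, weights) {
  if (is(weights, "GeneWeightTable")) weights <- geneWeights(weights)
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (is.null(expr)) return(NA_real_)
  W <- matrix(weights, ncol = 1, dimnames = list(names(weights), NULL))
  missing_n <- sum(!(gprGenes(expr) %in% names(weights)))
  structure(evalGPRWeightMatrix(expr, W)[1], n_missing_genes = missing_n)
}

#' Propagate transcript abundances to a reaction value
#'
#' An `and` node takes the minimum of its children (the complex is limited
#' by its scarcest subunit) and an `or` node the sum (isozymes contribute
#' additively). Genes absent from `tpm` contribute 0. A reaction without a
#' GPR is unassessed and returns `NA_real_`.
#'
#' @param expr A `GPRExpression` or `NULL`.
#' @param tpm Named numeric vector of nonnegative transcript abundances
#'   (e.g. median TPM per gene within a condition).
#' @return Nonnegative scalar, or `NA_real_` for an absent GPR.
#' @export
reactionAbundance <- function(expr, tpm) {
  stopifnot(is.numeric(tpm))
  if (any(tpm < 0, na.rm = TRUE)) stop("transcript abundances must be >= 0")
  if (is.null(expr)) return(NA_real_)
  rec <- function(node) {
    if (node$kind == "gene") {
      v <- unname(tpm[node$gene])
      if (is.na(v)) 0 else v
    } else {
      vals <- vapply(node$children, rec, numeric(1))
      if (node$kind == "and") min(vals) else sum(vals)
    }
  }
  rec(expr)
}
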