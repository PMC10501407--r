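# Expression trees are nested plain lists:
#   list(type = "op",       symbol = "+", children = list(<node>, <node>))
#   list(type = "terminal", symbol = "MECN")
#   list(type = "const",    value  = 1)
# Arithmetic is vectorized; a division (or inv) whose denominator has
# absolute value below 1e-12, or a log of a non-positive value, yields
# UNDEFINED (NA), which propagates to the root.

.UNDEF_EPS <- 1e-12

opNode <- function(symbol, ...) list(type = "op", symbol = symbol,
                                     children = list(...))
terminalNode <- function(symbol) list(type = "terminal", symbol = symbol)
constNode <- function(value) list(type = "const", value = value)

#' GEP function set constructors
#'
#' \code{defaultFunctionSet} builds the six-operator set used by the
#' nonlinear branch: addition, subtraction, multiplication, division, inverse
#' and sine, all with selection weight 1. The "inverse" operator is 1/x; a
#' natural-logarithm reading is available with \code{inverse = "ln"}.
#'
#' @param inverse "inv" (1/x, default) or "ln" (natural log).
#' @return a \linkS4class{FunctionSet}.
#' @export
defaultFunctionSet <- function(inverse = c("inv", "ln")) {
  inverse <- match.arg(inverse)
  functionSet(symbols = c("+", "-", "*", "/", inverse, "sin"),
              arity = c(2L, 2L, 2L, 2L, 1L, 1L))
}

#' @rdname defaultFunctionSet
#' @param symbols operator symbols.
#' @param arity integer arities (>= 1).
#' @param weight positive selection weights, default all 1.
#' @export
functionSet <- function(symbols, arity, weight = rep(1, length(symbols))) {
  new("FunctionSet", symbols = as.character(symbols),
      arity = as.integer(arity), weight = as.numeric(weight))
}

.applyOp <- function(symbol, args) {
  switch(symbol,
    "+" = args[[1L]] + args[[2L]],
    "-" = if (length(args) == 1L) -args[[1L]] else args[[1L]] - args[[2L]],
    "*" = args[[1L]] * args[[2L]],
    "/" = { den <- args[[2L]]
            out <- args[[1L]] / den
            out[abs(den) < .UNDEF_EPS] <- NA_real_
            out },
    "inv" = { x <- args[[1L]]
              out <- 1 / x
              out[abs(x) < .UNDEF_EPS] <- NA_real_
              out },
    "sin" = sin(args[[1L]]),
    "ln" = { x <- args[[1L]]
             out <- suppressWarnings(log(x))
             out[x <= 0] <- NA_real_
             out },
    stopf("unknown operator: %s", symbol))
}

#' Evaluate an expression tree
#'
#' Evaluates the tree under a set of terminal bindings. Bindings may be
#' scalars or equal-length vectors (evaluation is vectorized). Division or
#' inversion by a near-zero value (|x| < 1e-12) yields UNDEFINED, represented
#' as \code{NA} and propagated to the root.
#'
#' @param tree an \linkS4class{ExpressionTree} (or a raw node list).
#' @param bindings named list or named numeric vector covering all terminals;
#'   alternatively a matrix/data.frame whose columns are terminals.
#' @return numeric vector of values, \code{NA} where undefined.
#' @export
evaluateTree <- function(tree, bindings) {
  node <- if (is(tree, "ExpressionTree")) tree@root else tree
  if (is.matrix(bindings)) bindings <- as.data.frame(bindings)
  if (is.numeric(bindings) && !is.null(names(bindings)))
    bindings <- as.list(bindings)
  evalNode <- function(nd) {
    switch(nd$type,
      const = nd$value,
      terminal = {
        if (is.null(bindings[[nd$symbol]]))
          stopf("unbound terminal: %s", nd$symbol)
        bindings[[nd$symbol]]
      },
      op = .applyOp(nd$symbol, lapply(nd$children, evalNode)),
      stopf("malformed tree node"))
  }
  evalNode(node)
}

#' Terminal names used by a tree
#' @param tree ExpressionTree or node list.
#' @return character vector of distinct terminal symbols.
#' @export
treeTerminals <- function(tree) {
  node <- if (is(tree, "ExpressionTree")) tree@root else tree
  walk <- function(nd)
    switch(nd$type,
      terminal = nd$symbol,
      op = unlist(lapply(nd$children, walk)),
      character())
  unique(walk(node))
}

#' Print an expression tree as parenthesized infix text
#'
#' Binary operations are fully parenthesized and unary functions appear as
#' calls (\code{sin(x)}, \code{inv(x)}), so \code{parseExpression} of the
#' output reconstructs the identical tree.
#'
#' @param tree ExpressionTree or node list.
#' @return character(1) infix expression.
#' @export
deparseTree <- function(tree) {
  node <- if (is(tree, "ExpressionTree")) tree@root else tree
  dp <- function(nd) {
    switch(nd$type,
      const = formatC(nd$value, format = "g", digits = 17),
      terminal = nd$symbol,
      op = {
        args <- vapply(nd$children, dp, "")
        if (nd$symbol %in% c("+", "-", "*", "/") && length(args) == 2L)
          paste0("(", args[1L], " ", nd$symbol, " ", args[2L], ")")
        else paste0(nd$symbol, "(", paste(args, collapse = ", "), ")")
      })
  }
  dp(node)
}

# ---- recursive-descent infix parser -----------------------------------------

.tokenize <- function(text) {
  pats <- c(name = "[A-Za-z_][A-Za-z0-9_.]*",
            number = "[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?",
            op = "[-+*/(),]")
  tokens <- list(); pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(ws)) { pos <- pos + nchar(ws); next }
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(paste0("^(", pats[[ty]], ")"), rest))
      if (length(m)) {
        tokens[[length(tokens) + 1L]] <- list(type = ty, value = m, pos = pos)
        pos <- pos + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stopf("parse error at position %d: unexpected character '%s'",
            pos, substr(text, pos, pos))
  }
  tokens
}

#' Parse an infix expression into an ExpressionTree
#'
#' Conventional precedence: unary function calls bind tightest, then
#' \code{*} and \code{/} (left-associative), then \code{+} and \code{-}
#' (left-associative); parentheses group. A leading minus is accepted on
#' numbers and parenthesized groups (encoded as subtraction from zero).
#' Known unary functions are \code{sin}, \code{inv} and \code{ln}; any other
#' identifier is a terminal.
#'
#' @param text character(1) infix expression.
#' @return an \linkS4class{ExpressionTree}.
#' @examples
#' deparseTree(parseExpression("a + sin(b)*c"))
#' @export
parseExpression <- function(text) {
  tokens <- .tokenize(text)
  i <- 1L
  peek <- function() if (i <= length(tokens)) tokens[[i]] else NULL
  advance <- function() { tk <- tokens[[i]]; i <<- i + 1L; tk }
  expect <- function(val) {
    tk <- peek()
    if (is.null(tk) || tk$value != val)
      stopf("parse error at position %s: expected '%s'",
            if (is.null(tk)) "end" else tk$pos, val)
    advance()
  }
  parsePrimary <- function() {
    tk <- peek()
    if (is.null(tk)) stopf("parse error: unexpected end of input")
    if (tk$value == "(") {
      advance(); nd <- parseExpr(); expect(")"); return(nd)
    }
    if (tk$value == "-") {           # unary minus
      advance()
      nd <- parsePrimary()
      if (nd$type == "const") return(constNode(-nd$value))
      return(opNode("-", constNode(0), nd))
    }
    if (tk$type == "number") { advance(); return(constNode(as.numeric(tk$value))) }
    if (tk$type == "name") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$value == "(") {
        advance()
        args <- list(parseExpr())
        while (!is.null(peek()) && peek()$value == ",") { advance()
          args[[length(args) + 1L]] <- parseExpr() }
        expect(")")
        return(do.call(opNode, c(list(tk$value), args)))
      }
      return(terminalNode(tk$value))
    }
    stopf("parse error at position %d: unexpected token '%s'", tk$pos, tk$value)
  }
  parseTerm <- function() {
    nd <- parsePrimary()
    while (!is.null(peek()) && peek()$value %in% c("*", "/")) {
      op <- advance()$value
      nd <- opNode(op, nd, parsePrimary())
    }
    nd
  }
  parseExpr <- function() {
    nd <- parseTerm()
    while (!is.null(peek()) && peek()$value %in% c("+", "-")) {
      op <- advance()$value
      nd <- opNode(op, nd, parseTerm())
    }
    nd
  }
  root <- parseExpr()
  if (i <= length(tokens))
    stopf("parse error at position %d: trailing input '%s'",
          tokens[[i]]$pos, tokens[[i]]$value)
  new("ExpressionTree", root = root)
}

#' The published nonlinear (GEP) activity model
#'
#' Parses the packaged transcription of the published symbolic-regression
#' equation over the six descriptors TEIZP, NFA, MECN, MRCH, MCIHN and ZXS.
#' Note two structural quirks printed in the source equation and preserved
#' here: a self-cancelling (MECN - MECN) subexpression, and a leading
#' 1/(TEIZP - NFA) term that is UNDEFINED whenever TEIZP equals NFA.
#'
#' @return an \linkS4class{ExpressionTree}.
#' @export
publishedGepModel <- function() {
  path <- system.file("extdata", "gep_published_equation.txt",
                      package = "gbmQSAR", mustWork = TRUE)
  parseExpression(paste(readLines(path, warn = FALSE), collapse = " "))
}
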