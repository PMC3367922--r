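## Macro expansion for grammar S-expressions.
##
## The macro vocabulary is fixed: iteration (&foreach, &foreach-token,
## &foreach-integer, &foreach-node, &foreach-leaf, &foreach-branch),
## conditionals (&if with &eq / &neq string tests and &numeq / &gt / &lt /
## &geq / &leq numeric tests), string building (&cat), exact arithmetic
## (&+ &- &* &/), bindings (&define) and file inclusion (&include).
## List-valued atoms &TOKENS, &NODES, &LEAVES, &BRANCHES and &COLUMNS splice
## their elements into the enclosing list.
##
## Arithmetic is exact-rational whenever every operand is an integer or
## rational, so probabilities like 1/3 survive expansion without decimal
## drift; mixed operands fall back to double precision.  Division whose
## numerator is still a symbolic parameter name expands to the product form
## (name 1/k), matching the multi-factor syntax of (rate ...) and (prob ...)
## expressions.

## ---- exact number handling -------------------------------------------------

numGcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

## Parse an atom as a number: list(kind="rat", num, den) for exact values,
## list(kind="dbl", x) for decimals, NULL if symbolic.
parseExactNumber <- function(atom) {
  if (!isAtom(atom)) return(NULL)
  if (grepl("^[+-]?[0-9]+$", atom))
    return(list(kind = "rat", num = as.numeric(atom), den = 1))
  if (grepl("^[+-]?[0-9]+/[0-9]+$", atom)) {
    parts <- strsplit(sub("^\\+", "", atom), "/", fixed = TRUE)[[1]]
    return(ratCanon(as.numeric(parts[1]), as.numeric(parts[2])))
  }
  x <- suppressWarnings(as.numeric(atom))
  if (!is.na(x)) return(list(kind = "dbl", x = x))
  NULL
}

ratCanon <- function(num, den) {
  if (den == 0) stop("division by zero in macro arithmetic", call. = FALSE)
  if (den < 0) { num <- -num; den <- -den }
  g <- numGcd(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  list(kind = "rat", num = num, den = den)
}

numAsDouble <- function(v) if (v$kind == "rat") v$num / v$den else v$x

formatMacroNumber <- function(v) {
  if (v$kind == "rat") {
    if (v$den == 1) return(format(v$num, scientific = FALSE))
    return(paste0(format(v$num, scientific = FALSE), "/",
                  format(v$den, scientific = FALSE)))
  }
  formatNum(v$x)
}

formatNum <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  s
}

## Evaluate an atom as a numeric value (supports "p/q"), NA if symbolic.
#' Numeric value of a grammar atom
#'
#' Atoms produced by macro arithmetic may be integers, decimals or exact
#' rationals of the form \code{"p/q"}; this resolves them to doubles.
#'
#' @param atom a character scalar.
#' @return a double, or \code{NA} if the atom is not numeric.
#' @export
atomNumber <- function(atom) {
  v <- parseExactNumber(atom)
  if (is.null(v)) return(NA_real_)
  numAsDouble(v)
}

macroArith <- function(op, args) {
  vals <- lapply(args, function(a) if (isAtom(a)) parseExactNumber(a) else NULL)
  sym <- vapply(vals, is.null, logical(1))
  if (!any(sym)) {
    allRat <- all(vapply(vals, function(v) v$kind == "rat", logical(1)))
    if (allRat) {
      acc <- vals[[1L]]
      if (op == "-" && length(vals) == 1L) acc <- ratCanon(-acc$num, acc$den)
      for (v in vals[-1L]) {
        acc <- switch(op,
          "+" = ratCanon(acc$num * v$den + v$num * acc$den, acc$den * v$den),
          "-" = ratCanon(acc$num * v$den - v$num * acc$den, acc$den * v$den),
          "*" = ratCanon(acc$num * v$num, acc$den * v$den),
          "/" = {
            if (v$num == 0) stop("division by zero in macro arithmetic",
                                 call. = FALSE)
            ratCanon(acc$num * v$den, acc$den * v$num)
          })
      }
      return(formatMacroNumber(acc))
    }
    xs <- vapply(vals, numAsDouble, numeric(1))
    acc <- xs[1L]
    if (op == "-" && length(xs) == 1L) acc <- -acc
    for (x in xs[-1L]) {
      if (op == "/" && x == 0)
        stop("division by zero in macro arithmetic", call. = FALSE)
      acc <- switch(op, "+" = acc + x, "-" = acc - x,
                    "*" = acc * x, "/" = acc / x)
    }
    return(formatNum(acc))
  }
  ## Symbolic operands: only product forms are representable.
  if (op == "/" && length(args) == 2L && sym[1L] && !sym[2L]) {
    inv <- ratCanon(if (vals[[2L]]$kind == "rat") vals[[2L]]$den else 1,
                    if (vals[[2L]]$kind == "rat") vals[[2L]]$num
                    else stop("cannot divide by a non-exact value symbolically",
                              call. = FALSE))
    if (numAsDouble(vals[[2L]]) == 0)
      stop("division by zero in macro arithmetic", call. = FALSE)
    return(list(args[[1L]], formatMacroNumber(inv)))
  }
  if (op == "*") {
    acc <- list(kind = "rat", num = 1, den = 1)
    syms <- list()
    for (k in seq_along(args)) {
      if (sym[k]) syms[[length(syms) + 1L]] <- args[[k]]
      else {
        v <- vals[[k]]
        if (acc$kind == "rat" && v$kind == "rat")
          acc <- ratCanon(acc$num * v$num, acc$den * v$den)
        else acc <- list(kind = "dbl", x = numAsDouble(acc) * numAsDouble(v))
      }
    }
    num <- formatMacroNumber(acc)
    if (num == "1") {
      if (length(syms) == 1L) return(syms[[1L]])
      return(syms)
    }
    return(c(syms, list(num)))
  }
  stop("macro arithmetic on a non-numeric atom: ",
       writeSExpr(as.list(c(paste0("&", op), args))), call. = FALSE)
}

## ---- expansion environment -------------------------------------------------

#' Macro expansion context
#'
#' Bundles the data a grammar's macros may refer to: the ordered alphabet
#' tokens, the tree's node/leaf/branch labels, the alignment column count,
#' \code{&define} bindings and \code{&include} search paths.
#'
#' @param tokens ordered alphabet tokens (for \code{&foreach-token}).
#' @param tree a \code{PhyloTree} (or \code{NULL}) supplying node iterators.
#' @param ncol alignment column count (or \code{NULL}).
#' @param defines named list of pre-bound S-expressions.
#' @param includeDirs directories searched by \code{&include}.
#' @return an environment of class \code{"MacroEnv"}.
#' @export
macroEnv <- function(tokens = character(0), tree = NULL, ncol = NULL,
                     defines = list(), includeDirs = character(0)) {
  env <- new.env(parent = emptyenv())
  env$tokens <- as.character(tokens)
  if (!is.null(tree)) {
    env$nodes <- treeNodeLabels(tree)
    env$leaves <- treeLeafLabels(tree)
    env$branches <- treeBranchLabels(tree)
  } else {
    env$nodes <- NULL; env$leaves <- NULL; env$branches <- NULL
  }
  env$ncol <- ncol
  env$defines <- new.env(parent = emptyenv())
  for (nm in names(defines)) assign(nm, defines[[nm]], envir = env$defines)
  env$includeDirs <- includeDirs
  env$file <- NULL
  class(env) <- "MacroEnv"
  env
}

substAtom <- function(expr, name, repl) {
  if (isAtom(expr)) {
    if (expr == name) return(repl)
    return(expr)
  }
  lapply(expr, substAtom, name = name, repl = repl)
}

isEmptyList <- function(x) is.list(x) && length(x) == 0L

macroNames <- c("&foreach", "&foreach-token", "&foreach-integer",
                "&foreach-node", "&foreach-leaf", "&foreach-branch",
                "&if", "&eq", "&neq", "&numeq", "&gt", "&lt", "&geq", "&leq",
                "&cat", "&define", "&include", "&+", "&-", "&*", "&/")

## unprefixed aliases accepted for the iteration macros
macroAliases <- c("foreach" = "&foreach", "foreach-token" = "&foreach-token",
                  "foreach-integer" = "&foreach-integer")

listAtoms <- c("&TOKENS", "&NODES", "&LEAVES", "&BRANCHES", "&COLUMNS")

## ---- the expander ----------------------------------------------------------

## expandSplice returns a list of zero or more expanded expressions.
expandSplice <- function(expr, env) {
  if (isAtom(expr)) {
    if (expr %in% listAtoms) return(lapply(macroListAtom(expr, env), identity))
    if (exists(expr, envir = env$defines, inherits = FALSE))
      return(list(get(expr, envir = env$defines, inherits = FALSE)))
    if (startsWith(expr, "&") && nchar(expr) > 1L &&
        !grepl("^&[0-9.]", expr))
      stop("unknown macro: ", expr, call. = FALSE)
    return(list(expr))
  }
  if (length(expr) == 0L) return(list(expr))
  head <- expr[[1L]]
  if (isAtom(head)) {
    if (!is.na(macroAliases[head])) head <- unname(macroAliases[head])
    if (head %in% macroNames || head %in% listAtoms) {
      res <- expandMacroCall(head, expr[-1L], env)
      return(Filter(function(e) !isEmptyList(e), res))
    }
    if (grepl("^&/.+$", head)) {   # spelled-together division, e.g. (&/1 K)
      first <- substring(head, 3L)
      return(expandSplice(c(list("&/", first), expr[-1L]), env))
    }
    if (startsWith(head, "&"))
      stop("unknown macro: ", head, call. = FALSE)
  }
  out <- list()
  for (e in expr) out <- c(out, expandSplice(e, env))
  list(out)
}

expandOneStrict <- function(expr, env, what = "expression") {
  res <- expandSplice(expr, env)
  if (length(res) != 1L)
    stop("macro ", what, " must expand to exactly one expression, got ",
         length(res), call. = FALSE)
  res[[1L]]
}

expandAtomStrict <- function(expr, env, what = "argument") {
  res <- expandOneStrict(expr, env, what)
  if (!isAtom(res))
    stop("macro ", what, " must expand to an atom, got: ", writeSExpr(res),
         call. = FALSE)
  res
}

macroListAtom <- function(name, env) {
  switch(name,
    "&TOKENS" = {
      if (length(env$tokens) == 0L)
        stop("&TOKENS: no alphabet in context", call. = FALSE)
      env$tokens
    },
    "&NODES" = {
      if (is.null(env$nodes)) stop("&NODES: no tree in context", call. = FALSE)
      env$nodes
    },
    "&LEAVES" = {
      if (is.null(env$leaves)) stop("&LEAVES: no tree in context", call. = FALSE)
      env$leaves
    },
    "&BRANCHES" = {
      if (is.null(env$branches))
        stop("&BRANCHES: no tree in context", call. = FALSE)
      env$branches
    },
    "&COLUMNS" = {
      if (is.null(env$ncol)) stop("&COLUMNS: no alignment in context",
                                  call. = FALSE)
      as.character(seq_len(env$ncol))
    })
}

expandLoop <- function(var, values, body, env) {
  out <- list()
  for (v in values) {
    for (b in body) {
      sb <- substAtom(b, var, v)
      out <- c(out, expandSplice(sb, env))
    }
  }
  out
}

macroTruth <- function(atom) !(atom %in% c("0", ""))

expandMacroCall <- function(head, args, env) {
  switch(head,
    "&foreach-token" = {
      if (length(args) < 2L) stop("&foreach-token needs a variable and a body",
                                  call. = FALSE)
      if (length(env$tokens) == 0L)
        stop("&foreach-token: no alphabet in context", call. = FALSE)
      expandLoop(args[[1L]], env$tokens, args[-1L], env)
    },
    "&foreach" = {
      if (length(args) < 3L)
        stop("&foreach needs a variable, a value list and a body",
             call. = FALSE)
      values <- expandSplice(args[[2L]], env)
      if (length(values) == 1L && isSList(values[[1L]]))
        values <- values[[1L]]
      vals <- vapply(values, function(v) {
        if (!isAtom(v)) stop("&foreach values must be atoms", call. = FALSE)
        v
      }, character(1))
      expandLoop(args[[1L]], vals, args[-(1:2)], env)
    },
    "&foreach-integer" = {
      if (length(args) < 3L || !isSList(args[[2L]]) || length(args[[2L]]) != 2L)
        stop("&foreach-integer needs a variable, a (from to) pair and a body",
             call. = FALSE)
      fromTo <- vapply(args[[2L]],
                       function(a) atomNumber(expandAtomStrict(a, env)),
                       numeric(1))
      if (any(is.na(fromTo)))
        stop("&foreach-integer bounds must be numeric", call. = FALSE)
      values <- if (fromTo[1] <= fromTo[2])
        as.character(seq(fromTo[1], fromTo[2])) else character(0)
      expandLoop(args[[1L]], values, args[-(1:2)], env)
    },
    "&foreach-node" = ,
    "&foreach-leaf" = ,
    "&foreach-branch" = {
      which <- sub("&foreach-", "", head)
      values <- switch(which, node = env$nodes, leaf = env$leaves,
                       branch = env$branches)
      if (is.null(values))
        stop(head, ": no tree in context", call. = FALSE)
      expandLoop(args[[1L]], values, args[-1L], env)
    },
    "&if" = {
      if (length(args) < 2L || length(args) > 3L)
        stop("&if needs a condition and one or two branches", call. = FALSE)
      cond <- expandAtomStrict(args[[1L]], env, "&if condition")
      if (macroTruth(cond)) expandSplice(args[[2L]], env)
      else if (length(args) == 3L) expandSplice(args[[3L]], env)
      else list()
    },
    "&eq" = ,
    "&neq" = {
      a <- expandAtomStrict(args[[1L]], env)
      b <- expandAtomStrict(args[[2L]], env)
      hit <- identical(a, b)
      list(if (xor(head == "&neq", hit)) "1" else "0")
    },
    "&numeq" = ,
    "&gt" = ,
    "&lt" = ,
    "&geq" = ,
    "&leq" = {
      a <- atomNumber(expandAtomStrict(args[[1L]], env))
      b <- atomNumber(expandAtomStrict(args[[2L]], env))
      if (is.na(a) || is.na(b))
        stop(head, ": operands must be numeric", call. = FALSE)
      hit <- switch(head, "&numeq" = a == b, "&gt" = a > b, "&lt" = a < b,
                    "&geq" = a >= b, "&leq" = a <= b)
      list(if (hit) "1" else "0")
    },
    "&cat" = {
      parts <- character(0)
      for (a in args) {
        for (e in expandSplice(a, env)) {
          if (isAtom(e)) parts <- c(parts, e)
          else parts <- c(parts, vapply(e, function(x) {
            if (!isAtom(x))
              stop("&cat arguments must flatten to atoms", call. = FALSE)
            x
          }, character(1)))
        }
      }
      list(paste(parts, collapse = ""))
    },
    "&define" = {
      if (length(args) != 2L || !isAtom(args[[1L]]))
        stop("&define needs a name and a value", call. = FALSE)
      assign(args[[1L]], expandOneStrict(args[[2L]], env, "&define value"),
             envir = env$defines)
      list()
    },
    "&include" = {
      if (length(args) != 1L || !isAtom(args[[1L]]))
        stop("&include needs a file name", call. = FALSE)
      path <- resolveInclude(args[[1L]], env)
      forest <- parseSExpr(readLines(path, warn = FALSE))
      oldFile <- env$file
      env$file <- path
      on.exit(env$file <- oldFile)
      out <- list()
      for (e in forest) out <- c(out, expandSplice(e, env))
      out
    },
    "&+" = list(macroArith("+", lapply(args, expandOneStrict, env = env))),
    "&-" = list(macroArith("-", lapply(args, expandOneStrict, env = env))),
    "&*" = {
      r <- macroArith("*", lapply(args, expandOneStrict, env = env))
      if (is.list(r) && !isAtom(r)) list(r) else list(r)
    },
    "&/" = {
      r <- macroArith("/", lapply(args, expandOneStrict, env = env))
      list(r)
    },
    stop("unknown macro: ", head, call. = FALSE))
}

resolveInclude <- function(name, env) {
  cand <- character(0)
  if (!is.null(env$file)) cand <- file.path(dirname(env$file), name)
  cand <- c(cand, file.path(env$includeDirs, name), name)
  for (p in cand) if (file.exists(p)) return(p)
  stop("&include: cannot find file '", name, "'", call. = FALSE)
}

#' Expand macros in an S-expression
#'
#' Rewrites an expression (or a whole file's forest of expressions) into
#' macro-free form: iteration macros splice one copy of their body per
#' element, \code{&if} keeps one branch, expansions to the empty list are
#' discarded, \code{&cat} builds atoms, arithmetic evaluates to numeric
#' atoms, \code{&define} binds names and \code{&include} splices other files.
#' Expansion is the identity on macro-free input and is deterministic.
#'
#' @param expr a single S-expression.
#' @param env a \code{\link{macroEnv}} supplying alphabet/tree/alignment
#'   context.
#' @return the expanded expression (for \code{expandMacros}), or the expanded
#'   forest as a list (for \code{expandForest}).
#' @examples
#' env <- macroEnv(tokens = c("a", "c", "g", "t"))
#' expandMacros(parseSExpr("(&cat r_ 2)")[[1]], env)
#' @export
expandMacros <- function(expr, env) {
  expandOneStrict(expr, env, "top-level expression")
}

#' @rdname expandMacros
#' @param forest a list of top-level expressions (as from
#'   \code{\link{parseSExpr}}).
#' @export
expandForest <- function(forest, env) {
  out <- list()
  for (e in forest) out <- c(out, expandSplice(e, env))
  out
}
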