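# Expression language for dynamics templates.
#
# Grammar (precedence low -> high):
#   pred   := cmp ( 'and' cmp )*
#   cmp    := sum ( ('<'|'<='|'>'|'>='|'=='|'!=') sum )?
#   sum    := term ( ('+'|'-') term )*
#   term   := unary ( ('*'|'/') unary )*
#   unary  := '-' unary | power
#   power  := atom ( '^' unary )?          (right-associative)
#   atom   := number | ident | ident '(' pred ')' | '(' pred ')'
#
# LEMS-style dotted operators (.lt. .leq. .gt. .geq. .eq. .neq. .and.) are
# accepted and normalised during tokenisation. Allowed functions: exp, log,
# sqrt, abs.

.expr_functions <- c("exp", "log", "sqrt", "abs")

.dotted_ops <- c(".lt." = "<", ".leq." = "<=", ".gt." = ">", ".geq." = ">=",
                 ".eq." = "==", ".neq." = "!=", ".and." = "and")

expr_tokenize <- function(text) {
  for (i in seq_along(.dotted_ops)) {
    text <- gsub(names(.dotted_ops)[i], paste0(" ", .dotted_ops[i], " "),
                 text, fixed = TRUE)
  }
  pattern <- paste0(
    "[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?",  # number
    "|[A-Za-z_][A-Za-z0-9_]*",               # identifier / 'and'
    "|<=|>=|==|!=|&&|[-+*/^()<>]"            # operators
  )
  starts <- gregexpr(pattern, text)[[1]]
  if (starts[1] == -1L) stop("empty expression", call. = FALSE)
  toks <- regmatches(text, gregexpr(pattern, text))[[1]]
  if (nchar(gsub("\\s", "", text)) != sum(nchar(toks)))
    stop("unrecognised characters in expression: '", text, "'", call. = FALSE)
  toks[toks == "&&"] <- "and"
  toks
}

#' Parse a dynamics expression
#'
#' Parses the arithmetic/predicate expression language used in dynamics
#' templates (time derivatives, derived variables, condition tests) into a
#' parse tree. Supported: `+ - * / ^`, unary minus, parentheses, the
#' functions `exp`, `log`, `sqrt`, `abs`, comparisons
#' (`< <= > >= == !=`, or LEMS-style `.lt.` etc.) and conjunction
#' (`and` / `.and.`).
#'
#' @param text expression source string.
#' @return A parse tree of class `wl_expr` (nested lists with nodes of kind
#'   `num`, `var` and `call`).
#' @export
#' @examples
#' e <- parse_expression("gL * (EL - v) / C")
#' eval_expression(e, list(gL = 10e-9, EL = -0.065, v = -0.05, C = 0.2e-9))
parse_expression <- function(text) {
  toks <- expr_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  expect <- function(t) {
    if (!identical(peek(), t))
      stop("expected '", t, "' in expression '", text, "'", call. = FALSE)
    advance()
  }

  parse_pred <- function() {
    left <- parse_cmp()
    while (identical(peek(), "and")) {
      advance()
      left <- list(kind = "call", op = "and", args = list(left, parse_cmp()))
    }
    left
  }
  parse_cmp <- function() {
    left <- parse_sum()
    if (!is.na(peek()) && peek() %in% c("<", "<=", ">", ">=", "==", "!=")) {
      op <- advance()
      left <- list(kind = "call", op = op, args = list(left, parse_sum()))
    }
    left
  }
  parse_sum <- function() {
    left <- parse_term()
    while (!is.na(peek()) && peek() %in% c("+", "-")) {
      op <- advance()
      left <- list(kind = "call", op = op, args = list(left, parse_term()))
    }
    left
  }
  parse_term <- function() {
    left <- parse_unary()
    while (!is.na(peek()) && peek() %in% c("*", "/")) {
      op <- advance()
      left <- list(kind = "call", op = op, args = list(left, parse_unary()))
    }
    left
  }
  parse_unary <- function() {
    if (identical(peek(), "-")) {
      advance()
      return(list(kind = "call", op = "neg", args = list(parse_unary())))
    }
    parse_power()
  }
  parse_power <- function() {
    base <- parse_atom()
    if (identical(peek(), "^")) {
      advance()
      return(list(kind = "call", op = "^", args = list(base, parse_unary())))
    }
    base
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression '", text, "'", call. = FALSE)
    if (grepl("^[0-9.]", t)) {
      advance()
      return(list(kind = "num", value = as.numeric(t)))
    }
    if (t == "(") {
      advance()
      inner <- parse_pred()
      expect(")")
      return(inner)
    }
    if (grepl("^[A-Za-z_]", t)) {
      advance()
      if (identical(peek(), "(")) {
        if (!t %in% .expr_functions)
          stop("unknown function '", t, "' in expression", call. = FALSE)
        advance()
        arg <- parse_pred()
        expect(")")
        return(list(kind = "call", op = t, args = list(arg)))
      }
      return(list(kind = "var", name = t))
    }
    stop("unexpected token '", t, "' in expression '", text, "'",
         call. = FALSE)
  }

  tree <- parse_pred()
  if (pos <= length(toks))
    stop("trailing tokens in expression '", text, "'", call. = FALSE)
  structure(tree, class = "wl_expr")
}

#' Evaluate a parsed expression by direct tree recursion
#'
#' The reference evaluator: a recursive walk over the parse tree. Every
#' free variable must be supplied in `env`. Comparisons and `and` yield
#' 1 (true) / 0 (false).
#'
#' @param expr a `wl_expr` from [parse_expression()] (or a raw node).
#' @param env named list or environment of variable values.
#' @return A numeric scalar.
#' @export
eval_expression <- function(expr, env = list()) {
  if (is.environment(env)) env <- as.list(env)
  rec <- function(node) {
    switch(node$kind,
      num = node$value,
      var = {
        v <- env[[node$name]]
        if (is.null(v))
          stop("unbound symbol '", node$name, "' in expression", call. = FALSE)
        v
      },
      call = {
        a <- lapply(node$args, rec)
        switch(node$op,
          "+" = a[[1]] + a[[2]],
          "-" = a[[1]] - a[[2]],
          "*" = a[[1]] * a[[2]],
          "/" = a[[1]] / a[[2]],
          "^" = a[[1]]^a[[2]],
          neg = -a[[1]],
          "<" = as.numeric(a[[1]] < a[[2]]),
          "<=" = as.numeric(a[[1]] <= a[[2]]),
          ">" = as.numeric(a[[1]] > a[[2]]),
          ">=" = as.numeric(a[[1]] >= a[[2]]),
          "==" = as.numeric(a[[1]] == a[[2]]),
          "!=" = as.numeric(a[[1]] != a[[2]]),
          and = as.numeric(a[[1]] != 0 && a[[2]] != 0),
          exp = exp(a[[1]]),
          log = log(a[[1]]),
          sqrt = sqrt(a[[1]]),
          abs = abs(a[[1]]),
          stop("unknown operator '", node$op, "'", call. = FALSE)
        )
      },
      stop("malformed expression node", call. = FALSE)
    )
  }
  rec(expr)
}

#' Free variables of an expression
#'
#' @param expr a `wl_expr`.
#' @return Character vector of distinct symbol names referenced.
#' @export
expr_variables <- function(expr) {
  acc <- character()
  rec <- function(node) {
    if (node$kind == "var") acc[[length(acc) + 1L]] <<- node$name
    if (node$kind == "call") lapply(node$args, rec)
    invisible(NULL)
  }
  rec(expr)
  unique(acc)
}

# Convert a parse tree to an R language object; the runtime compiles these
# into closures once per flatten, which is much faster than tree recursion
# in the integration loop.
expr_to_lang <- function(expr) {
  rec <- function(node) {
    switch(node$kind,
      num = node$value,
      var = as.name(node$name),
      call = {
        a <- lapply(node$args, rec)
        switch(node$op,
          neg = call("-", a[[1]]),
          and = call("&", call("!=", a[[1]], 0), call("!=", a[[2]], 0)),
          "<" = , "<=" = , ">" = , ">=" = , "==" = , "!=" =
            call(node$op, a[[1]], a[[2]]),
          do.call(call, c(list(node$op), a), quote = TRUE)
        )
      }
    )
  }
  rec(expr)
}

expr_compile <- function(expr) {
  lang <- expr_to_lang(expr)
  function(.env) as.numeric(eval(lang, .env))
}

# Dimension of an expression given dimensions of its free symbols.
# Comparisons/conjunction yield dimensionless and require compatible sides;
# functions require dimensionless arguments; '^' requires a literal
# exponent (integer unless the base is dimensionless); numeric literals
# are dimensionless.
expr_dimension <- function(expr, symbol_dims) {
  dimless <- dimension()
  rec <- function(node) {
    switch(node$kind,
      num = dimless,
      var = {
        d <- symbol_dims[[node$name]]
        if (is.null(d))
          stop("symbol '", node$name, "' has no declared dimension",
               call. = FALSE)
        d
      },
      call = {
        op <- node$op
        if (op %in% c("+", "-")) {
          a <- rec(node$args[[1]]); b <- rec(node$args[[2]])
          if (!dim_equal(a, b))
            stop("dimension mismatch in '", op, "'", call. = FALSE)
          a
        } else if (op == "*") {
          dim_multiply(rec(node$args[[1]]), rec(node$args[[2]]))
        } else if (op == "/") {
          dim_divide(rec(node$args[[1]]), rec(node$args[[2]]))
        } else if (op == "neg") {
          rec(node$args[[1]])
        } else if (op == "^") {
          base <- rec(node$args[[1]])
          ex <- node$args[[2]]
          if (dim_is_dimensionless(base)) return(dimless)
          if (ex$kind != "num" || ex$value != round(ex$value))
            stop("non-integer power of a dimensional quantity", call. = FALSE)
          dim_power(base, ex$value)
        } else if (op %in% c("<", "<=", ">", ">=", "==", "!=")) {
          a <- rec(node$args[[1]]); b <- rec(node$args[[2]])
          if (!dim_equal(a, b))
            stop("dimension mismatch in comparison", call. = FALSE)
          dimless
        } else if (op == "and") {
          rec(node$args[[1]]); rec(node$args[[2]])
          dimless
        } else {
          a <- rec(node$args[[1]])
          if (!dim_is_dimensionless(a))
            stop("function '", op, "' requires a dimensionless argument",
                 call. = FALSE)
          dimless
        }
      }
    )
  }
  rec(expr)
}

# Render a parse tree back to source (fully parenthesised; deterministic).
expr_deparse <- function(expr) {
  rec <- function(node) {
    switch(node$kind,
      num = format(node$value, digits = 15, scientific = FALSE, trim = TRUE),
      var = node$name,
      call = {
        a <- vapply(node$args, rec, "")
        switch(node$op,
          neg = paste0("(-", a[[1]], ")"),
          and = paste0("(", a[[1]], " and ", a[[2]], ")"),
          exp = , log = , sqrt = , abs = paste0(node$op, "(", a[[1]], ")"),
          paste0("(", a[[1]], " ", node$op, " ", a[[2]], ")")
        )
      }
    )
  }
  rec(expr)
}
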