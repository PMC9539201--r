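## Expression trees for fuzzy-logic propositions.
##
## A proposition is stored as a nested list of class "fz_expr" with a `kind`
## field: "var", "const", "and", "or" or "not".  Conjunction and disjunction
## are binary; rules with more operands are left-folded, which is
## unobservable because both connectives are associative under the
## multiplicative norm.

fz_var <- function(name) {
  structure(list(kind = "var", name = name), class = "fz_expr")
}

fz_const <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop_fz("constants in rules must lie in [0,1], got ", format(value),
            class = "fuzzynet_domain_error")
  }
  structure(list(kind = "const", value = as.numeric(value)), class = "fz_expr")
}

fz_and <- function(lhs, rhs) {
  structure(list(kind = "and", lhs = lhs, rhs = rhs), class = "fz_expr")
}

fz_or <- function(lhs, rhs) {
  structure(list(kind = "or", lhs = lhs, rhs = rhs), class = "fz_expr")
}

fz_not <- function(arg) {
  structure(list(kind = "not", arg = arg), class = "fz_expr")
}

stop_fz <- function(..., class) {
  rlang::abort(paste0(...), class = class)
}

#' Evaluate a fuzzy proposition under the multiplicative t-norm
#'
#' Truth values live in \eqn{[0,1]}. Connectives follow the product norm:
#' conjunction \eqn{p \wedge q \to p\,q}, disjunction
#' \eqn{p \vee q \to p + q - p\,q}, negation \eqn{\neg q \to 1 - q}.
#' Restricted to \{0,1\} states this reduces to ordinary Boolean evaluation.
#'
#' @param expr A `fz_expr` as returned by [fz_parse()].
#' @param state Named numeric vector (or list) of node levels in \eqn{[0,1]}.
#' @return A numeric truth value in \eqn{[0,1]}.
#' @examples
#' e <- fz_parse("q1 & (q2 | q3) & !q4")
#' fz_eval(e, c(q1 = 1, q2 = 0.5, q3 = 0.5, q4 = 0))  # 0.75
#' @export
fz_eval <- function(expr, state) {
  state <- unlist(state)
  if (length(state) && (anyNA(state) || any(state < 0) || any(state > 1))) {
    bad <- names(state)[is.na(state) | state < 0 | state > 1]
    stop_fz("state values outside [0,1] for: ", paste(bad, collapse = ", "),
            class = "fuzzynet_domain_error")
  }
  fz_eval_rec(expr, state)
}

fz_eval_rec <- function(expr, state) {
  switch(expr$kind,
    var = {
      v <- state[expr$name]
      if (is.na(match(expr$name, names(state)))) {
        stop_fz("unresolved symbol in rule: ", expr$name,
                class = "fuzzynet_unresolved_symbol")
      }
      unname(v)
    },
    const = expr$value,
    and = fz_eval_rec(expr$lhs, state) * fz_eval_rec(expr$rhs, state),
    or = {
      p <- fz_eval_rec(expr$lhs, state)
      q <- fz_eval_rec(expr$rhs, state)
      p + q - p * q
    },
    not = 1 - fz_eval_rec(expr$arg, state),
    stop_fz("corrupt expression node kind: ", expr$kind,
            class = "fuzzynet_internal_error")
  )
}

#' Sigmoid characteristic (gating) function
#'
#' Maps a proposition's fuzzy value to an activation input through
#' \eqn{\mu(v) = 1 / (1 + e^{-\beta (v - \theta)})}. `beta` is the rate at
#' which the proposition is expressed and `theta` the truth threshold; the
#' defaults (`beta = 10`, `theta = 1/2`) place the midpoint at the fuzzy
#' boundary between falsity and truth, so `fz_gate(theta) == 0.5` for any
#' `beta`. The range is the open interval (0,1): the gate never saturates
#' exactly, which keeps every node's dynamics strictly inward-pointing at the
#' boundary of the unit hypercube.
#'
#' @param v Numeric vector of fuzzy truth values.
#' @param beta Positive slope parameter (default 10).
#' @param theta Threshold in (0,1) (default 0.5).
#' @return Numeric vector of gated values in (0,1).
#' @export
fz_gate <- function(v, beta = 10, theta = 0.5) {
  stopifnot(is.numeric(v), beta > 0, theta > 0, theta < 1)
  1 / (1 + exp(-beta * (v - theta)))
}

#' Variables referenced by a proposition
#'
#' @param expr A `fz_expr`.
#' @return Character vector of distinct variable names, in first-use order.
#' @export
fz_vars <- function(expr) {
  out <- switch(expr$kind,
    var = expr$name,
    const = character(),
    and = c(fz_vars(expr$lhs), fz_vars(expr$rhs)),
    or = c(fz_vars(expr$lhs), fz_vars(expr$rhs)),
    not = fz_vars(expr$arg)
  )
  unique(out)
}

## Compile an AST to an R expression in the node-name environment; used by
## the ODE right-hand side so each rule is a single eval() of native
## arithmetic rather than a recursive list walk.
fz_compile <- function(expr) {
  switch(expr$kind,
    var = as.name(expr$name),
    const = expr$value,
    and = call("*", fz_compile(expr$lhs), fz_compile(expr$rhs)),
    or = {
      p <- fz_compile(expr$lhs)
      q <- fz_compile(expr$rhs)
      call("-", call("+", p, q), call("*", p, q))
    },
    not = call("-", 1, fz_compile(expr$arg))
  )
}

#' Parse a Boolean rule string into a fuzzy expression tree
#'
#' Grammar: `expr := term ('|' term)* ; term := factor ('&' factor)* ;
#' factor := '!' factor | '(' expr ')' | IDENT | NUMBER`. Identifiers start
#' with a letter or underscore and may contain letters, digits, underscores
#' and hyphens. Both symbolic (`&`, `|`, `!`) and word (`AND`, `OR`, `NOT`,
#' case-insensitive) operator spellings are accepted. Numeric literals must
#' lie in \eqn{[0,1]}.
#'
#' @param text A single rule string.
#' @return A `fz_expr`.
#' @examples
#' fz_deparse(fz_parse("A AND NOT (B OR C)"))
#' @export
fz_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- fz_tokenize(text)
  if (nrow(toks) == 0L) {
    stop_fz("empty rule", class = "fuzzynet_parse_error")
  }
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  e <- fz_parse_or(st, text)
  if (st$pos <= nrow(st$toks)) {
    tk <- st$toks[st$pos, ]
    stop_fz("syntax error at column ", tk$col, ": unexpected '", tk$text, "'",
            class = "fuzzynet_parse_error")
  }
  e
}

fz_tokenize <- function(text) {
  pat <- "([A-Za-z_][A-Za-z0-9_-]*)|([0-9]*\\.?[0-9]+)|([&|!()])|(\\s+)|(.)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  pieces <- substring(text, starts, starts + lens - 1L)
  keep <- !grepl("^\\s+$", pieces)
  pieces <- pieces[keep]
  starts <- starts[keep]
  if (length(pieces) == 0L) {
    return(data.frame(type = character(), text = character(), col = integer()))
  }
  type <- ifelse(grepl("^[A-Za-z_]", pieces), "ident",
          ifelse(grepl("^[0-9.]", pieces), "number",
          ifelse(pieces %in% c("&", "|", "!", "(", ")"), pieces, "bad")))
  up <- toupper(pieces)
  type[type == "ident" & up == "AND"] <- "&"
  type[type == "ident" & up == "OR"] <- "|"
  type[type == "ident" & up == "NOT"] <- "!"
  if (any(type == "bad")) {
    i <- which(type == "bad")[1L]
    stop_fz("syntax error at column ", starts[i], ": unexpected '",
            pieces[i], "'", class = "fuzzynet_parse_error")
  }
  data.frame(type = type, text = pieces, col = starts,
             stringsAsFactors = FALSE)
}

fz_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

fz_advance <- function(st) {
  tk <- st$toks[st$pos, ]
  st$pos <- st$pos + 1L
  tk
}

fz_parse_or <- function(st, text) {
  e <- fz_parse_and(st, text)
  while (!is.null(tk <- fz_peek(st)) && tk$type == "|") {
    fz_advance(st)
    e <- fz_or(e, fz_parse_and(st, text))
  }
  e
}

fz_parse_and <- function(st, text) {
  e <- fz_parse_factor(st, text)
  while (!is.null(tk <- fz_peek(st)) && tk$type == "&") {
    fz_advance(st)
    e <- fz_and(e, fz_parse_factor(st, text))
  }
  e
}

fz_parse_factor <- function(st, text) {
  tk <- fz_peek(st)
  if (is.null(tk)) {
    stop_fz("syntax error: unexpected end of rule in '", text, "'",
            class = "fuzzynet_parse_error")
  }
  if (tk$type == "!") {
    fz_advance(st)
    return(fz_not(fz_parse_factor(st, text)))
  }
  if (tk$type == "(") {
    fz_advance(st)
    e <- fz_parse_or(st, text)
    tk2 <- fz_peek(st)
    if (is.null(tk2) || tk2$type != ")") {
      stop_fz("syntax error at column ", tk$col, ": unbalanced parenthesis",
              class = "fuzzynet_parse_error")
    }
    fz_advance(st)
    return(e)
  }
  if (tk$type == "ident") {
    fz_advance(st)
    return(fz_var(tk$text))
  }
  if (tk$type == "number") {
    fz_advance(st)
    val <- as.numeric(tk$text)
    if (is.na(val) || val < 0 || val > 1) {
      stop_fz("syntax error at column ", tk$col,
              ": numeric literal outside [0,1]: ", tk$text,
              class = "fuzzynet_parse_error")
    }
    return(fz_const(val))
  }
  stop_fz("syntax error at column ", tk$col, ": unexpected '", tk$text, "'",
          class = "fuzzynet_parse_error")
}

#' Canonical printer for fuzzy expressions
#'
#' Emits the symbolic spelling (`&`, `|`, `!`) with minimal parentheses;
#' `fz_parse(fz_deparse(e))` reproduces `e`.
#'
#' @param expr A `fz_expr`.
#' @return A single string.
#' @export
fz_deparse <- function(expr) {
  prec <- function(e) switch(e$kind, or = 1L, and = 2L, not = 3L, 4L)
  wrap <- function(e, outer) {
    s <- fz_deparse(e)
    if (prec(e) < outer) paste0("(", s, ")") else s
  }
  switch(expr$kind,
    var = expr$name,
    const = format(expr$value, trim = TRUE),
    and = paste(wrap(expr$lhs, 2L), "&", wrap(expr$rhs, 2L)),
    or = paste(wrap(expr$lhs, 1L), "|", wrap(expr$rhs, 1L)),
    not = paste0("!", wrap(expr$arg, 4L))
  )
}

#' @export
print.fz_expr <- function(x, ...) {
  cat("<fuzzy proposition> ", fz_deparse(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.fz_expr <- function(x, ...) fz_deparse(x)
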