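#' Row filters for event tables
#'
#' Filters use a small expression grammar: comparisons (`<`, `<=`, `>`,
#' `>=`, `==`, `!=`) between a column name and a numeric or quoted-string
#' literal, combined with `and` / `or` and parentheses, e.g.
#' `"Case > 10 and RelativeTime < 380"`. Filtering happens after the
#' derived columns are computed and does not re-anchor `relative_time`.
#'
#' @name event_filter
NULL

FILTER_OPS <- c("<=", ">=", "==", "!=", "<", ">")

tokenize_filter <- function(expression) {
  tokens <- list()
  i <- 1L
  n <- nchar(expression)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    if (ch == "(") {
      push("lparen", "(", i); i <- i + 1L; next
    }
    if (ch == ")") {
      push("rparen", ")", i); i <- i + 1L; next
    }
    two <- substr(expression, i, i + 1L)
    if (two %in% FILTER_OPS) {
      push("op", two, i); i <- i + 2L; next
    }
    if (ch %in% c("<", ">")) {
      push("op", ch, i); i <- i + 1L; next
    }
    if (ch %in% c("'", '"')) {
      rest <- substr(expression, i + 1L, n)
      close <- regexpr(ch, rest, fixed = TRUE)
      if (close < 0) {
        stop(sprintf("filter syntax error at position %d: unterminated string", i))
      }
      push("string", substr(rest, 1L, close - 1L), i)
      i <- i + close + 1L
      next
    }
    if (grepl("^[0-9.+-]$", ch)) {
      m <- regexpr("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                   substr(expression, i, n))
      if (m < 0) {
        stop(sprintf("filter syntax error at position %d: bad number", i))
      }
      len <- attr(m, "match.length")
      push("number", as.numeric(substr(expression, i, i + len - 1L)), i)
      i <- i + len
      next
    }
    if (grepl("^[A-Za-z_.]$", ch)) {
      m <- regexpr("^[A-Za-z_.][A-Za-z0-9_.]*", substr(expression, i, n))
      len <- attr(m, "match.length")
      word <- substr(expression, i, i + len - 1L)
      if (word %in% c("and", "or")) {
        push(word, word, i)
      } else {
        push("ident", word, i)
      }
      i <- i + len
      next
    }
    stop(sprintf("filter syntax error at position %d: unexpected '%s'", i, ch))
  }
  tokens
}

# Recursive-descent parser: expr := term ('or' term)*;
# term := factor ('and' factor)*; factor := '(' expr ')' | ident op literal.
parse_filter <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  expect <- function(type, what) {
    tok <- peek()
    if (is.null(tok)) {
      stop(sprintf("filter syntax error at end of expression: expected %s", what))
    }
    if (tok$type != type) {
      stop(sprintf("filter syntax error at position %d: expected %s, got '%s'",
                   tok$pos, what, tok$value))
    }
    advance()
  }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      node <- list(kind = "or", left = node, right = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      node <- list(kind = "and", left = node, right = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) {
      stop("filter syntax error at end of expression: expected comparison")
    }
    if (tok$type == "lparen") {
      advance()
      node <- parse_expr()
      expect("rparen", "')'")
      return(node)
    }
    ident <- expect("ident", "column name")
    op <- expect("op", "comparison operator")
    lit <- peek()
    if (is.null(lit) || !lit$type %in% c("number", "string")) {
      stop(sprintf("filter syntax error at position %d: expected literal",
                   if (is.null(lit)) nchar_end(tokens) else lit$pos))
    }
    advance()
    list(kind = "cmp", column = ident$value, pos = ident$pos,
         op = op$value, literal = lit$value)
  }
  root <- parse_expr()
  if (!is.null(peek())) {
    tok <- peek()
    stop(sprintf("filter syntax error at position %d: unexpected '%s'",
                 tok$pos, tok$value))
  }
  root
}

nchar_end <- function(tokens) {
  last <- tokens[[length(tokens)]]
  last$pos + nchar(as.character(last$value))
}

resolve_filter_column <- function(name, events) {
  if (name %in% names(events)) {
    return(events[[name]])
  }
  if (name %in% names(CANONICAL_ALIASES) &&
      CANONICAL_ALIASES[[name]] %in% names(events)) {
    return(events[[CANONICAL_ALIASES[[name]]]])
  }
  stop(sprintf("unknown column '%s' in filter expression", name))
}

eval_filter_node <- function(node, events) {
  if (node$kind == "and") {
    return(eval_filter_node(node$left, events) & eval_filter_node(node$right, events))
  }
  if (node$kind == "or") {
    return(eval_filter_node(node$left, events) | eval_filter_node(node$right, events))
  }
  col <- resolve_filter_column(node$column, events)
  lit <- node$literal
  if (is.numeric(lit) && !is.numeric(col)) {
    col <- suppressWarnings(as.numeric(as.character(col)))
  }
  if (is.character(lit)) col <- as.character(col)
  res <- do.call(node$op, list(col, lit))
  res & !is.na(res)
}

#' Filter an event table with a comparison expression
#'
#' Keeps the rows for which the expression is true. Column names are matched
#' exactly and case-sensitively against the table's columns; the display
#' names `Time`, `Case`, `EventType`, `RelativeTime` and `AnyEvent` are also
#' accepted for the canonical role columns. Derived columns are not
#' recomputed: `relative_time` keeps its pre-filter anchoring.
#'
#' @param events An [event_table].
#' @param expression Filter string, e.g. `"Case > 10 and RelativeTime < 380"`.
#' @return The filtered `event_table`.
#' @export
#' @examples
#' ev <- as_event_table(data.frame(time = c(1, 5, 9), case = "A"))
#' filter_events(ev, "RelativeTime < 5")
filter_events <- function(events, expression) {
  stopifnot(is.character(expression), length(expression) == 1L)
  tokens <- tokenize_filter(expression)
  if (length(tokens) == 0L) {
    stop("filter syntax error: empty expression")
  }
  ast <- parse_filter(tokens)
  keep <- eval_filter_node(ast, events)
  new_event_table(events[keep, , drop = FALSE])
}
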