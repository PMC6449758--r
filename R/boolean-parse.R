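# Parsing of Boolean network models written in a MaBoSS-style two-file
# dialect.  The supported subset is documented in ?parse_network; constructs
# outside the subset are rejected with a named error.

# ---- tokenizer -------------------------------------------------------------

.bn_tokenize <- function(text) {
  # strip // and # comments
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("//.*$", "", lines)
  lines <- sub("#.*$", "", lines)
  text <- paste(lines, collapse = "\n")
  pat <- "\\$?[A-Za-z_][A-Za-z0-9_]*|[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?|\\{|\\}|\\(|\\)|;|=|&&|\\|\\||&|\\||!|\\.|,"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # anything not matched by the token pattern (other than whitespace) is illegal
  rest <- text
  regmatches(rest, gregexpr(pat, rest)) <- list(rep("", length(toks)))
  rest <- gsub("[[:space:]]", "", rest)
  if (nzchar(rest))
    stop("unexpected character(s) in model text: '",
         substr(rest, 1, 10), "'", call. = FALSE)
  toks
}

# cursor over a token vector
.bn_cursor <- function(tokens) {
  e <- new.env(parent = emptyenv())
  e$toks <- tokens
  e$i <- 1L
  e
}
.bn_peek <- function(cur) if (cur$i <= length(cur$toks)) cur$toks[cur$i] else NA_character_
.bn_next <- function(cur) {
  t <- .bn_peek(cur)
  cur$i <- cur$i + 1L
  t
}
.bn_expect <- function(cur, what) {
  t <- .bn_next(cur)
  if (is.na(t) || t != what)
    stop("parse error: expected '", what, "' but found '",
         if (is.na(t)) "<end of input>" else t, "'", call. = FALSE)
  t
}
.bn_is_ident <- function(t) !is.na(t) && grepl("^[A-Za-z_][A-Za-z0-9_]*$", t)
.bn_is_number <- function(t) !is.na(t) && grepl("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", t)

# ---- logic expression -> AST ----------------------------------------------

# AST: list(op = "var"/"const"/"and"/"or"/"not", ...)
.bn_parse_expr <- function(cur) {
  lhs <- .bn_parse_and(cur)
  repeat {
    t <- .bn_peek(cur)
    if (!is.na(t) && (t == "|" || t == "||" || toupper(t) == "OR")) {
      .bn_next(cur)
      rhs <- .bn_parse_and(cur)
      lhs <- list(op = "or", a = lhs, b = rhs)
    } else break
  }
  lhs
}
.bn_parse_and <- function(cur) {
  lhs <- .bn_parse_unary(cur)
  repeat {
    t <- .bn_peek(cur)
    if (!is.na(t) && (t == "&" || t == "&&" || toupper(t) == "AND")) {
      .bn_next(cur)
      rhs <- .bn_parse_unary(cur)
      lhs <- list(op = "and", a = lhs, b = rhs)
    } else break
  }
  lhs
}
.bn_parse_unary <- function(cur) {
  t <- .bn_peek(cur)
  if (!is.na(t) && (t == "!" || toupper(t) == "NOT")) {
    .bn_next(cur)
    return(list(op = "not", a = .bn_parse_unary(cur)))
  }
  .bn_parse_primary(cur)
}
.bn_parse_primary <- function(cur) {
  t <- .bn_next(cur)
  if (is.na(t)) stop("parse error: unexpected end of logic expression", call. = FALSE)
  if (t == "(") {
    e <- .bn_parse_expr(cur)
    .bn_expect(cur, ")")
    return(e)
  }
  if (t == "0") return(list(op = "const", value = FALSE))
  if (t == "1") return(list(op = "const", value = TRUE))
  if (.bn_is_ident(t)) return(list(op = "var", name = t))
  stop("parse error in logic expression near '", t, "'", call. = FALSE)
}

# compile AST to reverse-Polish integer code (see src/boolean.cpp)
.bn_compile <- function(ast, index, node) {
  switch(ast$op,
    var = {
      i <- index[[ast$name]]
      if (is.null(i))
        stop("logic of node '", node, "' references undeclared node '",
             ast$name, "'", call. = FALSE)
      i
    },
    const = if (ast$value) -4L else -5L,
    not = c(.bn_compile(ast$a, index, node), -3L),
    and = c(.bn_compile(ast$a, index, node), .bn_compile(ast$b, index, node), -1L),
    or  = c(.bn_compile(ast$a, index, node), .bn_compile(ast$b, index, node), -2L)
  )
}

.bn_ast_vars <- function(ast) {
  switch(ast$op,
    var = ast$name,
    const = character(0),
    not = .bn_ast_vars(ast$a),
    c(.bn_ast_vars(ast$a), .bn_ast_vars(ast$b))
  )
}

# ---- model (.bnd) file -----------------------------------------------------

# returns list of raw node specs (rates possibly symbolic "$x")
.bn_parse_model <- function(text) {
  cur <- .bn_cursor(.bn_tokenize(text))
  nodes <- list()
  repeat {
    t <- .bn_peek(cur)
    if (is.na(t)) break
    if (toupper(t) == "NODE") .bn_next(cur)
    name <- .bn_next(cur)
    if (!.bn_is_ident(name))
      stop("parse error: expected a node name, found '", name, "'", call. = FALSE)
    if (!is.null(nodes[[name]]))
      stop("duplicate node '", name, "'", call. = FALSE)
    .bn_expect(cur, "{")
    spec <- list(name = name, logic = NULL, rate_up = "1", rate_down = "1",
                 is_input = FALSE, is_internal = FALSE)
    while (!identical(.bn_peek(cur), "}")) {
      field <- .bn_next(cur)
      if (is.na(field)) stop("parse error: unterminated block for node '",
                             name, "'", call. = FALSE)
      .bn_expect(cur, "=")
      if (field == "logic") {
        spec$logic <- .bn_parse_expr(cur)
      } else if (field %in% c("rate_up", "rate_down")) {
        v <- .bn_next(cur)
        if (!(.bn_is_number(v) || startsWith(v, "$")))
          stop("rate of node '", name, "' must be a number or $symbol, found '",
               v, "'", call. = FALSE)
        spec[[field]] <- v
      } else if (field %in% c("is_input", "is_internal")) {
        v <- toupper(.bn_next(cur))
        if (!v %in% c("TRUE", "FALSE", "0", "1"))
          stop("flag '", field, "' of node '", name, "' must be TRUE/FALSE",
               call. = FALSE)
        spec[[field]] <- v %in% c("TRUE", "1")
      } else {
        stop("unsupported field '", field, "' in node '", name,
             "' (supported: logic, rate_up, rate_down, is_input, is_internal)",
             call. = FALSE)
      }
      .bn_expect(cur, ";")
    }
    .bn_expect(cur, "}")
    nodes[[name]] <- spec
  }
  if (!length(nodes)) stop("model text declares no nodes", call. = FALSE)
  nodes
}

# ---- config (.cfg) file ----------------------------------------------------

# returns list(symbols = named numeric, node_settings = list(name -> list))
.bn_parse_config <- function(text) {
  cur <- .bn_cursor(.bn_tokenize(text))
  symbols <- list()
  settings <- list()
  repeat {
    t <- .bn_peek(cur)
    if (is.na(t)) break
    t <- .bn_next(cur)
    if (startsWith(t, "$")) {
      .bn_expect(cur, "=")
      v <- .bn_next(cur)
      if (!.bn_is_number(v))
        stop("config error: '", t, "' must be assigned a number", call. = FALSE)
      symbols[[substring(t, 2)]] <- as.numeric(v)
      .bn_expect(cur, ";")
    } else if (.bn_is_ident(t)) {
      .bn_expect(cur, ".")
      key <- .bn_next(cur)
      .bn_expect(cur, "=")
      v <- .bn_next(cur)
      .bn_expect(cur, ";")
      if (is.null(settings[[t]])) settings[[t]] <- list()
      if (key %in% c("is_internal", "is_input")) {
        settings[[t]][[key]] <- toupper(v) %in% c("TRUE", "1")
      } else if (key == "istate") {
        p <- as.numeric(v)
        if (is.na(p) || p < 0 || p > 1)
          stop("config error: ", t, ".istate must be a probability", call. = FALSE)
        settings[[t]][[key]] <- p
      } else {
        stop("unsupported config key '", t, ".", key,
             "' (supported: istate, is_internal, is_input)", call. = FALSE)
      }
    } else {
      stop("config parse error near '", t, "'", call. = FALSE)
    }
  }
  list(symbols = symbols, settings = settings)
}

# ---- public API ------------------------------------------------------------

#' Parse a Boolean network from MaBoSS-style model and config texts
#'
#' The documented dialect subset is: the model file holds `node NAME { ... }`
#' blocks (the `node` keyword is optional) with fields `logic` (expression
#' over node names using `&`/`|`/`!` or `AND`/`OR`/`NOT`, parentheses and the
#' constants 0/1), `rate_up`, `rate_down` (a number or a `$symbol` resolved
#' from the config), and optional flags `is_input` / `is_internal`.  The
#' config file holds `$symbol = number;` assignments and per-node settings
#' `NAME.istate = p;` (probability of starting at 1, default 0),
#' `NAME.is_internal = TRUE;`, `NAME.is_input = TRUE;`.  Comments start with
#' `//` or `#`.  Input nodes are pinned: they undergo no stochastic
#' transitions and are set only by the coupling layer (or initial state).
#'
#' @param model_text model file contents (single string or character vector
#'   of lines); `model_file`/`config_file` variants read from disk.
#' @param config_text config file contents ("" for none).
#' @param symbols named list overriding/adding `$symbol` values after the
#'   config file is read.
#' @return an object of class `boolean_network`.
#' @export
parse_network <- function(model_text, config_text = "", symbols = list()) {
  if (length(model_text) > 1) model_text <- paste(model_text, collapse = "\n")
  if (length(config_text) > 1) config_text <- paste(config_text, collapse = "\n")
  raw <- .bn_parse_model(model_text)
  cfg <- .bn_parse_config(config_text)
  cfg$symbols <- modifyList(cfg$symbols, symbols)

  names_vec <- names(raw)
  # a list so that lookups of unknown names yield NULL, not an error
  index <- as.list(setNames(seq_along(names_vec), names_vec))

  resolve_rate <- function(v, node, which) {
    if (startsWith(v, "$")) {
      sym <- substring(v, 2)
      if (is.null(cfg$symbols[[sym]]))
        stop("config error: rate symbol '$", sym, "' of node '", node,
             "' (", which, ") is not assigned", call. = FALSE)
      v <- cfg$symbols[[sym]]
    }
    v <- as.numeric(v)
    if (!is.finite(v) || v < 0)
      stop("rate ", which, " of node '", node, "' must be finite and >= 0",
           call. = FALSE)
    v
  }

  n <- length(raw)
  net <- list(
    nodes = names_vec,
    index = index,
    logic = vector("list", n),
    code = vector("list", n),
    rate_up = numeric(n), rate_down = numeric(n),
    is_input = logical(n), is_internal = logical(n),
    istate = numeric(n)
  )
  for (i in seq_len(n)) {
    sp <- raw[[i]]
    s <- cfg$settings[[sp$name]]
    if (!is.null(s)) {
      for (k in names(s)) sp[[k]] <- s[[k]]
    }
    if (is.null(sp$logic)) sp$logic <- list(op = "const", value = FALSE)
    net$logic[[i]] <- sp$logic
    net$code[[i]] <- as.integer(.bn_compile(sp$logic, index, sp$name))
    net$rate_up[i] <- resolve_rate(sp$rate_up, sp$name, "rate_up")
    net$rate_down[i] <- resolve_rate(sp$rate_down, sp$name, "rate_down")
    net$is_input[i] <- isTRUE(sp$is_input)
    net$is_internal[i] <- isTRUE(sp$is_internal)
    net$istate[i] <- if (!is.null(sp$istate)) sp$istate else 0
  }
  # flattened RPN programs for the C++ kernel
  net$flat <- list(
    code = unlist(net$code),
    off = as.integer(cumsum(c(0L, vapply(net$code, length, 1L)))[seq_len(n)]),
    len = vapply(net$code, length, 1L)
  )
  class(net) <- "boolean_network"
  net
}

#' @rdname parse_network
#' @param model_file,config_file paths to the two text files.
#' @export
parse_network_files <- function(model_file, config_file = NULL, symbols = list()) {
  model <- paste(readLines(model_file, warn = FALSE), collapse = "\n")
  config <- if (is.null(config_file)) "" else
    paste(readLines(config_file, warn = FALSE), collapse = "\n")
  parse_network(model, config, symbols = symbols)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", length(x$nodes), "nodes (",
      sum(x$is_input), "input,", sum(x$is_internal), "internal )\n")
  readouts <- x$nodes[!x$is_internal & !x$is_input]
  if (length(readouts)) cat("read-outs:", paste(readouts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.boolean_network <- function(x) length(x$nodes)

#' Rate override (mutation) specification
#'
#' Mutations are modelled as overrides of a node's up/down transition rates,
#' leaving the logic untouched.  `overexpress()` pins a node at 1 (very high
#' activation rate, null deactivation); `knockout()` pins it at 0.
#'
#' @param node node name.
#' @param rate_up,rate_down new rates in 1/min (NA = keep current).
#' @return an object of class `rate_override`.
#' @export
rate_override <- function(node, rate_up = NA_real_, rate_down = NA_real_) {
  if (is.na(rate_up) && is.na(rate_down))
    stop("a rate_override must set at least one rate", call. = FALSE)
  structure(list(node = node, rate_up = rate_up, rate_down = rate_down),
            class = "rate_override")
}

# saturating rate: >= 1e4 x any physiological rate, flips within one step
.BC_HUGE_RATE <- 1e6

#' @rdname rate_override
#' @export
overexpress <- function(node) rate_override(node, rate_up = .BC_HUGE_RATE, rate_down = 0)

#' @rdname rate_override
#' @export
knockout <- function(node) rate_override(node, rate_up = 0, rate_down = .BC_HUGE_RATE)

#' Apply rate overrides to a network
#'
#' Returns a copy of the network with the listed rates replaced; overrides
#' compose left-to-right (the last one naming a node wins).
#'
#' @param net a `boolean_network`.
#' @param overrides a list of [rate_override()] objects (or a single one).
#' @return the modified `boolean_network`.
#' @export
apply_overrides <- function(net, overrides) {
  stopifnot(inherits(net, "boolean_network"))
  if (inherits(overrides, "rate_override")) overrides <- list(overrides)
  for (ov in overrides) {
    i <- net$index[[ov$node]]
    if (is.null(i))
      stop("rate_override names unknown node '", ov$node, "'", call. = FALSE)
    if (!is.na(ov$rate_up)) net$rate_up[i] <- ov$rate_up
    if (!is.na(ov$rate_down)) net$rate_down[i] <- ov$rate_down
  }
  net
}

#' Construct a network state
#'
#' A state is a named integer 0/1 vector aligned with the network's node
#' order.  Unlisted nodes start at 0.
#'
#' @param net a `boolean_network`.
#' @param on character vector of node names active in the state, or a named
#'   numeric/logical vector of node values.
#' @return named integer vector of class `network_state`.
#' @export
network_state <- function(net, on = character(0)) {
  s <- setNames(integer(length(net$nodes)), net$nodes)
  if (length(on)) {
    if (is.character(on)) {
      unknown <- setdiff(on, net$nodes)
      if (length(unknown))
        stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
      s[on] <- 1L
    } else {
      unknown <- setdiff(names(on), net$nodes)
      if (length(unknown))
        stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
      s[names(on)] <- as.integer(as.logical(on))
    }
  }
  class(s) <- "network_state"
  s
}
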