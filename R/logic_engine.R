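# Multi-valued logical networks: expressions, rules, clamping, synchronous
# update and exhaustive fixpoint enumeration. Components carry an integer
# activity level in 0..max_level (max_level 1 = Boolean, 2 = ternary); an
# expression atom "X:k" is true when the level of X is >= k.

## ---- expressions ----------------------------------------------------------

#' Build an expression atom
#'
#' An atom is the elementary proposition of a rule condition: it is true in a
#' state when the referenced component's activity level is at least
#' `threshold`. Thresholds above 1 address the high level of ternary
#' components (written `X:2` in the text format).
#'
#' @param component Component name (single string).
#' @param threshold Positive integer activity threshold (default 1).
#' @return An object of class `lx_expr`.
#' @seealso [lx_not()], [lx_and()], [lx_or()], [parse_expression()]
#' @export
#' @examples
#' lx_atom("NFkB", 2)
lx_atom <- function(component, threshold = 1L) {
  stopifnot(is.character(component), length(component) == 1L, nzchar(component))
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L)
    stop("atom threshold must be a positive integer", call. = FALSE)
  structure(list(type = "atom", comp = component, thr = threshold),
            class = "lx_expr")
}

#' Logical connectives for rule expressions
#'
#' `lx_not`, `lx_and` and `lx_or` combine atoms (or sub-expressions) into the
#' NOT/AND/OR formula tree of a rule condition. Character arguments are parsed
#' with [parse_expression()].
#'
#' @param x,... Sub-expressions (`lx_expr` objects or strings).
#' @return An object of class `lx_expr`.
#' @export
#' @examples
#' lx_and("PI3K | NFkB", lx_not("BCL6"))
lx_not <- function(x) {
  structure(list(type = "not", x = as_lx_expr(x)), class = "lx_expr")
}

#' @rdname lx_not
#' @export
lx_and <- function(...) {
  xs <- lapply(list(...), as_lx_expr)
  if (length(xs) < 2L) stop("AND needs at least two arguments", call. = FALSE)
  structure(list(type = "and", xs = xs), class = "lx_expr")
}

#' @rdname lx_not
#' @export
lx_or <- function(...) {
  xs <- lapply(list(...), as_lx_expr)
  if (length(xs) < 2L) stop("OR needs at least two arguments", call. = FALSE)
  structure(list(type = "or", xs = xs), class = "lx_expr")
}

as_lx_expr <- function(x) {
  if (inherits(x, "lx_expr")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_expression(x))
  stop("not an expression: supply an 'lx_expr' or a single string", call. = FALSE)
}

#' Parse a rule expression from text
#'
#' Grammar: atoms are component names, optionally suffixed `:k` for a level
#' threshold (`X` means level >= 1, `X:2` means level >= 2); operators are
#' `!` (NOT), `&` (AND), `|` (OR) with the usual precedence `!` > `&` > `|`;
#' parentheses group. Component names start with a letter and may contain
#' letters, digits and underscores.
#'
#' @param text A single string, e.g. `"(PI3K | NFkB) & !BCL6"`.
#' @return An object of class `lx_expr`.
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- gsub("[[:space:]]+", "", text)
  if (!nzchar(stripped)) stop("empty expression", call. = FALSE)
  pat <- "[A-Za-z][A-Za-z0-9_]*(:[0-9]+)?|[&|!()]"
  toks <- regmatches(stripped, gregexpr(pat, stripped))[[1]]
  if (paste(toks, collapse = "") != stripped)
    stop("cannot tokenize expression: '", text, "'", call. = FALSE)

  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }

  parse_or <- function() {
    xs <- list(parse_and())
    while (!is.na(peek()) && peek() == "|") { take(); xs <- c(xs, list(parse_and())) }
    if (length(xs) == 1L) xs[[1]] else structure(list(type = "or", xs = xs), class = "lx_expr")
  }
  parse_and <- function() {
    xs <- list(parse_unary())
    while (!is.na(peek()) && peek() == "&") { take(); xs <- c(xs, list(parse_unary())) }
    if (length(xs) == 1L) xs[[1]] else structure(list(type = "and", xs = xs), class = "lx_expr")
  }
  parse_unary <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression in '", text, "'", call. = FALSE)
    if (t == "!") { take(); return(lx_not(parse_unary())) }
    if (t == "(") {
      take()
      e <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop("missing ')' in expression '", text, "'", call. = FALSE)
      take()
      return(e)
    }
    if (t %in% c("&", "|", ")"))
      stop("unexpected '", t, "' in expression '", text, "'", call. = FALSE)
    take()
    if (grepl(":", t, fixed = TRUE)) {
      parts <- strsplit(t, ":", fixed = TRUE)[[1]]
      lx_atom(parts[1], as.integer(parts[2]))
    } else {
      lx_atom(t, 1L)
    }
  }

  e <- parse_or()
  if (!is.na(peek()))
    stop("trailing tokens in expression '", text, "'", call. = FALSE)
  e
}

#' Render an expression in the text-format syntax
#'
#' Produces the canonical text form used by the model-definition file format
#' (and re-parseable by [parse_expression()]).
#'
#' @param expr An `lx_expr`.
#' @return A single string.
#' @export
format_expression <- function(expr) {
  wrap_and_arg <- function(x) {
    s <- format_expression(x)
    if (x$type == "or") paste0("(", s, ")") else s
  }
  switch(expr$type,
    atom = if (expr$thr == 1L) expr$comp else paste0(expr$comp, ":", expr$thr),
    not  = {
      s <- format_expression(expr$x)
      if (expr$x$type %in% c("and", "or")) paste0("!(", s, ")") else paste0("!", s)
    },
    and  = paste(vapply(expr$xs, wrap_and_arg, ""), collapse = " & "),
    or   = paste(vapply(expr$xs, format_expression, ""), collapse = " | "),
    stop("corrupt expression node")
  )
}

#' @export
print.lx_expr <- function(x, ...) {
  cat("<rule expression> ", format_expression(x), "\n", sep = "")
  invisible(x)
}

# components referenced by an expression, with the maximal threshold used
expr_atoms <- function(expr) {
  switch(expr$type,
    atom = stats::setNames(expr$thr, expr$comp),
    not  = expr_atoms(expr$x),
    {
      out <- integer(0)
      for (s in expr$xs) {
        a <- expr_atoms(s)
        for (nm in names(a)) out[nm] <- max(a[nm], if (nm %in% names(out)) out[nm] else 0L)
      }
      out
    }
  )
}

# vectorised evaluation over a state matrix (rows = states, named columns)
lx_eval <- function(expr, M) {
  switch(expr$type,
    atom = M[, expr$comp] >= expr$thr,
    not  = !lx_eval(expr$x, M),
    and  = Reduce(`&`, lapply(expr$xs, lx_eval, M)),
    or   = Reduce(`|`, lapply(expr$xs, lx_eval, M))
  )
}

## ---- level rules and networks ---------------------------------------------

#' Associate a target activity level with a condition
#'
#' A component's behaviour is an ordered list of `(target level, condition)`
#' pairs; at update time the component adopts the highest target level whose
#' condition is satisfied, or 0 when none is. Boolean components have exactly
#' one pair with target level 1; ternary components may define levels 1 and 2
#' separately.
#'
#' @param level Target activity level (positive integer).
#' @param expr Condition (`lx_expr` or string).
#' @return A `level_rule` object.
#' @export
#' @examples
#' level_rule(2, "TRAF6")
level_rule <- function(level, expr) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("target level must be >= 1", call. = FALSE)
  structure(list(level = level, expr = as_lx_expr(expr)), class = "level_rule")
}

#' Construct a multi-valued logical network
#'
#' @param components Data frame with columns `name` (unique identifiers),
#'   `max_level` (1 for Boolean, 2 for ternary) and `input` (logical flag;
#'   inputs have no rule and are held constant by the update).
#' @param rules Named list over the non-input components. Each element is
#'   either a single condition (`lx_expr`/string; target level 1) or a list of
#'   [level_rule()]s with distinct target levels.
#' @param clamps Optional named integer vector fixing components at a level
#'   regardless of their rule (genetic lesions, drugs); see [apply_clamps()].
#' @return An object of class `logical_network`.
#' @details Networks are immutable values: clamping or editing returns a new
#'   network, the original is unchanged.
#' @export
logical_network <- function(components, rules, clamps = NULL) {
  stopifnot(is.data.frame(components),
            all(c("name", "max_level", "input") %in% names(components)))
  nm <- as.character(components$name)
  ml <- as.integer(components$max_level)
  inp <- as.logical(components$input)
  if (anyDuplicated(nm)) stop("component names must be unique", call. = FALSE)
  if (length(nm) && (any(is.na(ml)) || any(!ml %in% 1:2)))
    stop("max_level must be 1 (Boolean) or 2 (ternary)", call. = FALSE)

  max_level <- stats::setNames(ml, nm)
  is_input <- stats::setNames(inp, nm)

  norm_rules <- vector("list", 0L)
  non_inputs <- nm[!inp]
  if (!setequal(names(rules), non_inputs))
    stop("rules must be given for exactly the non-input components; ",
         "missing: ", paste(setdiff(non_inputs, names(rules)), collapse = ", "),
         "; extra: ", paste(setdiff(names(rules), non_inputs), collapse = ", "),
         call. = FALSE)
  for (comp in non_inputs) {
    r <- rules[[comp]]
    if (inherits(r, "level_rule")) r <- list(r)
    if (inherits(r, "lx_expr") || is.character(r)) r <- list(level_rule(1L, r))
    if (!is.list(r) || !all(vapply(r, inherits, TRUE, "level_rule")))
      stop("rule for '", comp, "' must be an expression or a list of level_rule()s",
           call. = FALSE)
    lv <- vapply(r, function(x) x$level, 0L)
    if (anyDuplicated(lv)) stop("duplicate target levels in rule for '", comp, "'",
                                call. = FALSE)
    if (any(lv > max_level[comp]))
      stop("target level exceeds max_level for '", comp, "'", call. = FALSE)
    if (max_level[comp] == 1L && !identical(sort(lv), 1L))
      stop("Boolean component '", comp, "' must have exactly one rule with target level 1",
           call. = FALSE)
    r <- r[order(lv)]  # ascending; update overwrites upward = highest wins
    for (x in r) {
      a <- expr_atoms(x$expr)
      bad <- setdiff(names(a), nm)
      if (length(bad))
        stop("rule for '", comp, "' references unknown component(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      over <- names(a)[a > max_level[names(a)]]
      if (length(over))
        stop("rule for '", comp, "' uses a threshold above max_level of: ",
             paste(over, collapse = ", "), call. = FALSE)
    }
    norm_rules[[comp]] <- r
  }

  net <- structure(list(names = nm, max_level = max_level, is_input = is_input,
                        rules = norm_rules, clamps = integer(0)),
                   class = "logical_network")
  if (!is.null(clamps) && length(clamps)) net <- apply_clamps(net, clamps)
  net
}

#' @export
print.logical_network <- function(x, ...) {
  cat("Logical network: ", length(x$names), " components (",
      sum(x$is_input), " inputs, ", sum(x$max_level == 2L), " ternary)\n", sep = "")
  if (length(x$clamps)) {
    cat("Clamps: ", paste0(names(x$clamps), "=", x$clamps, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.logical_network <- function(object, ...) {
  cat("Logical network with", length(object$names), "components\n")
  for (comp in object$names) {
    if (object$is_input[comp]) {
      cat(sprintf("  %-8s [0..%d] input\n", comp, object$max_level[comp]))
    } else {
      rr <- vapply(object$rules[[comp]],
                   function(r) paste0(r$level, " <- ", format_expression(r$expr)), "")
      cat(sprintf("  %-8s [0..%d] %s\n", comp, object$max_level[comp],
                  paste(rr, collapse = " ; ")))
    }
    if (comp %in% names(object$clamps))
      cat(sprintf("  %-8s        clamped at %d\n", "", object$clamps[comp]))
  }
  invisible(object)
}

#' Component names of a network
#' @param network A `logical_network`.
#' @return Character vector in network order.
#' @export
component_names <- function(network) network$names

#' Build a state vector for a network
#'
#' @param network A `logical_network`.
#' @param ... Named levels overriding the all-zero default.
#' @return Named integer vector ordered as the network's components.
#' @export
#' @examples
#' network_state(gc_network(), BCR = 1, CD40 = 1)
network_state <- function(network, ...) {
  s <- stats::setNames(integer(length(network$names)), network$names)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), network$names)
    if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    s[names(ov)] <- as.integer(ov)
  }
  check_state(network, s)
  s
}

check_state <- function(network, state) {
  if (!all(network$names %in% names(state)))
    stop("state is missing component(s): ",
         paste(setdiff(network$names, names(state)), collapse = ", "), call. = FALSE)
  lv <- state[network$names]
  if (any(lv < 0L) || any(lv > network$max_level))
    stop("state level out of 0..max_level range", call. = FALSE)
  invisible(TRUE)
}

as_state_matrix <- function(state) {
  matrix(as.integer(state), nrow = 1L, dimnames = list(NULL, names(state)))
}

## ---- update semantics ------------------------------------------------------

#' Evaluate a rule condition in a state
#'
#' @param expr Condition (`lx_expr` or string).
#' @param state Named integer state vector.
#' @return `TRUE`/`FALSE`: the formula's truth value with atoms read as
#'   "activity >= threshold".
#' @export
#' @examples
#' evaluate_expression("(PI3K | NFkB) & !BCL6",
#'                     c(PI3K = 1, NFkB = 0, BCL6 = 1))
evaluate_expression <- function(expr, state) {
  expr <- as_lx_expr(expr)
  a <- expr_atoms(expr)
  bad <- setdiff(names(a), names(state))
  if (length(bad))
    stop("expression references component(s) absent from the state: ",
         paste(bad, collapse = ", "), call. = FALSE)
  as.logical(lx_eval(expr, as_state_matrix(state)))
}

#' Target activity level of one component
#'
#' Clamped components return their clamp level; unclamped inputs return their
#' current level (inputs are held constant); otherwise the highest target
#' level whose condition holds in `state`, or 0 when none holds.
#'
#' @param network A `logical_network`.
#' @param component Component name.
#' @param state Named integer state vector.
#' @return Integer level.
#' @export
target_level <- function(network, component, state) {
  if (!component %in% network$names)
    stop("unknown component '", component, "'", call. = FALSE)
  check_state(network, state)
  if (component %in% names(network$clamps))
    return(unname(network$clamps[component]))
  if (network$is_input[component]) return(unname(as.integer(state[component])))
  lv <- 0L
  for (r in network$rules[[component]]) {
    if (evaluate_expression(r$expr, state)) lv <- r$level
  }
  lv
}

# next levels for every component over a state matrix (vectorised core)
next_levels <- function(network, M) {
  out <- M
  cl <- network$clamps
  for (comp in network$names) {
    if (comp %in% names(cl)) {
      out[, comp] <- cl[comp]
    } else if (network$is_input[comp]) {
      # inputs are the environment: held at their current level
    } else {
      lv <- integer(nrow(M))
      for (r in network$rules[[comp]]) {   # ascending levels: highest wins
        lv[lx_eval(r$expr, M)] <- r$level
      }
      out[, comp] <- lv
    }
  }
  out
}

#' Synchronous update step
#'
#' Simultaneously sets every component to its [target_level()].
#'
#' @param network A `logical_network`.
#' @param state Named integer state vector.
#' @return The successor state vector.
#' @export
synchronous_step <- function(network, state) {
  check_state(network, state)
  M <- as_state_matrix(state[network$names])
  stats::setNames(as.integer(next_levels(network, M)[1L, ]), network$names)
}

#' Is a state a fixpoint?
#'
#' `TRUE` iff the synchronous update maps the state to itself. Fixpoints are
#' invariant across update schemes, so they are the attractors reported by
#' this package regardless of scheduling.
#'
#' @param network A `logical_network`.
#' @param state Named integer state vector.
#' @return Logical flag.
#' @export
is_fixpoint <- function(network, state) {
  if (length(network$names) == 0L) return(TRUE)
  s <- state[network$names]
  identical(as.integer(synchronous_step(network, s)), as.integer(s))
}

## ---- fixpoint enumeration --------------------------------------------------

# mixed-radix grid scan shared by enumerate_fixpoints()/all_fixpoints():
# fixed = named levels held constant, free = components scanned over 0..max
scan_fixpoints <- function(network, fixed, chunk_size = 2L^18L) {
  nm <- network$names
  free <- setdiff(nm, names(fixed))
  sizes <- network$max_level[free] + 1L
  n_states <- prod(as.double(sizes))
  if (n_states > 2^26)
    stop("state space too large to scan exhaustively (", n_states,
         " states); clamp or assign more components", call. = FALSE)

  # place value of each free component: later components vary fastest, so the
  # scan emits states in lexicographic order of the full state vector
  k <- length(free)
  place <- rev(cumprod(rev(c(as.double(sizes)[-1L], 1))))

  hits <- list()
  start <- 0
  while (start < n_states) {
    idx <- start + seq_len(min(chunk_size, n_states - start)) - 1
    M <- matrix(0L, nrow = length(idx), ncol = length(nm),
                dimnames = list(NULL, nm))
    for (comp in names(fixed)) M[, comp] <- fixed[comp]
    if (k) for (j in seq_len(k)) {
      M[, free[j]] <- as.integer((idx %/% place[j]) %% sizes[j])
    }
    nxt <- next_levels(network, M)
    ok <- rowSums(nxt != M) == 0L
    if (any(ok)) hits[[length(hits) + 1L]] <- M[ok, , drop = FALSE]
    start <- start + length(idx)
  }
  if (length(hits)) do.call(rbind, hits)
  else matrix(integer(0), nrow = 0L, ncol = length(nm), dimnames = list(NULL, nm))
}

#' Enumerate all fixpoints under an input assignment
#'
#' Exhaustively scans every state consistent with the input assignment and
#' the network's clamps and returns those mapped to themselves by the
#' synchronous update, in lexicographic order of the state vector.
#'
#' @param network A `logical_network`.
#' @param inputs Named integer vector assigning a level to every unclamped
#'   input (the environment the fixpoints are conditioned on). May be omitted
#'   when the network has no unclamped inputs.
#' @param chunk_size States scanned per block (memory/speed trade-off).
#' @return Integer matrix, one row per fixpoint, columns the components.
#' @export
#' @examples
#' fp <- enumerate_fixpoints(gc_network(), c(BCR = 1, CD40 = 1, IL21_4 = 1))
enumerate_fixpoints <- function(network, inputs = NULL, chunk_size = 2L^18L) {
  nm <- network$names
  cl <- network$clamps
  input_comps <- nm[network$is_input]
  unclamped_inputs <- setdiff(input_comps, names(cl))

  inputs <- if (is.null(inputs)) integer(0) else {
    bad <- setdiff(names(inputs), input_comps)
    if (length(bad))
      stop("not input component(s): ", paste(bad, collapse = ", "), call. = FALSE)
    stats::setNames(as.integer(inputs), names(inputs))
  }
  missing <- setdiff(unclamped_inputs, names(inputs))
  if (length(missing))
    stop("input assignment missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  both <- intersect(names(inputs), names(cl))
  if (any(inputs[both] != cl[both]))
    stop("input assignment conflicts with clamp on: ",
         paste(both[inputs[both] != cl[both]], collapse = ", "), call. = FALSE)
  if (any(inputs < 0L | inputs > network$max_level[names(inputs)]))
    stop("input level out of range", call. = FALSE)

  fixed <- c(cl, inputs[setdiff(names(inputs), names(cl))])
  scan_fixpoints(network, fixed, chunk_size)
}

#' Enumerate fixpoints over the full state space
#'
#' Scans input combinations as well: inputs are held constant by the update,
#' so this returns the union of [enumerate_fixpoints()] over every input
#' assignment. Used as the whole-space brute-force view of a model.
#'
#' @inheritParams enumerate_fixpoints
#' @return Integer matrix, one row per fixpoint.
#' @export
all_fixpoints <- function(network, chunk_size = 2L^18L) {
  scan_fixpoints(network, network$clamps, chunk_size)
}

## ---- clamping --------------------------------------------------------------

#' Clamp components at fixed levels
#'
#' Clamping replaces a component's rule with a constant: the component holds
#' the clamp level in every state, which is how genetic lesions (gain or loss
#' of function) and drug inhibition enter a model. Returns a new network;
#' later clamps on the same component replace earlier ones.
#'
#' @param network A `logical_network`.
#' @param clamps Named integer vector, component -> level.
#' @return A new `logical_network` with the clamps merged in.
#' @export
#' @examples
#' erk_ect <- apply_clamps(gc_network(), c(ERK = 1))
apply_clamps <- function(network, clamps) {
  if (length(clamps) == 0L) return(network)
  lv <- stats::setNames(as.integer(clamps), names(clamps))
  if (is.null(names(clamps)) || any(!nzchar(names(clamps))))
    stop("clamps must be named by component", call. = FALSE)
  bad <- setdiff(names(lv), network$names)
  if (length(bad))
    stop("clamp on unknown component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(is.na(lv)) || any(lv < 0L) || any(lv > network$max_level[names(lv)]))
    stop("clamp level outside 0..max_level for: ",
         paste(names(lv)[is.na(lv) | lv < 0L | lv > network$max_level[names(lv)]],
               collapse = ", "), call. = FALSE)
  merged <- network$clamps
  for (comp in names(lv)) merged[comp] <- lv[comp]  # later clamps win
  network$clamps <- merged[order(match(names(merged), network$names))]
  network
}

## ---- model-definition text format ------------------------------------------

#' Read a logical-network definition file
#'
#' One line per component, `name : max_level : spec` with an optional fourth
#' field `clamp=<level>`. `spec` is either the word `input` or one or more
#' `level <- expression` clauses separated by `;`, expressions in the
#' [parse_expression()] syntax. Blank lines and `#` comments are ignored.
#'
#' @param path File path, or `NULL` when `text` is given.
#' @param text Optional character vector of lines (instead of a file).
#' @return A `logical_network`.
#' @seealso [write_model()] for the byte-stable writer.
#' @export
read_model <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  raw <- lines
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  lines <- lines[keep]
  lineno <- seq_along(raw)[keep]

  nm <- character(0); ml <- integer(0); inp <- logical(0)
  rule_spec <- list(); clamp <- integer(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
    # rejoin "level <- X:2 ; ..." pieces: the first two fields are name and
    # max_level, everything after the second ':' belongs to the rule spec,
    # except a trailing 'clamp=<level>' field
    if (length(parts) < 3L)
      stop("line ", lineno[i], ": expected 'name : max_level : spec'", call. = FALSE)
    name <- trimws(parts[1])
    lvl <- suppressWarnings(as.integer(trimws(parts[2])))
    rest <- paste(parts[-(1:2)], collapse = ":")
    clamp_lv <- NA_integer_
    m <- regmatches(rest, regexec("[[:space:]]*:?[[:space:]]*clamp=([0-9]+)[[:space:]]*$", rest))[[1]]
    if (length(m)) {
      clamp_lv <- as.integer(m[2])
      rest <- sub("[[:space:]]*:?[[:space:]]*clamp=[0-9]+[[:space:]]*$", "", rest)
    }
    rest <- trimws(rest)
    if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", name))
      stop("line ", lineno[i], ": bad component name '", name, "'", call. = FALSE)
    if (is.na(lvl)) stop("line ", lineno[i], ": bad max_level", call. = FALSE)
    nm <- c(nm, name); ml <- c(ml, lvl)
    if (identical(rest, "input")) {
      inp <- c(inp, TRUE)
    } else {
      inp <- c(inp, FALSE)
      clauses <- strsplit(rest, ";", fixed = TRUE)[[1]]
      rl <- lapply(clauses, function(cl) {
        mm <- regmatches(cl, regexec("^[[:space:]]*([0-9]+)[[:space:]]*<-(.*)$", cl))[[1]]
        if (!length(mm))
          stop("line ", lineno[i], ": expected 'level <- expression' clause",
               call. = FALSE)
        level_rule(as.integer(mm[2]), parse_expression(mm[3]))
      })
      rule_spec[[name]] <- rl
    }
    if (!is.na(clamp_lv)) clamp[name] <- clamp_lv
  }
  logical_network(data.frame(name = nm, max_level = ml, input = inp,
                             stringsAsFactors = FALSE),
                  rule_spec, clamps = clamp)
}

#' Write a logical-network definition file
#'
#' Byte-stable: components in network order, canonical expression formatting,
#' so write/read/write round-trips are identical.
#'
#' @param network A `logical_network`.
#' @param path Output file path; when `NULL` the lines are returned instead.
#' @return Invisibly (or visibly for `path = NULL`), the character lines.
#' @export
write_model <- function(network, path = NULL) {
  lines <- vapply(network$names, function(comp) {
    spec <- if (network$is_input[comp]) "input" else {
      paste(vapply(network$rules[[comp]],
                   function(r) paste0(r$level, " <- ", format_expression(r$expr)), ""),
            collapse = " ; ")
    }
    ln <- paste0(comp, " : ", network$max_level[comp], " : ", spec)
    if (comp %in% names(network$clamps))
      ln <- paste0(ln, " : clamp=", network$clamps[comp])
    ln
  }, "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
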