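# Independent oracles for fixpoint enumeration.
#
# oracle A ("truth table"): translates every rule into base-R source and
# evaluates it with R's own parser/evaluator over all regulator-level
# combinations, then computes transitions by table lookup. Shares no code
# with the package's expression interpreter.
#
# oracle B ("literal"): loops over every consistent state and tests
# is_fixpoint() one state at a time; used on small networks.

# translate an lx_expr tree to base-R source over a named list `s`
expr_to_r_source <- function(expr) {
  switch(expr$type,
    atom = sprintf('(s[["%s"]] >= %d)', expr$comp, expr$thr),
    not  = paste0("(!", expr_to_r_source(expr$x), ")"),
    and  = paste0("(", paste(vapply(expr$xs, expr_to_r_source, ""),
                             collapse = " & "), ")"),
    or   = paste0("(", paste(vapply(expr$xs, expr_to_r_source, ""),
                             collapse = " | "), ")"))
}

# per-component lookup tables: target level indexed by regulator levels
oracle_tables <- function(net) {
  tabs <- list()
  for (comp in net$names) {
    if (net$is_input[comp] || comp %in% names(net$clamps)) next
    rules <- net$rules[[comp]]
    regs <- unique(unlist(lapply(rules, function(r)
      names(gclogic:::expr_atoms(r$expr)))))
    grid <- if (length(regs)) {
      expand.grid(lapply(net$max_level[regs], function(m) 0:m),
                  KEEP.OUT.ATTRS = FALSE)
    } else data.frame(row.names = 1)
    names(grid) <- regs
    target <- integer(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      s <- as.list(grid[i, , drop = FALSE])
      for (r in rules) {   # rules are stored ascending: highest wins
        if (eval(parse(text = expr_to_r_source(r$expr)), list(s = s)))
          target[i] <- r$level
      }
    }
    sizes <- net$max_level[regs] + 1L
    place <- if (length(regs)) cumprod(c(1L, sizes[-length(sizes)])) else integer(0)
    tabs[[comp]] <- list(regs = regs, place = place, target = target)
  }
  tabs
}

oracle_next <- function(net, M, tabs) {
  out <- M
  for (comp in net$names) {
    if (comp %in% names(net$clamps)) {
      out[, comp] <- net$clamps[comp]
    } else if (net$is_input[comp]) {
      # held constant
    } else {
      tb <- tabs[[comp]]
      idx <- rep(1L, nrow(M))
      for (j in seq_along(tb$regs))
        idx <- idx + M[, tb$regs[j]] * tb$place[j]
      out[, comp] <- tb$target[idx]
    }
  }
  out
}

# all fixpoints consistent with `fixed` (clamps + input assignment), by
# truth-table transition over the full grid
oracle_fixpoints <- function(net, inputs = NULL) {
  fixed <- net$clamps
  if (!is.null(inputs)) fixed <- c(fixed, inputs[setdiff(names(inputs), names(fixed))])
  free <- setdiff(net$names, names(fixed))
  grid <- expand.grid(lapply(net$max_level[free], function(m) 0:m),
                      KEEP.OUT.ATTRS = FALSE)
  M <- matrix(0L, nrow = max(nrow(grid), 1L), ncol = length(net$names),
              dimnames = list(NULL, net$names))
  for (comp in names(fixed)) M[, comp] <- fixed[comp]
  for (comp in free) M[, comp] <- grid[[comp]]
  tabs <- oracle_tables(net)
  ok <- rowSums(oracle_next(net, M, tabs) != M) == 0L
  sort_states(M[ok, , drop = FALSE])
}

# literal per-state is_fixpoint() loop (small networks only)
literal_fixpoints <- function(net, inputs = NULL) {
  fixed <- net$clamps
  if (!is.null(inputs)) fixed <- c(fixed, inputs[setdiff(names(inputs), names(fixed))])
  free <- setdiff(net$names, names(fixed))
  grid <- expand.grid(lapply(net$max_level[free], function(m) 0:m),
                      KEEP.OUT.ATTRS = FALSE)
  hits <- list()
  for (i in seq_len(max(nrow(grid), 1L))) {
    s <- stats::setNames(integer(length(net$names)), net$names)
    for (comp in names(fixed)) s[comp] <- fixed[comp]
    for (comp in free) s[comp] <- grid[[comp]][i]
    if (is_fixpoint(net, s)) hits[[length(hits) + 1L]] <- s
  }
  if (length(hits)) sort_states(do.call(rbind, hits))
  else matrix(integer(0), 0L, length(net$names), dimnames = list(NULL, net$names))
}

# canonical row order so fixpoint sets can be compared as sets
sort_states <- function(M) {
  if (nrow(M) < 2L) return(M)
  M[do.call(order, as.data.frame(M)), , drop = FALSE]
}

# random Boolean/ternary network for property tests
random_network <- function(n = 6L, n_inputs = 2L) {
  nm <- paste0("C", seq_len(n))
  ml <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  inp <- seq_len(n) <= n_inputs
  random_expr <- function() {
    k <- sample(1:3, 1)
    atoms <- lapply(sample(nm, k, replace = TRUE), function(cc) {
      a <- lx_atom(cc, sample.int(ml[match(cc, nm)], 1))
      if (stats::runif(1) < 0.4) lx_not(a) else a
    })
    if (k == 1) atoms[[1]]
    else if (stats::runif(1) < 0.5) do.call(lx_and, atoms)
    else do.call(lx_or, atoms)
  }
  rules <- list()
  for (i in which(!inp)) {
    rl <- list(level_rule(1L, random_expr()))
    if (ml[i] == 2L && stats::runif(1) < 0.8)
      rl <- c(rl, list(level_rule(2L, random_expr())))
    rules[[nm[i]]] <- rl
  }
  logical_network(data.frame(name = nm, max_level = ml, input = inp),
                  rules)
}

# random clamp set on the GC model
random_gc_clamps <- function(net, max_size = 4L) {
  k <- sample.int(max_size, 1)
  comps <- sample(net$names, k)
  stats::setNames(
    vapply(comps, function(cc) sample.int(net$max_level[cc] + 1L, 1) - 1L, 0L),
    comps)
}

# marker pattern of a named stage in a profile
stage_pattern <- function(profile, stage_name) {
  for (rec in profile$stages)
    if (rec$stage_name == stage_name)
      return(if (rec$lost) "lost" else paste(sort(rec$patterns), collapse = " / "))
  stop("no stage ", stage_name)
}

fixture_model <- function(pid) {
  patient_model(genotype_to_perturbations(fixture_patients(), patient_id = pid))
}
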