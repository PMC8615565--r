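test_that("expression evaluation follows the thresholded-atom semantics", {
  expect_true(evaluate_expression("BCR", c(BCR = 1)))
  expect_false(evaluate_expression("BCR", c(BCR = 0)))
  # the BCL2 rule: survival input present but BCL6 represses
  expect_false(evaluate_expression("(PI3K | NFkB) & !BCL6",
                                   c(PI3K = 1, NFkB = 0, BCL6 = 1)))
  expect_true(evaluate_expression("(PI3K | NFkB) & !BCL6",
                                  c(PI3K = 0, NFkB = 2, BCL6 = 0)))
  # tautology holds in every state
  for (a in 0:1)
    expect_true(evaluate_expression("!A | A", c(A = a)))
  # threshold atoms distinguish ternary levels
  expect_false(evaluate_expression("X:2", c(X = 1)))
  expect_true(evaluate_expression("X:2", c(X = 2)))
  expect_error(evaluate_expression("Q & B", c(B = 1)), "absent")
})

test_that("expression parser and formatter round-trip with correct precedence", {
  cases <- c("A & B | C", "!(A | B) & C:2", "A & !B & C", "!A", "(A | B) & (C | D)")
  for (src in cases) {
    e <- parse_expression(src)
    expect_identical(format_expression(parse_expression(format_expression(e))),
                     format_expression(e))
  }
  # precedence: NOT > AND > OR
  e <- parse_expression("!A & B | C")
  expect_identical(e$type, "or")
  expect_error(parse_expression("A &"), "unexpected")
  expect_error(parse_expression("(A"), "missing")
  expect_error(parse_expression(""), "empty")
})

test_that("target_level picks the highest satisfied level and respects clamps", {
  net <- gc_network()
  s <- network_state(net, CBM = 1, TRAF6 = 1)
  expect_identical(target_level(net, "IKKc", s), 2L)
  expect_identical(target_level(net, "IKKc", network_state(net, CBM = 1)), 1L)
  expect_identical(target_level(net, "IKKc", network_state(net)), 0L)
  clamped <- apply_clamps(net, c(IKKc = 0))
  expect_identical(target_level(clamped, "IKKc", s), 0L)
  # unclamped inputs hold their level
  expect_identical(target_level(net, "BCR", network_state(net, BCR = 1)), 1L)
})

test_that("synchronous step updates all components simultaneously", {
  net <- gc_network()
  s0 <- network_state(net, BCR = 1)
  s1 <- synchronous_step(net, s0)
  expect_identical(unname(s1[c("SYK", "BTK")]), c(1L, 1L))
  expect_identical(unname(s1["PI3K"]), 0L)  # SYK/BTK were still 0 when read
  # a fixpoint maps to itself
  fp <- enumerate_fixpoints(net, c(BCR = 0, CD40 = 0, IL21_4 = 0))
  expect_identical(synchronous_step(net, fp[1L, ]), fp[1L, ])
  # single-edge chain under a clamp
  chain <- logical_network(
    data.frame(name = c("A", "B"), max_level = 1L, input = c(TRUE, FALSE)),
    list(B = "A"), clamps = c(A = 1))
  expect_identical(unname(synchronous_step(chain, c(A = 1L, B = 0L))["B"]), 1L)
})

test_that("is_fixpoint matches the definition, including degenerate networks", {
  net <- gc_network()
  expect_true(is_fixpoint(net, network_state(net)))           # resting LZ1 state
  expect_false(is_fixpoint(net, network_state(net, MYC = 1))) # MYC decays
  empty <- logical_network(
    data.frame(name = character(0), max_level = integer(0), input = logical(0)),
    list())
  expect_true(is_fixpoint(empty, stats::setNames(integer(0), character(0))))
})

test_that("a pure negative self-loop has no fixpoint", {
  osc <- logical_network(
    data.frame(name = "A", max_level = 1L, input = FALSE),
    list(A = "!A"))
  expect_identical(nrow(enumerate_fixpoints(osc)), 0L)
})

test_that("enumeration requires a complete input assignment", {
  net <- gc_network()
  expect_error(enumerate_fixpoints(net, c(BCR = 1)), "missing")
  expect_error(enumerate_fixpoints(net, c(BCR = 1, CD40 = 0, IL21_4 = 0, MYC = 1)),
               "not input")
  clamped <- apply_clamps(net, c(BCR = 1))
  expect_error(enumerate_fixpoints(clamped, c(BCR = 0, CD40 = 0, IL21_4 = 0)),
               "conflicts")
  # clamped inputs need no assignment
  expect_silent(enumerate_fixpoints(clamped, c(CD40 = 0, IL21_4 = 0)))
})

test_that("fixpoints are returned in lexicographic order with in-range levels", {
  net <- gc_network()
  fp <- all_fixpoints(net)
  expect_identical(fp, sort_states(fp))
  expect_true(all(fp >= 0L))
  expect_true(all(t(fp) <= net$max_level))
})

test_that("clamping is idempotent, replacing, and leaves the original untouched", {
  net <- gc_network()
  c1 <- apply_clamps(net, c(ERK = 1))
  expect_identical(apply_clamps(c1, c(ERK = 1)), c1)
  # later clamps on the same component replace earlier ones
  c2 <- apply_clamps(c1, c(ERK = 0))
  expect_identical(unname(c2$clamps["ERK"]), 0L)
  # original network is an unchanged value
  expect_identical(length(net$clamps), 0L)
  expect_identical(apply_clamps(net, integer(0)), net)
  expect_error(apply_clamps(net, c(ERK = 2)), "max_level")
  expect_error(apply_clamps(net, c(NOPE = 1)), "unknown")
})

test_that("enumeration agrees with a literal per-state is_fixpoint scan", {
  set.seed(901)
  for (rep in 1:12) {
    net <- random_network(n = 6L, n_inputs = 2L)
    inputs <- stats::setNames(
      vapply(net$names[net$is_input],
             function(cc) sample.int(net$max_level[cc] + 1L, 1) - 1L, 0L),
      net$names[net$is_input])
    if (rep %% 3 == 0) {
      cl <- random_gc_clamps(net, 2L)
      net <- apply_clamps(net, cl)
      inputs <- inputs[setdiff(names(inputs), names(cl))]
    }
    got <- enumerate_fixpoints(net, inputs)
    want <- literal_fixpoints(net, inputs)
    expect_identical(sort_states(got), want)
  }
})

test_that("fixpoints are invariant to component ordering", {
  lines <- write_model(gc_network())
  set.seed(77)
  perm <- sample(lines)
  net_perm <- read_model(text = perm)
  fp1 <- enumerate_fixpoints(gc_network(), c(BCR = 1, CD40 = 1, IL21_4 = 1))
  fp2 <- enumerate_fixpoints(net_perm, c(BCR = 1, CD40 = 1, IL21_4 = 1))
  expect_identical(fp1[, sort(colnames(fp1)), drop = FALSE],
                   fp2[, sort(colnames(fp2)), drop = FALSE])
})

test_that("model files round-trip byte-stably, including clamps", {
  net <- apply_clamps(gc_network(), c(ERK = 1, NFkB = 2))
  lines1 <- write_model(net)
  net2 <- read_model(text = lines1)
  expect_identical(write_model(net2), lines1)
  expect_identical(net2$clamps, net$clamps)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(net, path)
  expect_identical(write_model(read_model(path)), lines1)
  expect_error(read_model(text = "A : 1"), "expected")
  expect_error(read_model(text = "A : 1 : 1 <- B"), "unknown component")
})

test_that("network construction rejects malformed definitions", {
  comps <- data.frame(name = c("A", "B"), max_level = 1L, input = c(TRUE, FALSE))
  expect_error(logical_network(comps, list()), "exactly the non-input")
  expect_error(logical_network(comps, list(B = "A:2")), "threshold above")
  expect_error(
    logical_network(data.frame(name = c("A", "A"), max_level = 1L,
                               input = c(TRUE, FALSE)),
                    list(A = "A")), "unique")
  expect_error(
    logical_network(data.frame(name = c("A", "B"), max_level = c(1L, 3L),
                               input = c(TRUE, FALSE)),
                    list(B = "A")), "max_level")
  expect_error(
    logical_network(comps, list(B = list(level_rule(1, "A"), level_rule(1, "!A")))),
    "duplicate")
})
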