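test_that("merging networks keeps the union of unique signed interactions", {
  n1 <- signed_network(data.frame(source = "A", target = "B", sign = 1))
  n2 <- signed_network(data.frame(source = c("A", "B"), target = c("B", "C"),
                                  sign = c(1, -1)))
  m <- merge_networks(list(n1, n2))
  expect_setequal(m$nodes, c("A", "B", "C"))
  expect_equal(nrow(m$edges), 2)

  # opposite signs on the same pair stay as two distinct interactions
  n3 <- signed_network(data.frame(source = "A", target = "B", sign = -1))
  m2 <- merge_networks(list(n1, n3))
  expect_equal(length(m2$nodes), 2)
  expect_equal(nrow(m2$edges), 2)
  expect_setequal(m2$edges$sign, c(1, -1))
})

test_that("gate enumeration picks the first feasible gate deterministically", {
  # constraints: (A=1, I=0 => Y=1) and (A=0, I=0 => Y=0)
  net <- signed_network(data.frame(source = c("A", "I"), target = "Y",
                                   sign = c(1, -1)))
  profiles <- list(p1 = c(A = 1L, I = 0L, Y = 1L),
                   p2 = c(A = 0L, I = 0L, Y = 0L))
  syn <- synthesize_rules(net, profiles)
  expect_equal(syn$model$rules$Y$text, "A & !I")
  expect_true(all(syn$report$feasible))
  # deterministic: same inputs, same canonical text
  syn2 <- synthesize_rules(net, profiles)
  expect_identical(vapply(syn$model$rules, `[[`, "", "text"),
                   vapply(syn2$model$rules, `[[`, "", "text"))
})

test_that("contradictory fixed-point constraints are reported infeasible", {
  net <- signed_network(data.frame(source = c("A", "I"), target = "Y",
                                   sign = c(1, -1)))
  profiles <- list(p1 = c(A = 1L, I = 1L, Y = 1L),
                   p2 = c(A = 1L, I = 1L, Y = 0L))
  syn <- synthesize_rules(net, profiles)
  row <- syn$report[syn$report$node == "Y", ]
  expect_false(row$feasible)
  expect_equal(row$method, "infeasible")
  # the only distinct gate (A & !I) satisfies exactly one profile
  expect_equal(row$n_satisfied, 1)

  # with tied gate counts, the gate satisfying the earlier profile wins:
  # constraints (1,0)=>1, (0,1)=>0, (1,1)=>0 are monotone-infeasible; the
  # OR gate satisfies only p1, the AND gate only p2, so OR is chosen
  net2 <- signed_network(data.frame(source = c("A", "B"), target = "Y",
                                    sign = c(1, 1)))
  profs2 <- list(p1 = c(A = 1L, B = 0L, Y = 1L),
                 p2 = c(A = 0L, B = 1L, Y = 0L),
                 p3 = c(A = 1L, B = 1L, Y = 0L))
  syn2 <- synthesize_rules(net2, profs2)
  row2 <- syn2$report[syn2$report$node == "Y", ]
  expect_false(row2$feasible)
  expect_equal(row2$n_satisfied, 1)
  expect_equal(row2$satisfied, "p1")
  expect_equal(syn2$model$rules$Y$text, "(A | B)")
})

test_that("truth-table fallback finds the minimal sign-monotone rule", {
  # XOR-like demands cannot be met by the four simple gates but the
  # constraints below can: Y on iff exactly A (not B) among two activators
  net <- signed_network(data.frame(source = c("A", "B"), target = "Y",
                                   sign = c(1, 1)))
  profiles <- list(p1 = c(A = 1L, B = 0L, Y = 1L),
                   p2 = c(A = 0L, B = 1L, Y = 0L),
                   p3 = c(A = 0L, B = 0L, Y = 0L))
  syn <- synthesize_rules(net, profiles)
  row <- syn$report[syn$report$node == "Y", ]
  expect_true(row$feasible)
  expect_equal(row$method, "table")
  r <- syn$model$rules$Y
  # minimal monotone closure: ON exactly on patterns dominating (A=1,B=0)
  expect_equal(eval_rule_for_test(r, c(A = 1L, B = 0L)), 1L)
  expect_equal(eval_rule_for_test(r, c(A = 1L, B = 1L)), 1L)
  expect_equal(eval_rule_for_test(r, c(A = 0L, B = 1L)), 0L)
  expect_equal(eval_rule_for_test(r, c(A = 0L, B = 0L)), 0L)
})

test_that("profiles with missing nodes are filled with OFF and flagged", {
  net <- signed_network(data.frame(source = "A", target = "Y", sign = 1))
  syn <- synthesize_rules(net, list(p1 = c(A = 0L)))  # Y missing
  expect_true(any(grepl("Y", syn$filled)))
})

test_that("synchronous steady state handles constants, toggles and cycles", {
  # all-constant rules reach their constants in one step
  m <- boolean_model(list(A = const_rule("A", 1), B = const_rule("B", 0)))
  att <- steady_state(m, c(A = 0L, B = 1L))
  expect_equal(att$type, "fixed")
  expect_equal(att$state, c(A = 1L, B = 0L))

  # toggle from (1,0) stays at (1,0)
  att <- steady_state(toggle_model(), c(X = 1L, Y = 0L))
  expect_equal(att$type, "fixed")
  expect_equal(att$state, c(X = 1L, Y = 0L))

  # X = Y, Y = !X from (0,0): period-4 rotation, verified by enumeration
  m <- boolean_model(list(X = boolean_rule("X", activators = "Y"),
                          Y = boolean_rule("Y", inhibitors = "X")))
  att <- steady_state(m, c(X = 0L, Y = 0L))
  expect_equal(att$type, "cycle")
  expect_equal(att$period, 4L)
  succ <- oracle_successors(m)
  expect_equal(sort(apply(att$states, 1, oracle_index_of_state, nodes = m$nodes)),
               oracle_attractor_from(succ, oracle_index_of_state(c(X = 0L, Y = 0L),
                                                                 m$nodes)))

  # exceeding max_steps without an attractor is an explicit error
  expect_error(steady_state(m, c(X = 0L, Y = 0L), max_steps = 2),
               "max_steps")
})

test_that("asynchronous simulation absorbs into the synchronous fixed points", {
  gt <- generate_ground_truth_model(8, 3, seed = 11)
  for (s in names(gt$profiles)) {
    att <- steady_state(gt$model, gt$profiles[[s]], mode = "async_gillespie",
                        seed = 5, max_steps = 500)
    expect_equal(att$type, "fixed")
    expect_equal(att$state, gt$profiles[[s]])
  }
  # a non-steady start still yields an empirical distribution
  init <- gt$profiles[[1]]
  init[] <- 1L
  att <- steady_state(gt$model, init, mode = "async_gillespie", seed = 5,
                      max_steps = 300)
  expect_true(att$type %in% c("fixed", "distribution"))
})

test_that("cross-state similarity has unit diagonal and exact complements", {
  gt <- generate_ground_truth_model(10, 4, seed = 3)
  sim <- cross_state_similarity(gt$model, gt$profiles)
  expect_equal(unname(diag(sim)), rep(1, 4))
  expect_true(all(sim >= 0 & sim <= 1))

  # steady state from a constant model vs its complementary profile
  m <- boolean_model(list(A = const_rule("A", 1), B = const_rule("B", 1)))
  profs <- list(p1 = c(A = 1L, B = 1L), p2 = c(A = 0L, B = 0L))
  sim2 <- cross_state_similarity(m, profs)
  expect_equal(sim2["p1", "p2"], 0)
  expect_equal(sim2["p1", "p1"], 1)
})

test_that("cross-state similarity asymmetry matches the exhaustive oracle", {
  for (seed in 1:5) {
    gt <- generate_ground_truth_model(9, 4, seed = seed)
    sim <- cross_state_similarity(gt$model, gt$profiles)
    succ <- oracle_successors(gt$model)
    n <- length(gt$model$nodes)
    for (i in names(gt$profiles)) {
      idx <- oracle_index_of_state(gt$profiles[[i]], gt$model$nodes)
      attr_set <- oracle_attractor_from(succ, idx)
      expect_length(attr_set, 1)  # planted profiles are fixed points
      s <- oracle_state_from_index(attr_set, gt$model$nodes)
      for (j in names(gt$profiles)) {
        expect_equal(sim[i, j], 1 - sum(s != gt$profiles[[j]]) / n)
      }
    }
  }
})

test_that("knockout contract rejects OFF and already-clamped nodes", {
  gt <- generate_ground_truth_model(8, 4, seed = 2)
  base <- steady_state(gt$model, gt$profiles$MES)$state
  off <- gt$model$nodes[base == 0][1]
  expect_error(knockout(gt$model, base, off), "OFF")
  on <- gt$model$nodes[base == 1][1]
  expect_error(knockout(gt$model, base, on,
                        clamps = stats::setNames(1L, on)), "clamped")
})

test_that("knockout of a node without outgoing edges only clears itself", {
  ci <- constructed_instance()
  base <- steady_state(ci$model, ci$profiles$NPC)$state
  # G has no outgoing edges; its KO changes nothing downstream
  att <- knockout(ci$model, base, "G")
  expect_equal(att$type, "fixed")
  expected <- base; expected[["G"]] <- 0L
  expect_equal(att$state, expected)
})

test_that("knockout screen statistics satisfy their identities", {
  gt <- generate_ground_truth_model(14, 4, seed = 7)
  scr <- knockout_screen(gt$model, gt$profiles)
  tab <- scr$table
  n <- length(gt$model$nodes)
  states <- scr$states

  # row count = sum over start states of ON-node counts in baseline steadies
  expect_equal(nrow(tab), sum(scr$references == 1))
  # knocked node is OFF in every post-KO steady state
  expect_true(all(scr$steady[cbind(seq_len(nrow(tab)),
                                   match(tab$ko_node, scr$nodes))] == 0))
  for (r in states) {
    h <- tab[[paste0("hamming_", r)]]
    s <- tab[[paste0("similarity_", r)]]
    expect_equal(s, 1 - h / n)
    # recompute hamming directly
    hd <- apply(scr$steady, 1, function(x) sum(x != scr$references[r, ]))
    expect_equal(h, unname(hd))
    for (st in states) {
      z <- tab[[paste0("z_", r)]][tab$start_state == st]
      sims <- s[tab$start_state == st]
      if (length(sims) >= 2 && stats::sd(sims) > 0) {
        expect_lt(abs(mean(z)), 1e-9)
        expect_lt(abs(stats::sd(z) - 1), 1e-9)
      } else {
        expect_true(all(z == 0))
      }
    }
  }
  # assigned = argmax similarity with fixed-order tie-break
  simcols <- as.matrix(tab[, paste0("similarity_", states)])
  expect_equal(tab$assigned,
               states[apply(simcols, 1, which.max)])
})

test_that("the planted knockout drives the NPC state onto the MES fixed point", {
  ci <- constructed_instance()
  # both profiles are fixed points, by enumeration
  fps <- oracle_fixed_points(ci$model)
  for (p in ci$profiles) {
    expect_true(oracle_index_of_state(p, ci$model$nodes) %in% fps)
  }
  scr <- knockout_screen(ci$model, ci$profiles[c("MES", "NPC")])
  row <- scr$table[scr$table$start_state == "NPC" & scr$table$ko_node == "T", ]
  expect_equal(row$assigned, "MES")
  expect_equal(row$hamming_MES, 0)  # lands exactly on the MES fixed point
})

test_that("steady state is stable when restarted from its own fixed point", {
  for (seed in 1:10) {
    m <- random_gate_model(6, seed)
    fps <- oracle_fixed_points(m)
    for (fp in fps) {
      s <- oracle_state_from_index(fp, m$nodes)
      att <- steady_state(m, s)
      expect_equal(att$type, "fixed")
      expect_equal(att$steps, 1L)
      expect_equal(att$state, s)
    }
  }
})
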