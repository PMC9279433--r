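test_that("FVA recovers hand-derived ranges on canonical fixtures", {
  ## linear chain with capped source: every reaction spans [0, 10]
  p <- toy_chain_problem(src_ub = 10)
  v <- fva(p)
  expect_equal(v$min, rep(0, 3), tolerance = 1e-6)
  expect_equal(v$max, rep(10, 3), tolerance = 1e-6)

  ## all exchanges closed: conservation forces zero everywhere
  closed <- flux_problem(p$S, lb = c(0, 0, 0), ub = c(0, 1000, 0))
  vc <- fva(closed)
  expect_true(all(abs(vc$min) < 1e-6 & abs(vc$max) < 1e-6))

  ## an isolated reversible loop still carries arbitrary circulating flux
  loop <- toy_loop_problem()
  vl <- fva(loop, c("r1", "r2"))
  expect_equal(vl$min, c(-1000, -1000), tolerance = 1e-5)
  expect_equal(vl$max, c(1000, 1000), tolerance = 1e-5)

  ## infeasible problem raises a located error
  S1 <- matrix(1, 1, 1, dimnames = list("A", "r"))
  expect_error(fva(flux_problem(S1, lb = 5, ub = 10)),
               class = "infeasibility_error")
})

test_that("FVA agrees with a vertex-enumeration oracle on random small fixtures", {
  set.seed(101)
  for (rep in 1:6) {
    m <- sample(2:3, 1); n <- sample(4:6, 1)
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      rows <- sample(seq_len(m), min(m, 2))
      S[rows[1], j] <- -1
      if (length(rows) > 1 && stats::runif(1) < 0.7) S[rows[2], j] <- 1
    }
    ## make the first two columns exchanges
    S[, 1] <- 0; S[1, 1] <- -1
    S[, 2] <- 0; S[min(2, m), 2] <- 1
    rev <- stats::runif(n) < 0.4
    lb <- ifelse(rev, -1000, 0); ub <- rep(1000, n)
    lb[1] <- -5; ub[1] <- 5
    dimnames(S) <- list(paste0("m", 1:m), paste0("r", 1:n))
    p <- flux_problem(S, lb, ub)
    got <- fva(p)
    want <- fva_vertex_oracle(S, lb, ub)
    expect_false(is.null(want))
    expect_equal(got$min, want$min, tolerance = 1e-6)
    expect_equal(got$max, want$max, tolerance = 1e-6)
  }
})

test_that("blocked reactions are detected and removal reaches a fixpoint", {
  ## chain with a dangling branch B -> C (C unconsumed, no exchange)
  S <- matrix(c(1, -1, 0, 0,
                0, 1, -1, -1,
                0, 0, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c("EX_in", "r_AB", "EX_out", "r_BC")))
  p <- flux_problem(S, lb = rep(0, 4), ub = rep(1000, 4))
  bl <- blocked_reactions(p)
  expect_identical(bl, "r_BC")

  ## consistent network: empty set
  expect_length(blocked_reactions(toy_chain_problem()), 0)

  ## fixpoint: blocked set of the reduced network is empty
  keep <- setdiff(colnames(S), bl)
  p2 <- flux_problem(S[, keep][rowSums(S[, keep] != 0) > 0, ],
                     lb = rep(0, 3), ub = rep(1000, 3))
  expect_length(blocked_reactions(p2), 0)
})

test_that("weighted FASTCORE prefers annotated routes and matches the subset oracle", {
  ## core secretion EX_B supported by an annotated 2-step route (weight 1
  ## each) or an unannotated shortcut (weight 100)
  S <- matrix(c(-1, -1, 0, 1, 0,
                0, 1, -1, 0, 0,
                1, 0, 1, 0, -1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "C", "B"),
                              c("shortcut", "r1", "r2", "EX_A", "EX_B")))
  lb <- c(0, 0, 0, -1000, 0); ub <- rep(1000, 5)
  p <- flux_problem(S, lb, ub)
  w <- c(shortcut = 100, r1 = 1, r2 = 1, EX_A = 1, EX_B = 0)
  sel <- fastcore_weighted(p, core = "EX_B", weights = w)
  expect_true("EX_B" %in% sel)
  expect_setequal(sel, c("EX_B", "EX_A", "r1", "r2"))

  oracle <- fastcore_subset_oracle(p, "EX_B", w)
  expect_setequal(sel, oracle$set)
  expect_equal(sum(w[setdiff(sel, "EX_B")]), oracle$weight)

  ## output is flux-consistent and contains the core
  idx <- match(sel, p$reaction_ids)
  psub <- flux_problem(as.matrix(p$S)[, idx, drop = FALSE], p$lb[idx], p$ub[idx])
  expect_length(blocked_reactions(psub), 0)

  ## empty core -> empty selection
  expect_length(fastcore_weighted(p, character(0)), 0)

  ## unsupportable core reaction -> named core-infeasible error
  S2 <- cbind(S, dead = c(0, 0, 0)); S2["A", "dead"] <- 0
  S2 <- rbind(S2, D = 0); S2["D", "dead"] <- 1
  p2 <- flux_problem(S2, c(lb, 0), c(ub, 1000))
  err <- tryCatch(fastcore_weighted(p2, core = "dead"), condition = identity)
  expect_s3_class(err, "core_infeasible_error")
  expect_match(conditionMessage(err), "dead")
})

test_that("raising a non-core penalty never increases its selection", {
  ## with a cheap shortcut the shortcut is chosen; making it expensive
  ## switches the selection to the two-step route
  S <- matrix(c(-1, -1, 0, 1, 0,
                0, 1, -1, 0, 0,
                1, 0, 1, 0, -1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "C", "B"),
                              c("shortcut", "r1", "r2", "EX_A", "EX_B")))
  p <- flux_problem(S, c(0, 0, 0, -1000, 0), rep(1000, 5))
  cheap <- fastcore_weighted(p, "EX_B",
                             weights = c(shortcut = 0.5, r1 = 1, r2 = 1,
                                         EX_A = 1, EX_B = 0))
  expect_true("shortcut" %in% cheap)
  dear <- fastcore_weighted(p, "EX_B",
                            weights = c(shortcut = 100, r1 = 1, r2 = 1,
                                        EX_A = 1, EX_B = 0))
  expect_false("shortcut" %in% dear)
})
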