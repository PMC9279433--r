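## Shared fixtures and independent oracles for the test suite.
## Expensive synthetic objects are built once per session and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

## ---- toy stoichiometric fixtures ------------------------------------------

## linear chain 0 -> A -> B -> 0 with the source exchange capped at [0, 10]
toy_chain_problem <- function(src_ub = 10) {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX_in", "r_AB", "EX_out")))
  flux_problem(S, lb = c(0, 0, 0), ub = c(src_ub, 1000, 1000))
}

## reversible loop A <-> B (two reversible conversions) with closed exchanges
toy_loop_problem <- function() {
  S <- matrix(c(-1, 1, -1,
                1, -1, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("r1", "r2", "EX_A")))
  flux_problem(S, lb = c(-1000, -1000, 0), ub = c(1000, 1000, 0))
}

## small toy metabolic network used by io / filtering tests:
## EX_a -> a ; r1: a -> b (taxa s1) ; r2: b -> c (no taxa) ; EX_b, EX_c
toy_network <- function() {
  mets <- metabolite_table(c("a", "b", "c"),
                           inchi = c("InChI=1S/CH4/h1H4", "InChI=1S/CH4O/c1-2/h2H,1H3", NA),
                           smiles = c("C", "CO", NA),
                           formula = c("CH4", "CH4O", NA),
                           compartment = "e")
  rxns <- reaction_table(c("EX_a", "r1", "r2", "EX_b", "EX_c"),
                         reversible = c(TRUE, FALSE, FALSE, TRUE, TRUE),
                         provenance = c("exchange", "annotated", "annotated",
                                        "exchange", "exchange"),
                         taxa = c("", "s1", "", "", ""))
  stoi <- stoichiometry_table(
    c("EX_a", "r1", "r1", "r2", "r2", "EX_b", "EX_c"),
    c("a", "a", "b", "b", "c", "b", "c"),
    c(-1, -1, 1, -1, 1, -1, -1))
  metabolic_network(mets, rxns, stoi)
}

## ---- memoised synthetic objects -------------------------------------------

small_universe <- function() memo("universe", generate_universe(3, 14, seed = 42))

planted <- function() memo("planted", plant_pathways(small_universe(), 2, 2, seed = 7))

## full search -> integration pipeline on the memoised universe
pipeline_fixture <- function() {
  memo("pipeline", {
    u <- small_universe()
    pp <- planted()
    sinks <- u$metabolites$inchi[!is.na(u$metabolites$inchi)]
    params <- search_params(itermax = 50, chem_cutoff = 0.2, seed = 1)
    universal <- u
    predictions <- list()
    src_met <- character(0)
    for (i in seq_len(nrow(pp$sources))) {
      src <- pp$sources[i, ]
      scope <- search_biosensor(src, sinks, pp$rules, params, u$metabolites, u)
      fr <- pathway_reactions(scope, extract_connected_pathways(scope, sinks))
      ext <- add_predicted_reactions(universal, fr)
      universal <- ext$network
      predictions[[src$id]] <- ext$reaction_ids
      src_met[src$id] <- fr$metabolites$id[fr$metabolites$inchi == src$inchi]
    }
    gf <- sequential_gapfill(universal, u, predictions)
    net1 <- prune_and_consistency(gf$network)
    pred_ids <- unlist(predictions)
    pred_mets <- unique(net1$stoichiometry$metabolite_id[
      net1$stoichiometry$reaction_id %in% pred_ids])
    evidence <- expand.grid(species = net1$species_catalog, metabolite = pred_mets,
                            stringsAsFactors = FALSE)
    net_new <- single_species_repair(net1, evidence)
    list(universe = u, planted = pp, universal = universal,
         predictions = predictions, src_met = src_met, gapfill = gf,
         net_new = net_new)
  })
}

## ---- independent oracles ---------------------------------------------------

## FVA by vertex enumeration of { v : S v = 0, lb <= v <= ub } (n <= ~8).
## Every vertex has >= n - rank(S) coordinates tight at a bound; enumerate
## bound-fixing patterns and solve for the rest.
fva_vertex_oracle <- function(S, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  nf <- n - r                      # number of coordinates to pin at bounds
  verts <- list()
  add_vertex <- function(v) {
    if (max(abs(S %*% v)) > 1e-6) return()
    if (any(v < lb - 1e-6) || any(v > ub + 1e-6)) return()
    verts[[length(verts) + 1]] <<- pmin(pmax(v, lb), ub)
  }
  if (nf == 0) {
    sol <- qr.solve(S, rep(0, nrow(S)))
    add_vertex(sol)
  } else {
    subsets <- utils::combn(n, nf, simplify = FALSE)
    for (N in subsets) {
      B <- setdiff(seq_len(n), N)
      corners <- expand.grid(rep(list(c("lb", "ub")), nf))
      for (ci in seq_len(nrow(corners))) {
        vN <- ifelse(unlist(corners[ci, ]) == "lb", lb[N], ub[N])
        rhs <- -S[, N, drop = FALSE] %*% vN
        sol <- tryCatch(qr.solve(S[, B, drop = FALSE], rhs), error = function(e) NULL)
        if (is.null(sol)) next
        v <- numeric(n); v[N] <- vN; v[B] <- sol
        add_vertex(v)
      }
    }
  }
  if (length(verts) == 0) return(NULL)   # infeasible
  V <- do.call(rbind, lapply(verts, as.numeric))
  data.frame(min = apply(V, 2, min), max = apply(V, 2, max))
}

## exhaustive minimum-weight flux-consistent superset of a core
fastcore_subset_oracle <- function(p, core, weights) {
  noncore <- setdiff(p$reaction_ids, core)
  consistent <- function(ids) {
    idx <- match(ids, p$reaction_ids)
    S <- as.matrix(p$S)[, idx, drop = FALSE]
    keep <- rowSums(S != 0) > 0
    v <- fva_vertex_oracle(S[keep, , drop = FALSE], p$lb[idx], p$ub[idx])
    if (is.null(v)) return(FALSE)
    all(pmax(abs(v$min), abs(v$max)) > 1e-6)
  }
  best <- NULL; best_w <- Inf
  for (k in 0:length(noncore)) {
    for (sub in utils::combn(length(noncore), k, simplify = FALSE)) {
      ids <- c(core, noncore[sub])
      w <- sum(weights[noncore[sub]])
      if (w >= best_w) next
      if (consistent(ids)) { best <- sort(ids); best_w <- w }
    }
  }
  list(set = best, weight = best_w)
}

## two-sided Fisher p by direct enumeration with log-binomial coefficients
## (coded independently of stats::dhyper)
fisher_enum_oracle <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  r1 <- a + b; c1 <- a + c_
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  logp <- function(k) {
    lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  }
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- vapply(ks, logp, numeric(1))
  obs <- logp(a)
  sum(exp(lp[lp <= obs + 1e-7]))
}

## summed elemental formula of one reaction side, by plain string parsing
## (used to verify balancing independently of the package's residual code)
formula_sum_oracle <- function(formulas, coefs) {
  acc <- list()
  for (i in seq_along(formulas)) {
    f <- formulas[i]
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    parts <- parts[nzchar(parts)]
    for (pt in parts) {
      el <- sub("[0-9]*$", "", pt)
      cnt <- as.integer(sub("^[A-Za-z]+", "", pt))
      if (is.na(cnt)) cnt <- 1L
      acc[[el]] <- (acc[[el]] %||% 0L) + coefs[i] * cnt
    }
  }
  unlist(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
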