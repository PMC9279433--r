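## Stoichiometric LP machinery: flux variability analysis, blocked-reaction
## detection, and weighted FASTCORE context extraction.
##
## All operations work on a `flux_problem`: the steady-state polytope
## { v : S v = 0, lb <= v <= ub } with a flux tolerance eps below which a
## flux is considered zero.

#' Construct a flux problem
#'
#' @param S stoichiometric matrix (metabolites x reactions), dense or sparse,
#'   with dimnames used as metabolite/reaction ids when present.
#' @param lb,ub per-reaction flux bounds.
#' @param tol flux threshold below which a flux counts as zero (default `1e-6`).
#' @return object of class `flux_problem`.
#' @export
flux_problem <- function(S, lb, ub, tol = 1e-6) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  n <- ncol(S)
  if (length(lb) != n || length(ub) != n) {
    pf_error("bound length does not match reaction count", "input_error")
  }
  if (any(lb > ub)) pf_error("lb > ub in flux problem", "input_error")
  rids <- if (n == 0) character(0) else colnames(S) %||% paste0("r", seq_len(n))
  mids <- if (nrow(S) == 0) character(0) else
    rownames(S) %||% paste0("m", seq_len(nrow(S)))
  structure(list(S = S, lb = as.numeric(lb), ub = as.numeric(ub), tol = tol,
                 reaction_ids = rids, metabolite_ids = mids),
            class = "flux_problem")
}

#' Flux problem of a metabolic network
#'
#' @param net a `metabolic_network`.
#' @param tol flux threshold.
#' @export
as_flux_problem <- function(net, tol = 1e-6) {
  flux_problem(stoich_matrix(net), net$reactions$lb, net$reactions$ub, tol = tol)
}

#' Flux variability analysis
#'
#' For each reaction in `subset`, the minimum and maximum steady-state flux
#' over the feasible polytope.
#'
#' @param p a `flux_problem`.
#' @param subset reaction ids to analyse (default: all).
#' @return data frame with columns `reaction_id`, `min`, `max`.
#' @export
fva <- function(p, subset = NULL) {
  subset <- subset %||% p$reaction_ids
  idx <- match(subset, p$reaction_ids)
  if (anyNA(idx)) {
    pf_error(sprintf("unknown reaction id: %s", subset[which(is.na(idx))[1]]),
             "input_error")
  }
  n <- length(p$lb)
  Aeq <- as.matrix(p$S)
  beq <- numeric(nrow(Aeq))
  res <- matrix(NA_real_, length(idx), 2)
  for (k in seq_along(idx)) {
    cc <- numeric(n); cc[idx[k]] <- 1
    lo <- lp_solve(cc, Aeq, beq, p$lb, p$ub)
    hi <- lp_solve(-cc, Aeq, beq, p$lb, p$ub)
    if (lo$status != "ok" || hi$status != "ok") {
      pf_error(sprintf("FVA LP %s for reaction '%s' (%s)",
                       if (lo$status != "ok") "min" else "max",
                       subset[k],
                       (if (lo$status != "ok") lo$status else hi$status)),
               "infeasibility_error", data = list(reaction = subset[k]))
    }
    res[k, ] <- c(lo$objective, -hi$objective)
  }
  ## numerical guard: min can exceed max only by solver noise
  flip <- res[, 1] > res[, 2]
  res[flip, ] <- res[flip, c(2, 1)]
  data.frame(reaction_id = subset, min = res[, 1], max = res[, 2],
             stringsAsFactors = FALSE)
}

#' Blocked reactions of a flux problem
#'
#' Reactions whose flux magnitude cannot exceed the tolerance in any feasible
#' steady state.  Removing all blocked reactions leaves a flux-consistent
#' network.
#'
#' @param p a `flux_problem`.
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(p) {
  v <- fva(p)
  v$reaction_id[abs(v$min) <= p$tol & abs(v$max) <= p$tol]
}

#' Restrict a flux problem to a reaction subset
#' @noRd
restrict_problem <- function(p, keep_ids) {
  idx <- match(keep_ids, p$reaction_ids)
  S <- p$S[, idx, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  flux_problem(S[used, , drop = FALSE], p$lb[idx], p$ub[idx], tol = p$tol)
}

## ---- weighted FASTCORE -----------------------------------------------------

## LP-7: maximize the number of reactions in J that reach flux >= eps.
##   max sum(z)  s.t.  S v = 0, v_j >= z_j (j in J), 0 <= z <= eps, lb <= v <= ub
## Solved in the equality form by adding one slack per J-row.
lp7 <- function(p, J_idx, eps) {
  n <- length(p$lb); k <- length(J_idx)
  Aeq <- as.matrix(p$S)
  m <- nrow(Aeq)
  ## variables: v (n), z (k), s (k) with v_j - z_j - s_j = 0, s >= 0
  A <- cbind(Aeq, matrix(0, m, 2 * k))
  link <- matrix(0, k, n + 2 * k)
  for (j in seq_len(k)) {
    link[j, J_idx[j]] <- 1
    link[j, n + j] <- -1
    link[j, n + k + j] <- -1
  }
  Aeq2 <- rbind(A, link)
  beq2 <- numeric(m + k)
  cc <- c(numeric(n), rep(-1, k), numeric(k))
  big <- max(abs(c(p$lb, p$ub))) * 2 + 1
  lb2 <- c(p$lb, numeric(k), numeric(k))
  ub2 <- c(p$ub, rep(eps, k), rep(2 * big, k))
  sol <- lp_solve(cc, Aeq2, beq2, lb2, ub2)
  if (sol$status != "ok") return(NULL)
  sol$x[seq_len(n)]
}

## LP-10: among fluxes supporting K at >= eps', minimize the weighted sum of
## absolute fluxes over the penalty set P.
##   min sum(w_p z_p)  s.t.  S v = 0, -z_p <= v_p <= z_p, v_k >= eps', bounds
lp10 <- function(p, K_idx, P_idx, weights, eps_force) {
  n <- length(p$lb); k <- length(P_idx)
  Aeq <- as.matrix(p$S)
  m <- nrow(Aeq)
  lb <- p$lb; ub <- p$ub
  lb[K_idx] <- pmax(lb[K_idx], eps_force)
  if (any(lb > ub)) return(NULL)
  ## variables: v (n), z (k), slacks s1,s2 (k each):
  ##   z_p - v_p - s1_p = 0 ;  z_p + v_p - s2_p = 0
  nv <- n + 3 * k
  rows <- m + 2 * k
  A <- matrix(0, rows, nv)
  A[seq_len(m), seq_len(n)] <- Aeq
  for (j in seq_len(k)) {
    A[m + j, P_idx[j]] <- -1; A[m + j, n + j] <- 1; A[m + j, n + k + j] <- -1
    A[m + k + j, P_idx[j]] <- 1; A[m + k + j, n + j] <- 1; A[m + k + j, n + 2 * k + j] <- -1
  }
  beq <- numeric(rows)
  big <- max(abs(c(lb, ub))) + 1
  lb2 <- c(lb, numeric(3 * k))
  ub2 <- c(ub, rep(big, k), rep(2 * big, 2 * k))
  cc <- c(numeric(n), weights, numeric(2 * k))
  sol <- lp_solve(cc, A, beq, lb2, ub2)
  if (sol$status != "ok") return(NULL)
  sol$x[seq_len(n)]
}

find_sparse_mode <- function(p, J_idx, P_idx, weights, eps) {
  if (length(J_idx) == 0) return(integer(0))
  v <- lp7(p, J_idx, eps)
  if (is.null(v)) return(integer(0))
  K <- J_idx[v[J_idx] >= 0.99 * eps]
  if (length(K) == 0) return(integer(0))
  v <- lp10(p, K, P_idx, weights[P_idx], eps_force = 0.99 * eps)
  if (is.null(v)) return(integer(0))
  ## support threshold well below the forcing level: reactions carrying the
  ## forced flux through non-unit stoichiometry must not fall off the edge
  which(abs(v) >= max(p$tol * 10, 0.05 * eps))
}

#' Weighted FASTCORE context extraction
#'
#' Extracts a flux-consistent reaction set that contains every core reaction
#' while heuristically minimizing the total weight of included non-core
#' reactions, following the LP-7/LP-10 scheme of the FASTCORE family with
#' per-reaction penalty weights on the sparsity step.
#'
#' @param p a `flux_problem` for the universal network (every core reaction
#'   must be unblocked in it).
#' @param core character vector of core reaction ids.
#' @param weights named numeric vector of nonnegative penalties for non-core
#'   reactions; unnamed reactions default to `default_weight`.
#' @param default_weight penalty for non-core reactions absent from
#'   `weights` (default 1).
#' @param check_core verify upfront that each core reaction is unblocked,
#'   giving a named `core_infeasible_error` (default `TRUE`).
#' @return character vector of selected reaction ids (a superset of `core`).
#' @export
fastcore_weighted <- function(p, core, weights = NULL, default_weight = 1,
                              check_core = TRUE) {
  if (length(core) == 0) return(character(0))
  core_idx <- match(core, p$reaction_ids)
  if (anyNA(core_idx)) {
    pf_error(sprintf("core reaction not in network: %s", core[which(is.na(core_idx))[1]]),
             "input_error")
  }
  w <- rep(default_weight, length(p$reaction_ids))
  names(w) <- p$reaction_ids
  if (!is.null(weights)) {
    if (any(weights < 0)) pf_error("weights must be nonnegative", "input_error")
    w[names(weights)] <- weights
  }
  if (check_core) {
    v <- fva(p, core)
    bad <- v$reaction_id[abs(v$min) <= p$tol & abs(v$max) <= p$tol]
    if (length(bad) > 0) {
      pf_error(sprintf("core reaction blocked in universal network: %s", bad[1]),
               "core_infeasible_error", data = list(reactions = bad))
    }
  }

  n <- length(p$lb)
  supp_tol <- max(p$tol * 100, 1e-4)
  pw <- p                                  # working copy; columns may be flipped
  flip_sign <- rep(1, n)
  irrev <- pw$lb >= 0

  J <- intersect(core_idx, which(irrev))
  P <- setdiff(seq_len(n), core_idx)
  A <- find_sparse_mode(pw, J, P, w, supp_tol)
  if (!all(J %in% A)) {
    miss <- setdiff(J, A)
    pf_error(sprintf("irreversible core reaction cannot carry flux: %s",
                     p$reaction_ids[miss[1]]),
             "core_infeasible_error",
             data = list(reactions = p$reaction_ids[miss]))
  }
  J <- setdiff(core_idx, A)
  flipped <- FALSE; singleton <- FALSE
  while (length(J) > 0) {
    P <- setdiff(P, A)
    Jw <- if (singleton) J[1] else J
    Anew <- find_sparse_mode(pw, Jw, P, w, supp_tol)
    A <- union(A, Anew)
    if (length(intersect(J, A)) > 0) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      JiRev <- setdiff(Jw, which(irrev))
      if (flipped || length(JiRev) == 0) {
        if (singleton) {
          pf_error(sprintf("core reaction cannot be made consistent: %s",
                           p$reaction_ids[J[1]]),
                   "core_infeasible_error",
                   data = list(reactions = p$reaction_ids[J[1]]))
        }
        flipped <- FALSE; singleton <- TRUE
      } else {
        ## flip the direction of reversible core reactions that resisted
        pw$S[, JiRev] <- -pw$S[, JiRev]
        tmp <- pw$lb[JiRev]
        pw$lb[JiRev] <- -pw$ub[JiRev]
        pw$ub[JiRev] <- -tmp
        flip_sign[JiRev] <- -flip_sign[JiRev]
        flipped <- TRUE
      }
    }
  }
  sort(p$reaction_ids[A])
}
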