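## Thin LP solver adapter.
##
## Solves   min  c'v   s.t.  Aeq v = beq,  lb <= v <= ub
## by shifting to the nonnegative standard form x = v - lb expected by the
## pracma simplex backend, with upper bounds as explicit inequality rows.
## The backend's big-M phase occasionally lands on a singular basis for a
## particular big-M value, so the adapter retries over a ladder of values
## before declaring failure; infeasibility is reported as a distinct status.

lp_solve <- function(cc, Aeq, beq, lb, ub, maxiter = NULL) {
  n <- length(cc)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub)) return(list(status = "infeasible", x = NULL))
  Aeq <- as.matrix(Aeq)
  if (is.null(maxiter)) maxiter <- max(200L, 20L * n)
  span <- ub - lb
  beq_shift <- beq - as.vector(Aeq %*% lb)
  free <- span > 0
  ## fixed variables are substituted out
  if (!all(free)) {
    if (sum(free) == 0) {
      resid <- max(abs(beq_shift))
      if (resid > 1e-7) return(list(status = "infeasible", x = NULL))
      return(list(status = "ok", x = lb, objective = sum(cc * lb)))
    }
    A_free <- Aeq[, free, drop = FALSE]
  } else {
    A_free <- Aeq
  }
  cc_f <- cc[free]; span_f <- span[free]
  nf <- length(cc_f)
  last_msg <- NULL
  saw_bigM_fail <- FALSE
  ## retry ladder: big-M values crossed with deterministic column
  ## permutations (a permuted pivoting order escapes singular bases)
  for (attempt in 1:3) {
    perm <- if (attempt == 1) seq_len(nf) else
      with_local_seed(1000L + attempt, sample.int(nf))
    for (bigM in c(100, 1000, 1e4, 10, 1e6)) {
      ## the backend breaks simplex pivot ties with sample(); pin the RNG
      ## locally so identical LPs always yield the identical vertex
      o <- with_local_seed(285714L, tryCatch(
        pracma::linprog(cc_f[perm], A = diag(nf), b = span_f[perm],
                        Aeq = A_free[, perm, drop = FALSE], beq = beq_shift,
                        maxiter = maxiter, bigM = bigM),
        error = function(e) list(errno = -99L, message = conditionMessage(e))))
      if (!is.null(o$errno) && o$errno == 1) {
        xf <- numeric(nf)
        xf[perm] <- o$x
        x <- lb
        x[free] <- pmin(pmax(xf, 0), span_f) + lb[free]
        return(list(status = "ok", x = x, objective = sum(cc * x)))
      }
      last_msg <- o$message
      if (!is.null(o$errno) && o$errno == -4) saw_bigM_fail <- TRUE
    }
  }
  if (saw_bigM_fail) {
    ## big-M phase could not drive the artificials out under any retry:
    ## the equality system has no feasible point within the bounds
    return(list(status = "infeasible", x = NULL, message = last_msg))
  }
  list(status = "failed", x = NULL, message = last_msg)
}
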