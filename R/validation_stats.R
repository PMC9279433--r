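## Comparison of predicted output metabolites against metabolomics
## presence/absence calls, with an exact two-sided Fisher test.

#' Confusion counts over (metabolite, sample) cells
#'
#' For each sample, the universe of metabolites is partitioned into true
#' positives (predicted and measured), false positives (predicted only),
#' false negatives (measured only) and true negatives (neither); counts are
#' summed over samples.  Measured metabolites outside the universe are
#' ignored with a warning.
#'
#' @param predicted named list: sample id -> character vector of predicted
#'   metabolites.
#' @param measured named list: sample id -> character vector of metabolites
#'   called present.
#' @param universe character vector fixing the metabolite universe (e.g. the
#'   metabolites whose prediction differs between model versions).
#' @return object of class `contingency_table` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(predicted, measured, universe) {
  samples <- union(names(predicted), names(measured))
  tp <- fp <- fn <- tn <- 0L
  for (s in samples) {
    p <- intersect(predicted[[s]] %||% character(0), universe)
    m_raw <- measured[[s]] %||% character(0)
    outside <- setdiff(m_raw, universe)
    if (length(outside) > 0) {
      warning(sprintf("sample %s: %d measured metabolite(s) outside universe ignored",
                      s, length(outside)))
    }
    m <- intersect(m_raw, universe)
    tp <- tp + length(intersect(p, m))
    fp <- fp + length(setdiff(p, m))
    fn <- fn + length(setdiff(m, p))
    tn <- tn + length(universe) - length(union(p, m))
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table: TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' With the margins of the table fixed, the p-value is the sum of the
#' hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed table (the standard probability-mass
#' two-sided rule).  Implemented by exact enumeration over all tables with
#' the observed margins.
#'
#' @param t a `contingency_table` (or list with `tp`, `fp`, `fn`, `tn`).
#' @return p-value in `(0, 1]`.  A zero margin yields `p = 1` with a warning.
#' @export
fisher_two_sided <- function(t) {
  a <- t$tp; b <- t$fp; cc <- t$fn; d <- t$tn
  if (min(a, b, cc, d) < 0) pf_error("negative count", "input_error")
  n <- a + b + cc + d
  if (n == 0) pf_error("empty table", "input_error")
  row1 <- a + b; col1 <- a + cc
  if (row1 == 0 || col1 == 0 || row1 == n || col1 == n) {
    warning("degenerate margin: p = 1 by convention")
    return(1)
  }
  ## enumerate every table with these margins: cell (1,1) = k
  k_min <- max(0L, row1 + col1 - n)
  k_max <- min(row1, col1)
  ks <- k_min:k_max
  logp <- stats::dhyper(ks, col1, n - col1, row1, log = TRUE)
  obs <- stats::dhyper(a, col1, n - col1, row1, log = TRUE)
  ## relative tolerance guards against ties lost to floating point; the sum
  ## of the full distribution can exceed 1 by rounding, so clamp
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}
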