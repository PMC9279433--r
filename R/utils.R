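## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' @noRd
pf_error <- function(msg, class, data = list()) {
  stop(errorCondition(msg, class = c(class, "phenoflux_error"), data = data))
}

#' Split a semicolon-collapsed set column into a character vector
#' @noRd
split_set <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  unique(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' @noRd
collapse_set <- function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";")

#' Parse an elemental formula string ("C15H10O4") to a named integer vector
#' @noRd
parse_formula <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(sub("^[A-Za-z]+", "", parts))
  n[is.na(n)] <- 1L
  out <- tapply(n, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' @noRd
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0) return("")
  counts <- counts[order(names(counts))]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Sum formula vectors with multiplicities
#' @noRd
sum_formulas <- function(formulas, coefs) {
  acc <- integer(0)
  for (i in seq_along(formulas)) {
    f <- formulas[[i]]
    if (length(f) == 0) next
    for (el in names(f)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0L) + coefs[i] * f[[el]]
    }
  }
  acc
}

#' Run an expression under a temporary RNG seed, restoring the prior state
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stream-specific 31-bit seed from a global seed
#' @noRd
split_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  ## double arithmetic is exact here (< 2^53); keep the result in 31 bits
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483629)
}
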