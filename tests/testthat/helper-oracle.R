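# Independent brute-force re-implementation of the disproportionality core:
# explicit double loops and hand-written formulas, deliberately sharing no
# code with the package internals.

oracle_norm <- function(x) toupper(gsub("[[:space:]]+", " ", trimws(x)))

oracle_contingency <- function(rs, drug, term) {
  tbl <- rs$reports
  drug <- oracle_norm(drug)
  term <- oracle_norm(term)
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(tbl))) {
    sus <- drug %in% oracle_norm(tbl$suspect_drugs[[i]])
    hit <- term %in% oracle_norm(tbl$reactions[[i]])
    if (sus && hit) a <- a + 1L
    else if (sus) b <- b + 1L
    else if (hit) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

oracle_count_cases <- function(rs, term) {
  tbl <- rs$reports
  term <- oracle_norm(term)
  counts <- list()
  for (i in seq_len(nrow(tbl))) {
    if (!(term %in% oracle_norm(tbl$reactions[[i]]))) next
    for (drug in unique(oracle_norm(tbl$suspect_drugs[[i]]))) {
      counts[[drug]] <- (counts[[drug]] %||% 0L) + 1L
    }
  }
  unlist(counts) %||% stats::setNames(integer(), character())
}

oracle_prr <- function(cell) {
  (cell[["a"]] / (cell[["a"]] + cell[["b"]])) /
    (cell[["c"]] / (cell[["c"]] + cell[["d"]]))
}

oracle_prr_ci <- function(cell, conf = 0.95) {
  prr <- oracle_prr(cell)
  se <- sqrt(1 / cell[["a"]] - 1 / (cell[["a"]] + cell[["b"]]) +
               1 / cell[["c"]] - 1 / (cell[["c"]] + cell[["d"]]))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(low = exp(log(prr) - z * se), high = exp(log(prr) + z * se))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
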