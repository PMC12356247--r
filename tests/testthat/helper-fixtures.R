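# shared fixtures: reduced-increment parameter sets and a brute-force
# matching oracle used to cross-check the linear-assignment solver

hnca_params <- function(n = 96L, cap = "after-zero-crossing", base = 4L)
  acq_params(35, 10e-6, 2e-3, 2e-3, 38e-3, n, base, boost_cap = cap)

hsqc_params <- function(n = 128L, cap = "after-zero-crossing", base = 4L)
  acq_params(38, 1e-3, 3e-3, 2e-3, 33e-3, n, base, boost_cap = cap)

# exhaustive search over all injective partial assignments of sequential
# values to intra values (self-links forbidden): maximal cardinality first,
# then minimal total |delta|; independent of the igraph route
oracle_link <- function(seqv, intrav, tol) {
  n <- length(seqv)
  best <- list(card = -1L, cost = Inf, pred = rep(NA_integer_, n))
  recurse <- function(i, used, pred, card, cost) {
    if (i > n) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12)) {
        best <<- list(card = card, cost = cost, pred = pred)
      }
      return(invisible())
    }
    recurse(i + 1L, used, pred, card, cost)  # leave strip i unlinked
    if (!is.na(seqv[i])) {
      for (j in setdiff(seq_len(n), c(i, used))) {
        if (is.na(intrav[j])) next
        d <- abs(seqv[i] - intrav[j])
        if (d <= tol) {
          pred[i] <- j
          recurse(i + 1L, c(used, j), pred, card + 1L, cost + d)
          pred[i] <- NA_integer_
        }
      }
    }
  }
  recurse(1L, integer(), rep(NA_integer_, n), 0L, 0)
  best
}

# wrap plain numeric vectors as a strip_list for solver-level tests
make_strips <- function(intra, seqv, truth = seq_along(intra)) {
  structure(lapply(seq_along(intra), function(k) {
    list(h = 8, n = 120, intra_ppm = intra[k], intra_int = 1,
         seq_ppm = if (is.na(seqv[k])) numeric() else seqv[k],
         seq_int = if (is.na(seqv[k])) numeric() else 0.5,
         truth = truth[k], merged = FALSE)
  }), class = "strip_list")
}
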