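# Independent brute-force optimizer for the path-recombination deduction.
# The elementary operations (two source paths -> resultants, with their
# DCJ-indel costs) are listed explicitly; the optimum over all operation
# sequences is found by memoized search. This is deliberately independent
# of the package's greedy group table.

# type order: W, Wbar, Wund, M, Mbar, Mund, Z, N
DELTA_OPS <- list(
  list(c(1, 4), integer(0), 2),   # AA^AB + BB^AB -> dot + dot
  list(c(1, 5), 8L, 1),           # AA^AB + BB^A  -> dot + AB^BA
  list(c(1, 6), 7L, 1),           # AA^AB + BB^B  -> dot + AB^AB
  list(c(2, 4), 7L, 1),           # AA^A + BB^AB  -> dot + AB^AB
  list(c(3, 4), 8L, 1),           # AA^B + BB^AB  -> dot + AB^BA
  list(c(2, 5), integer(0), 1),   # AA^A + BB^A
  list(c(3, 6), integer(0), 1),   # AA^B + BB^B
  list(c(1, 1), c(2L, 3L), 1),    # AA^AB + AA^AB -> AA^A + AA^B
  list(c(4, 4), c(5L, 6L), 1),    # BB^AB + BB^AB -> BB^A + BB^B
  list(c(1, 7), 2L, 1),           # AA^AB + AB^AB -> dot + AA^A
  list(c(1, 8), 3L, 1),           # AA^AB + AB^BA -> dot + AA^B
  list(c(4, 7), 6L, 1),           # BB^AB + AB^AB -> dot + BB^B
  list(c(4, 8), 5L, 1),           # BB^AB + AB^BA -> dot + BB^A
  list(c(7, 8), integer(0), 1),   # AB^AB + AB^BA
  list(c(2, 8), 1L, 0),           # AA^A + AB^BA -> dot + AA^AB
  list(c(3, 7), 1L, 0),           # AA^B + AB^AB -> dot + AA^AB
  list(c(5, 7), 4L, 0),           # BB^A + AB^AB -> dot + BB^AB
  list(c(6, 8), 4L, 0),           # BB^B + AB^BA -> dot + BB^AB
  list(c(2, 6), 7L, 0),           # AA^A + BB^B -> dot + AB^AB
  list(c(3, 5), 8L, 0),           # AA^B + BB^A -> dot + AB^BA
  list(c(7, 7), c(2L, 6L), 0),    # AB^AB + AB^AB -> AA^A + BB^B
  list(c(8, 8), c(3L, 5L), 0))    # AB^BA + AB^BA -> AA^B + BB^A

delta_bruteforce <- local({
  cache <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(state) {
    key <- paste(state, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    best <- 0L
    for (op in DELTA_OPS) {
      s <- state
      s[op[[1]][1]] <- s[op[[1]][1]] - 1L
      s[op[[1]][2]] <- s[op[[1]][2]] - 1L
      if (any(s < 0L)) next
      for (p in op[[2]]) s[p] <- s[p] + 1L
      v <- op[[3]] + rec(s)
      if (v > best) best <- v
    }
    cache[[key]] <- best
    best
  }
  function(counts) {
    full <- stats::setNames(integer(8),
                            c("W", "Wbar", "Wund", "M", "Mbar", "Mund", "Z", "N"))
    full[names(counts)] <- as.integer(counts)
    rec(unname(full))
  }
})
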