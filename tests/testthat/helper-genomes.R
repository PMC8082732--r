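# Random genome generators shared across the suite. All draw from the
# session RNG; tests seed explicitly.

# canonical pair: identical singular content, mixed topologies
random_canonical_pair <- function(n_markers = sample(2:5, 1),
                                  p_circular = 0.3) {
  mk <- as.character(seq_len(n_markers))
  mkg <- function(nm) {
    toks <- paste0(sample(c("", "-"), n_markers, replace = TRUE), sample(mk))
    k <- sample(1:min(2, n_markers), 1)
    sp <- if (k > 1) sort(sample(seq_len(n_markers - 1), k - 1)) else integer(0)
    genome(nm, lapply(split(toks, findInterval(seq_len(n_markers), sp + 1)),
                      function(p) chromosome(p, circular = runif(1) < p_circular)))
  }
  list(A = mkg("A"), B = mkg("B"))
}

# singular pair: singular common markers plus exclusive markers
random_singular_pair <- function(n_common = sample(2:6, 1),
                                 max_exclusive = 3, p_circular = 0.3) {
  mk <- as.character(seq_len(n_common))
  mkg <- function(nm, prefix) {
    toks <- c(mk, if ((nex <- sample(0:max_exclusive, 1)) > 0)
      paste0(prefix, seq_len(nex)))
    toks <- paste0(sample(c("", "-"), length(toks), replace = TRUE), sample(toks))
    k <- sample(1:2, 1)
    n <- length(toks)
    sp <- if (k > 1 && n > 1) sort(sample(seq_len(n - 1), k - 1)) else integer(0)
    genome(nm, lapply(split(toks, findInterval(seq_len(n), sp + 1)),
                      function(p) chromosome(p, circular = runif(1) < p_circular)))
  }
  list(A = mkg("A", "x"), B = mkg("B", "y"))
}

# tiny natural pair: <= max_occ occurrences per genome, <= 3 copies/marker
random_natural_pair <- function(max_occ = 8, p_circular = 0.3) {
  repeat {
    n_markers <- sample(2:4, 1)
    mk <- as.character(seq_len(n_markers))
    mkg <- function(nm) {
      toks <- rep(mk, 1L + sample(0:2, n_markers, replace = TRUE))
      if (length(toks) > max_occ) toks <- toks[seq_len(max_occ)]
      toks <- paste0(sample(c("", "-"), length(toks), replace = TRUE), sample(toks))
      genome(nm, list(chromosome(toks, circular = runif(1) < p_circular)))
    }
    p <- list(A = mkg("A"), B = mkg("B"))
    cn <- census(p$A, p$B)
    if (max(c(cn$phiA, cn$phiB)) <= 3L) return(p)
  }
}

# small natural pair with linear chromosomes only (capping enumerable)
random_cappable_pair <- function() {
  repeat {
    n_markers <- sample(2:3, 1)
    mk <- as.character(seq_len(n_markers))
    mkg <- function(nm, prefix) {
      toks <- c(rep(mk, sample(1:2, n_markers, replace = TRUE)),
                if (runif(1) < 0.5) paste0(prefix, 1))
      if (length(toks) > 6) toks <- toks[1:6]
      toks <- paste0(sample(c("", "-"), length(toks), replace = TRUE), sample(toks))
      k <- sample(1:2, 1)
      n <- length(toks)
      sp <- if (k > 1 && n > 1) sort(sample(seq_len(n - 1), k - 1)) else integer(0)
      genome(nm, lapply(split(toks, findInterval(seq_len(n), sp + 1)),
                        function(p) chromosome(p, circular = FALSE)))
    }
    p <- list(A = mkg("A", "x"), B = mkg("B", "y"))
    if (census(p$A, p$B)$p_star <= 3L) return(p)
  }
}
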