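# Adjacency-set view of a genome: each marker occurrence contributes a tail
# and a head extremity; the genome is a set of adjacencies (unordered pairs
# of extremities) plus telomeres (unpaired extremities). DCJ operations act
# naturally on this view; it backs the BFS sorter, the simulator's DCJ
# sampling and the recombination enumerator.

SEP <- "\x1f"

ext_key <- function(marker, occ, end) paste(marker, occ, end, sep = SEP)

ext_parts <- function(key) {
  p <- strsplit(key, SEP, fixed = TRUE)
  data.frame(marker = vapply(p, `[`, "", 1L),
             occ = as.integer(vapply(p, `[`, "", 2L)),
             end = vapply(p, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

ext_other <- function(key) {
  p <- ext_parts(key)
  ext_key(p$marker, p$occ, ifelse(p$end == "h", "t", "h"))
}

# genome -> list(adjacencies = list of sorted length-2 character, telomeres)
genome_adjacencies <- function(g) {
  occ <- occurrence_table(g)
  adjacencies <- list()
  telomeres <- character(0)
  for (ci in seq_along(g$chromosomes)) {
    rows <- which(occ$chrom == ci)
    left <- ifelse(occ$strand[rows] > 0L, "t", "h")
    right <- ifelse(occ$strand[rows] > 0L, "h", "t")
    lk <- ext_key(occ$marker[rows], occ$occ[rows], left)
    rk <- ext_key(occ$marker[rows], occ$occ[rows], right)
    k <- length(rows)
    if (k > 1L)
      for (i in seq_len(k - 1L))
        adjacencies[[length(adjacencies) + 1L]] <- sort(c(rk[i], lk[i + 1L]))
    if (g$chromosomes[[ci]]$circular) {
      adjacencies[[length(adjacencies) + 1L]] <- sort(c(rk[k], lk[1L]))
    } else {
      telomeres <- c(telomeres, lk[1L], rk[k])
    }
  }
  list(adjacencies = adjacencies, telomeres = telomeres)
}

adjacency_state_key <- function(adj) {
  paste(c(sort(vapply(adj$adjacencies, paste, "", collapse = "+")),
          "::", sort(adj$telomeres)), collapse = ";")
}

# rebuild a genome from an adjacency set
genome_from_adjacencies <- function(adj, name = "G") {
  partner <- character(0)  # extremity -> adjacent extremity ("" if telomere)
  for (a in adj$adjacencies) {
    partner[a[1]] <- a[2]
    partner[a[2]] <- a[1]
  }
  for (t in adj$telomeres) partner[t] <- ""
  all_ext <- names(partner)
  visited <- stats::setNames(rep(FALSE, length(all_ext)), all_ext)
  chroms <- list()
  walk <- function(start, circular) {
    toks <- character(0)
    e <- start
    repeat {
      p <- ext_parts(e)
      toks <- c(toks, paste0(if (p$end == "h") "-" else "", p$marker, SEP, p$occ))
      visited[e] <<- TRUE
      o <- ext_other(e)
      visited[o] <<- TRUE
      nxt <- partner[o]
      if (circular) {
        if (nxt == start) break
      } else if (nxt == "") break
      e <- nxt
    }
    toks
  }
  # linear chromosomes start at telomeres (each walked once)
  for (t in adj$telomeres) {
    if (visited[t]) next
    toks <- walk(t, circular = FALSE)
    chroms[[length(chroms) + 1L]] <- make_chrom_from_occtokens(toks, FALSE)
  }
  # remaining extremities form circular chromosomes
  for (e in all_ext) {
    if (visited[e]) next
    toks <- walk(e, circular = TRUE)
    chroms[[length(chroms) + 1L]] <- make_chrom_from_occtokens(toks, TRUE)
  }
  genome(name, chroms)
}

make_chrom_from_occtokens <- function(toks, circular) {
  # strip the occurrence tag appended during the walk
  chromosome(sub(paste0(SEP, ".*$"), "", toks), circular = circular)
}

# All genomes one DCJ away. Elements acted on: adjacencies and telomeres.
# The four operation kinds: two adjacencies rewired (2 ways), adjacency +
# telomere (2 ways), two telomeres joined, one adjacency split into two
# telomeres.
dcj_neighbor_states <- function(adj) {
  res <- list()
  A <- adj$adjacencies
  Tl <- adj$telomeres
  nA <- length(A)
  add <- function(adjacencies, telomeres) {
    res[[length(res) + 1L]] <<- list(adjacencies = adjacencies, telomeres = telomeres)
  }
  if (nA >= 2L) {
    for (i in seq_len(nA - 1L)) for (j in seq((i + 1L), nA)) {
      p <- A[[i]]; q <- A[[j]]
      rest <- A[-c(i, j)]
      add(c(rest, list(sort(c(p[1], q[1])), sort(c(p[2], q[2])))), Tl)
      add(c(rest, list(sort(c(p[1], q[2])), sort(c(p[2], q[1])))), Tl)
    }
  }
  if (nA >= 1L && length(Tl) >= 1L) {
    for (i in seq_len(nA)) for (t in Tl) {
      p <- A[[i]]
      rest <- A[-i]
      add(c(rest, list(sort(c(p[1], t)))), c(setdiff(Tl, t), p[2]))
      add(c(rest, list(sort(c(p[2], t)))), c(setdiff(Tl, t), p[1]))
    }
  }
  if (length(Tl) >= 2L) {
    for (i in seq_len(length(Tl) - 1L)) for (j in seq(i + 1L, length(Tl))) {
      add(c(A, list(sort(c(Tl[i], Tl[j])))), Tl[-c(i, j)])
    }
  }
  for (i in seq_len(nA)) {
    add(A[-i], c(Tl, A[[i]]))
  }
  res
}
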