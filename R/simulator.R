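# Genome evolution simulator: DCJs, duplications, deletions and insertions
# applied along the edges of a weighted rooted tree. Edge weights are the
# expected DCJ counts; indel/duplication counts are Poisson with mean
# weight * rate; segment lengths are Zipf-distributed.

#' Simulation configuration
#'
#' Defaults follow the simulation protocol the distance model was
#' benchmarked under: Zipf shape 4 for insertion and deletion lengths,
#' shape 6 for duplication lengths, insertion rate 0.1 and deletion rate
#' 0.2 (relative to the DCJ count); events are applied in the order DCJs,
#' duplications, deletions, insertions, with locations drawn uniformly
#' over the genome.
#'
#' @param root_length number of marker occurrences in the root genome.
#' @param tree a two-element numeric vector of edge weights (expected DCJ
#'   counts) for a rooted two-leaf tree, or an `ape::phylo` object with
#'   edge lengths.
#' @param insertion_rate,deletion_rate,duplication_rate event rates
#'   relative to the DCJ expectation.
#' @param zipf_s_indel,zipf_s_dup Zipf shape parameters for segment lengths.
#' @param n_chromosomes number of (linear) chromosomes of the root genome.
#' @param circular logical; make the root chromosomes circular.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return object of class `dcj_sim_config`.
#' @export
sim_config <- function(root_length = 20000, tree = c(10, 10),
                       insertion_rate = 0.1, deletion_rate = 0.2,
                       duplication_rate = 0.4,
                       zipf_s_indel = 4, zipf_s_dup = 6,
                       n_chromosomes = 1L, circular = FALSE, seed = 1L) {
  stopifnot(root_length >= 1, n_chromosomes >= 1)
  structure(list(root_length = as.integer(root_length), tree = tree,
                 insertion_rate = insertion_rate, deletion_rate = deletion_rate,
                 duplication_rate = duplication_rate,
                 zipf_s_indel = zipf_s_indel, zipf_s_dup = zipf_s_dup,
                 n_chromosomes = as.integer(n_chromosomes),
                 circular = isTRUE(circular), seed = as.integer(seed)),
            class = "dcj_sim_config")
}

# Zipf sampler: P(k) proportional to k^-s on 1..kmax. For the shapes used
# here (s >= 4) the mass beyond kmax = 1e4 is far below 1e-10.
rzipf <- function(n, s, kmax = 10000L) {
  w <- (1:kmax)^(-s)
  sample.int(kmax, n, replace = TRUE, prob = w)
}

# internal edge table from the tree specification
tree_edges <- function(tree) {
  if (inherits(tree, "phylo")) {
    if (is.null(tree$edge.length)) stop("tree needs edge lengths (weights)")
    data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
               weight = tree$edge.length,
               name = ifelse(tree$edge[, 2] <= length(tree$tip.label),
                             tree$tip.label[tree$edge[, 2]],
                             paste0("node", tree$edge[, 2])),
               stringsAsFactors = FALSE)
  } else {
    w <- as.numeric(tree)
    data.frame(parent = rep(length(w) + 1L, length(w)),
               child = seq_along(w), weight = w,
               name = paste0("L", seq_along(w)),
               stringsAsFactors = FALSE)
  }
}

#' Simulate genome evolution over a tree
#'
#' @param config a [sim_config()].
#' @return object of class `dcj_sim_result`: `genomes` (named list; leaves
#'   carry the edge names, the root is `"root"`), `events` (data frame log
#'   with one row per mutational event), and `counts` (realized event
#'   counts per edge and operation class).
#' @export
simulate_evolution <- function(config) {
  set.seed(config$seed)
  edges <- tree_edges(config$tree)
  root_id <- setdiff(edges$parent, edges$child)[1]

  # root genome: fresh markers split evenly over the chromosomes
  L <- config$root_length
  k <- min(config$n_chromosomes, L)
  bounds <- floor(seq(0, L, length.out = k + 1L))
  root <- genome("root", lapply(seq_len(k), function(i)
    chromosome(as.character((bounds[i] + 1L):bounds[i + 1L]),
               circular = config$circular)))

  genomes <- list()
  genomes[[as.character(root_id)]] <- root
  log <- list()
  fresh_counter <- 0L

  for (r in seq_len(nrow(edges))) {
    parent <- genomes[[as.character(edges$parent[r])]]
    w <- edges$weight[r]
    n_dcj <- stats::rpois(1, w)
    n_dup <- stats::rpois(1, w * config$duplication_rate)
    n_del <- stats::rpois(1, w * config$deletion_rate)
    n_ins <- stats::rpois(1, w * config$insertion_rate)
    g <- parent
    edge_name <- edges$name[r]
    emit <- function(op, detail) {
      log[[length(log) + 1L]] <<- data.frame(
        edge = edge_name, op = op, detail = detail, stringsAsFactors = FALSE)
    }
    if (n_dcj > 0L) {
      adj <- genome_adjacencies(g)
      for (i in seq_len(n_dcj)) {
        mv <- random_dcj_state(adj)
        if (is.null(mv)) next
        adj <- mv$state
        emit("dcj", mv$detail)
      }
      g <- genome_from_adjacencies(adj, g$name)
    }
    for (i in seq_len(n_dup)) {
      mv <- random_duplication(g, config$zipf_s_dup)
      g <- mv$genome
      emit("duplication", mv$detail)
    }
    for (i in seq_len(n_del)) {
      mv <- random_deletion(g, config$zipf_s_indel)
      if (is.null(mv)) next
      g <- mv$genome
      emit("deletion", mv$detail)
    }
    for (i in seq_len(n_ins)) {
      mv <- random_insertion(g, config$zipf_s_indel, fresh_counter)
      fresh_counter <- mv$counter
      g <- mv$genome
      emit("insertion", mv$detail)
    }
    g$name <- edge_name
    genomes[[as.character(edges$child[r])]] <- g
  }

  events <- if (length(log)) do.call(rbind, log)
            else data.frame(edge = character(0), op = character(0),
                            detail = character(0), stringsAsFactors = FALSE)
  leaf_ids <- setdiff(edges$child, edges$parent)
  out_genomes <- c(list(root = root),
                   stats::setNames(genomes[as.character(leaf_ids)],
                                   edges$name[match(leaf_ids, edges$child)]))
  counts <- as.data.frame(table(edge = events$edge, op = events$op))
  structure(list(genomes = out_genomes, events = events, counts = counts,
                 config = config),
            class = "dcj_sim_result")
}

# one uniformly drawn DCJ: two distinct sites (adjacencies + telomeres),
# rejoining chosen uniformly among the possibilities for the site pair
random_dcj_state <- function(adj) {
  nA <- length(adj$adjacencies)
  nT <- length(adj$telomeres)
  n_sites <- nA + nT
  if (n_sites < 2L) return(NULL)
  pick <- sample.int(n_sites, 2L)
  site <- function(i) if (i <= nA) list(type = "adjacency", ext = adj$adjacencies[[i]], i = i)
                      else list(type = "telomere", ext = adj$telomeres[i - nA], i = i - nA)
  s1 <- site(pick[1]); s2 <- site(pick[2])
  A <- adj$adjacencies; Tl <- adj$telomeres
  if (s1$type == "adjacency" && s2$type == "adjacency") {
    p <- s1$ext; q <- s2$ext
    rest <- A[-c(s1$i, s2$i)]
    choice <- sample.int(2L, 1L)
    newadj <- if (choice == 1L) list(sort(c(p[1], q[1])), sort(c(p[2], q[2])))
              else list(sort(c(p[1], q[2])), sort(c(p[2], q[1])))
    st <- list(adjacencies = c(rest, newadj), telomeres = Tl)
  } else if (s1$type == "telomere" && s2$type == "telomere") {
    choice <- 1L
    st <- list(adjacencies = c(A, list(sort(c(s1$ext, s2$ext)))),
               telomeres = setdiff(Tl, c(s1$ext, s2$ext)))
  } else {
    ad <- if (s1$type == "adjacency") s1 else s2
    tl <- if (s1$type == "telomere") s1 else s2
    p <- ad$ext
    rest <- A[-ad$i]
    choice <- sample.int(2L, 1L)
    keep <- if (choice == 1L) p[2] else p[1]
    join <- if (choice == 1L) p[1] else p[2]
    st <- list(adjacencies = c(rest, list(sort(c(join, tl$ext)))),
               telomeres = c(setdiff(Tl, tl$ext), keep))
  }
  list(state = st,
       detail = paste0(site_label(s1), ";", site_label(s2), ";choice=", choice))
}

site_label <- function(s) {
  if (s$type == "adjacency") paste0("adj:", paste(gsub("\x1f", ".", s$ext), collapse = "+"))
  else paste0("tel:", gsub("\x1f", ".", s$ext))
}

# duplication: uniform source segment, Zipf length, uniform target position
random_duplication <- function(g, s) {
  occ <- occurrence_table(g)
  start <- sample.int(nrow(occ), 1L)
  ci <- occ$chrom[start]
  chr <- g$chromosomes[[ci]]
  len <- min(rzipf(1L, s), length(chr$marker) - occ$pos[start] + 1L)
  seg_idx <- occ$pos[start] + seq_len(len) - 1L
  seg_m <- chr$marker[seg_idx]
  seg_s <- chr$strand[seg_idx]
  # target: uniform over insertion slots of all chromosomes
  tgt <- random_slot(g)
  g$chromosomes[[tgt$chrom]] <- splice_chromosome(
    g$chromosomes[[tgt$chrom]], tgt$slot, seg_m, seg_s)
  list(genome = genome(g$name, g$chromosomes),
       detail = paste0("chrom=", ci, ";pos=", occ$pos[start], ";len=", len,
                       ";target=", tgt$chrom, ":", tgt$slot))
}

random_deletion <- function(g, s) {
  occ <- occurrence_table(g)
  start <- sample.int(nrow(occ), 1L)
  ci <- occ$chrom[start]
  chr <- g$chromosomes[[ci]]
  # truncate so at least one occurrence survives on the chromosome
  max_len <- length(chr$marker) - occ$pos[start] + 1L
  if (occ$pos[start] == 1L) max_len <- max_len - 1L
  if (max_len < 1L) return(NULL)
  len <- min(rzipf(1L, s), max_len)
  idx <- occ$pos[start] + seq_len(len) - 1L
  chr$marker <- chr$marker[-idx]
  chr$strand <- chr$strand[-idx]
  g$chromosomes[[ci]] <- chromosome(paste0(ifelse(chr$strand < 0, "-", ""),
                                           chr$marker),
                                    circular = chr$circular)
  list(genome = genome(g$name, g$chromosomes),
       detail = paste0("chrom=", ci, ";pos=", occ$pos[start], ";len=", len))
}

random_insertion <- function(g, s, counter) {
  len <- rzipf(1L, s)
  new_m <- paste0("ins", counter + seq_len(len))
  tgt <- random_slot(g)
  g$chromosomes[[tgt$chrom]] <- splice_chromosome(
    g$chromosomes[[tgt$chrom]], tgt$slot, new_m, rep(1L, len))
  list(genome = genome(g$name, g$chromosomes), counter = counter + len,
       detail = paste0("target=", tgt$chrom, ":", tgt$slot, ";len=", len,
                       ";first=", counter + 1L))
}

# uniform insertion slot: for a linear chromosome of length k there are
# k+1 slots (0..k), for a circular one k slots (1..k)
random_slot <- function(g) {
  slots <- vapply(g$chromosomes, function(ch)
    length(ch$marker) + if (ch$circular) 0L else 1L, integer(1))
  ci <- sample.int(length(slots), 1L, prob = slots)
  slot <- sample.int(slots[ci], 1L) - if (g$chromosomes[[ci]]$circular) 0L else 1L
  list(chrom = ci, slot = slot)
}

splice_chromosome <- function(chr, after, markers, strands) {
  m <- append(chr$marker, markers, after = after)
  st <- append(chr$strand, strands, after = after)
  chromosome(paste0(ifelse(st < 0, "-", ""), m), circular = chr$circular)
}

#' @export
print.dcj_sim_result <- function(x, ...) {
  cat("Simulation:", length(x$genomes), "genomes,", nrow(x$events), "events\n")
  invisible(x)
}

#' Registered worked-example genome pairs
#'
#' Returns the exact genome pairs used in the worked examples of the
#' distance theory: a pair of unichromosomal natural genomes with
#' duplicates (`sec2_running`, also available as `fig5`), a singular pair
#' with exclusive markers (`fig1`), a canonical two-chromosome pair
#' (`fig6`), and a singular pair whose diagram holds the four chained
#' recombination sources (`fig7`).
#'
#' @param name one of `"sec2_running"`, `"fig1"`, `"fig5"`, `"fig6"`,
#'   `"fig7"`.
#' @return list with genomes `A` and `B`.
#' @export
make_fixture <- function(name) {
  switch(name,
    sec2_running = ,
    fig5 = list(
      A = genome("A", list(c("1", "3", "2", "-5", "-4", "3", "5", "4"))),
      B = genome("B", list(c("1", "6", "2", "3", "1", "7", "3", "4", "1", "3")))),
    fig1 = list(
      A = genome("A", list(c("1", "-6", "5", "3"), c("4", "2"))),
      B = genome("B", list(c("1", "7", "2", "3", "4", "5"), c("7", "-8")))),
    fig6 = list(
      A = genome("A", list(c("2", "1"), c("4", "3"))),
      B = genome("B", list(c("1", "2"), c("3", "4")))),
    fig7 = list(
      A = genome("A", list(c("5", "2", "1"), c("5", "4", "5", "3"))),
      B = genome("B", list(c("6", "1", "6", "2"), c("3", "6", "4")))),
    stop("unknown fixture '", name, "'"))
}

#' Replay a logged event sequence on a genome
#'
#' Applies the events of one tree edge (in log order) to the parent
#' genome; the result equals the simulated child genome exactly, which is
#' the correctness contract of the event log.
#'
#' @param g parent `dcj_genome`.
#' @param events rows of the `events` log (a single edge, in order).
#' @return the resulting `dcj_genome`.
#' @export
replay_events <- function(g, events) {
  kv <- function(detail) {
    parts <- strsplit(detail, ";", fixed = TRUE)[[1]]
    stats::setNames(sub("^[^=]*=", "", parts), sub("=.*$", "", parts))
  }
  unsite <- function(txt) {
    if (startsWith(txt, "adj:")) {
      ext <- strsplit(sub("^adj:", "", txt), "+", fixed = TRUE)[[1]]
      list(type = "adjacency", ext = gsub(".", "\x1f", ext, fixed = TRUE))
    } else {
      list(type = "telomere", ext = gsub(".", "\x1f", sub("^tel:", "", txt), fixed = TRUE))
    }
  }
  apply_dcj_detail <- function(adj, detail) {
    parts <- strsplit(detail, ";", fixed = TRUE)[[1]]
    s1 <- unsite(parts[1]); s2 <- unsite(parts[2])
    choice <- as.integer(sub("choice=", "", parts[3]))
    A <- adj$adjacencies; Tl <- adj$telomeres
    match_adj <- function(ext) which(vapply(A, function(a)
      identical(sort(a), sort(ext)), logical(1)))[1]
    if (s1$type == "adjacency" && s2$type == "adjacency") {
      i <- match_adj(s1$ext); j <- match_adj(s2$ext)
      p <- A[[i]]; q <- A[[j]]
      rest <- A[-c(i, j)]
      newadj <- if (choice == 1L) list(sort(c(p[1], q[1])), sort(c(p[2], q[2])))
                else list(sort(c(p[1], q[2])), sort(c(p[2], q[1])))
      list(adjacencies = c(rest, newadj), telomeres = Tl)
    } else if (s1$type == "telomere" && s2$type == "telomere") {
      list(adjacencies = c(A, list(sort(c(s1$ext, s2$ext)))),
           telomeres = setdiff(Tl, c(s1$ext, s2$ext)))
    } else {
      ad <- if (s1$type == "adjacency") s1 else s2
      tl <- if (s1$type == "telomere") s1 else s2
      p <- ad$ext  # stored sorted, matching the logged orientation
      rest <- A[-match_adj(ad$ext)]
      keep <- if (choice == 1L) p[2] else p[1]
      join <- if (choice == 1L) p[1] else p[2]
      list(adjacencies = c(rest, list(sort(c(join, tl$ext)))),
           telomeres = c(setdiff(Tl, tl$ext), keep))
    }
  }
  r <- 1L
  while (r <= nrow(events)) {
    op <- events$op[r]
    detail <- events$detail[r]
    if (op == "dcj") {
      # consecutive DCJs act on one adjacency representation, exactly as
      # during simulation, so later chromosome indices line up
      adj <- genome_adjacencies(g)
      while (r <= nrow(events) && events$op[r] == "dcj") {
        adj <- apply_dcj_detail(adj, events$detail[r])
        r <- r + 1L
      }
      g <- genome_from_adjacencies(adj, g$name)
      next
    }
    if (op == "duplication") {
      d <- kv(detail)
      ci <- as.integer(d["chrom"]); pos <- as.integer(d["pos"])
      len <- as.integer(d["len"])
      tgt <- strsplit(d["target"], ":", fixed = TRUE)[[1]]
      chr <- g$chromosomes[[ci]]
      idx <- pos + seq_len(len) - 1L
      g$chromosomes[[as.integer(tgt[1])]] <- splice_chromosome(
        g$chromosomes[[as.integer(tgt[1])]], as.integer(tgt[2]),
        chr$marker[idx], chr$strand[idx])
      g <- genome(g$name, g$chromosomes)
    } else if (op == "deletion") {
      d <- kv(detail)
      ci <- as.integer(d["chrom"])
      chr <- g$chromosomes[[ci]]
      idx <- as.integer(d["pos"]) + seq_len(as.integer(d["len"])) - 1L
      chr$marker <- chr$marker[-idx]
      chr$strand <- chr$strand[-idx]
      g$chromosomes[[ci]] <- chromosome(
        paste0(ifelse(chr$strand < 0, "-", ""), chr$marker),
        circular = chr$circular)
      g <- genome(g$name, g$chromosomes)
    } else if (op == "insertion") {
      d <- kv(detail)
      len <- as.integer(d["len"])
      tgt <- strsplit(d["target"], ":", fixed = TRUE)[[1]]
      new_m <- paste0("ins", as.integer(d["first"]) + seq_len(len) - 1L)
      g$chromosomes[[as.integer(tgt[1])]] <- splice_chromosome(
        g$chromosomes[[as.integer(tgt[1])]], as.integer(tgt[2]),
        new_m, rep(1L, len))
      g <- genome(g$name, g$chromosomes)
    }
    r <- r + 1L
  }
  g
}
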