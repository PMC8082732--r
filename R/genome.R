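# Genome data model: chromosomes of signed marker occurrences, linear or
# circular, plus the marker census arithmetic that every other module
# consumes (multiplicities, Delta-Phi, common markers, n*, kappa, p*, a*).

RESERVED_CHARS <- c(">", "|", "(", ")")

#' Create a chromosome
#'
#' A chromosome is an ordered sequence of signed marker occurrences.
#' Tokens are arbitrary non-whitespace strings; a leading `-` marks reverse
#' orientation. Circular chromosomes are stored in a canonical form (the
#' lexicographically smallest rotation over both reading directions) so
#' that genome comparison is well defined.
#'
#' @param tokens character vector of signed marker tokens, e.g.
#'   `c("1", "-6", "5", "3")`.
#' @param circular logical; `TRUE` for a circular chromosome.
#' @return an object of class `dcj_chromosome` with fields `marker`
#'   (character), `strand` (+1/-1 integer) and `circular`.
#' @export
chromosome <- function(tokens, circular = FALSE) {
  if (length(tokens) == 0L) stop("empty chromosome")
  tokens <- as.character(tokens)
  strand <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  marker <- sub("^-", "", tokens)
  if (any(marker == "")) stop("empty marker token")
  bad <- vapply(RESERVED_CHARS, function(ch) any(grepl(ch, marker, fixed = TRUE)), logical(1))
  if (any(grepl("-", marker, fixed = TRUE)) || any(bad))
    stop("marker token contains reserved character ('>', '|', '(', ')' or '-')")
  chr <- structure(list(marker = marker, strand = strand, circular = isTRUE(circular)),
                   class = "dcj_chromosome")
  if (chr$circular) chr <- canonicalize_circular(chr)
  chr
}

chrom_tokens <- function(chr) {
  paste0(ifelse(chr$strand < 0L, "-", ""), chr$marker)
}

chrom_key <- function(chr) {
  paste(c(if (chr$circular) "O" else "I", chrom_tokens(chr)), collapse = " ")
}

# Reverse reading direction: reverse order and flip strands.
chrom_reverse <- function(chr) {
  chr$marker <- rev(chr$marker)
  chr$strand <- -rev(chr$strand)
  chr
}

# Canonical circular form: lexicographically smallest token string over all
# rotations of both reading directions.
canonicalize_circular <- function(chr) {
  n <- length(chr$marker)
  best <- NULL
  best_key <- NULL
  for (cand in list(chr, chrom_reverse(chr))) {
    for (r in seq_len(n)) {
      idx <- c(seq(r, n), if (r > 1L) seq_len(r - 1L))
      rot <- cand
      rot$marker <- cand$marker[idx]
      rot$strand <- cand$strand[idx]
      key <- paste(chrom_tokens(rot), collapse = " ")
      if (is.null(best_key) || key < best_key) {
        best <- rot
        best_key <- key
      }
    }
  }
  best
}

#' Create a genome
#'
#' @param name genome name (single string).
#' @param chromosomes list of [chromosome()] objects, or character vectors
#'   (interpreted as linear chromosomes).
#' @return an object of class `dcj_genome`.
#' @examples
#' g <- genome("A", list(c("1", "-6", "5", "3"), c("4", "2")))
#' @export
genome <- function(name, chromosomes) {
  if (!is.list(chromosomes) || length(chromosomes) == 0L)
    chromosomes <- list(chromosomes)
  chromosomes <- lapply(chromosomes, function(ch) {
    if (inherits(ch, "dcj_chromosome")) ch else chromosome(ch)
  })
  if (sum(vapply(chromosomes, function(ch) length(ch$marker), integer(1))) < 1L)
    stop("genome must contain at least one marker occurrence")
  structure(list(name = as.character(name), chromosomes = chromosomes),
            class = "dcj_genome")
}

#' @export
print.dcj_genome <- function(x, ...) {
  cat(">", x$name, "\n", sep = "")
  for (chr in x$chromosomes)
    cat(paste(chrom_tokens(chr), collapse = " "),
        if (chr$circular) ")" else "|", "\n")
  invisible(x)
}

#' Number of linear chromosomes of a genome
#' @param g a `dcj_genome`.
#' @return integer count (the kappa of the capping theory).
#' @export
n_linear <- function(g) {
  sum(!vapply(g$chromosomes, function(ch) ch$circular, logical(1)))
}

n_occurrences <- function(g) {
  sum(vapply(g$chromosomes, function(ch) length(ch$marker), integer(1)))
}

marker_counts <- function(g) {
  tab <- table(unlist(lapply(g$chromosomes, function(ch) ch$marker)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Test two genomes for equality as marker-order genomes
#'
#' Chromosomes compare up to full reversal and, for circular chromosomes,
#' rotation; chromosome order within a genome is immaterial.
#' @param a,b `dcj_genome` objects.
#' @return logical.
#' @export
genomes_equal <- function(a, b) {
  keys <- function(g) sort(vapply(g$chromosomes, function(ch) {
    if (!ch$circular) {
      # linear: canonical = lexicographically smaller of the two readings
      k1 <- chrom_key(ch)
      k2 <- chrom_key(chrom_reverse(ch))
      min(k1, k2)
    } else chrom_key(ch)
  }, character(1)))
  identical(unname(keys(a)), unname(keys(b)))
}

# Occurrence table: one row per marker occurrence in reading order, with the
# occurrence index (1..Phi(marker)) used for diagram vertex identity.
occurrence_table <- function(g) {
  chrom <- integer(0); pos <- integer(0); marker <- character(0)
  strand <- integer(0); circular <- logical(0)
  for (ci in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[ci]]
    k <- length(ch$marker)
    chrom <- c(chrom, rep.int(ci, k))
    pos <- c(pos, seq_len(k))
    marker <- c(marker, ch$marker)
    strand <- c(strand, ch$strand)
    circular <- c(circular, rep.int(ch$circular, k))
  }
  occ <- stats::ave(seq_along(marker), marker, FUN = seq_along)
  data.frame(chrom = chrom, pos = pos, marker = marker, strand = strand,
             circular = circular, occ = as.integer(occ),
             stringsAsFactors = FALSE)
}

# --- file I/O: UniMoG dialect -----------------------------------------------

#' Parse genomes from a UniMoG-style genome file
#'
#' The dialect: a line `>name` introduces a genome; chromosomes are
#' whitespace-separated signed marker tokens terminated by `|` (linear) or
#' `)` (circular); `-` prefixes reverse orientation; `#` starts a comment.
#'
#' @param input path to a file, or a character vector of lines when
#'   `text = TRUE`.
#' @param text logical; treat `input` as the file content itself.
#' @return named list of [genome()] objects, in file order.
#' @export
parse_genomes <- function(input, text = FALSE) {
  lines <- if (text) unlist(strsplit(input, "\n", fixed = TRUE)) else readLines(input)
  lines <- sub("#.*$", "", lines)
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  pending <- character(0)
  flush_genome <- function() {
    if (is.null(cur_name)) return()
    if (length(pending) > 0L)
      stop("unterminated chromosome in genome '", cur_name,
           "' (last token must be '|' or ')')")
    if (length(cur_chroms) == 0L)
      stop("genome '", cur_name, "' has no chromosomes")
    if (cur_name %in% names(genomes))
      stop("duplicate genome name '", cur_name, "'")
    genomes[[cur_name]] <<- genome(cur_name, cur_chroms)
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, ">")) {
      flush_genome()
      cur_name <- trimws(sub("^>", "", line))
      if (cur_name == "") stop("empty genome name after '>'")
      cur_chroms <- list()
      pending <- character(0)
      next
    }
    if (is.null(cur_name)) stop("marker data before any '>' header")
    # terminators may be attached to the last token; detach them
    line <- gsub("([|)])", " \\1 ", line)
    for (tok in strsplit(line, "\\s+")[[1]]) {
      if (tok == "") next
      if (tok %in% c("|", ")")) {
        if (length(pending) == 0L) stop("empty chromosome in genome '", cur_name, "'")
        cur_chroms[[length(cur_chroms) + 1L]] <-
          chromosome(pending, circular = (tok == ")"))
        pending <- character(0)
      } else {
        pending <- c(pending, tok)
      }
    }
  }
  flush_genome()
  genomes
}

#' Write genomes in the UniMoG dialect
#'
#' @param genomes a `dcj_genome` or list of them.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of lines, invisibly when writing to a file.
#' @export
write_genomes <- function(genomes, path = NULL) {
  if (inherits(genomes, "dcj_genome")) genomes <- list(genomes)
  lines <- unlist(lapply(genomes, function(g) {
    c(paste0(">", g$name),
      vapply(g$chromosomes, function(ch)
        paste(c(chrom_tokens(ch), if (ch$circular) ")" else "|"), collapse = " "),
        character(1)))
  }))
  lines <- unname(lines)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# --- marker census ----------------------------------------------------------

#' Marker census of a genome pair
#'
#' Tabulates, for two genomes, the per-marker multiplicities Phi_A and
#' Phi_B, their difference Delta-Phi, the set of common markers, the number
#' of matched occurrences `n_star = sum over common m of min(Phi_A, Phi_B)`,
#' the linear chromosome counts kappa_A/kappa_B, and the capping quantities
#' `p_star = max(kappa_A, kappa_B)` (caps) and `a_star = |kappa_A - kappa_B|`
#' (artificial adjacencies, placed in the genome with fewer linear
#' chromosomes).
#'
#' @param A,B `dcj_genome` objects.
#' @return object of class `dcj_census`; see also [as.data.frame.dcj_census()].
#' @export
census <- function(A, B) {
  cA <- marker_counts(A)
  cB <- marker_counts(B)
  universe <- sort(unique(c(names(cA), names(cB))))
  phiA <- stats::setNames(integer(length(universe)), universe)
  phiB <- phiA
  phiA[names(cA)] <- cA
  phiB[names(cB)] <- cB
  common <- universe[phiA > 0L & phiB > 0L]
  kA <- n_linear(A)
  kB <- n_linear(B)
  structure(list(
    phiA = phiA, phiB = phiB, deltaPhi = phiA - phiB,
    common = common, exclusive = setdiff(universe, common),
    n_star = sum(pmin(phiA[common], phiB[common])),
    kappaA = kA, kappaB = kB,
    p_star = max(kA, kB), a_star = abs(kA - kB),
    a_star_side = if (kA == kB) "none" else if (kA < kB) "A" else "B"
  ), class = "dcj_census")
}

#' @export
print.dcj_census <- function(x, ...) {
  cat("Marker census: |G| =", length(x$common),
      "common markers, n* =", x$n_star, "\n")
  cat("kappa_A =", x$kappaA, " kappa_B =", x$kappaB,
      " p* =", x$p_star, " a* =", x$a_star, "(side", x$a_star_side, ")\n")
  invisible(x)
}

#' @describeIn census one row per marker with Phi_A, Phi_B, Delta-Phi and
#'   common-marker status.
#' @param x a `dcj_census`.
#' @param ... unused.
#' @export
as.data.frame.dcj_census <- function(x, ...) {
  data.frame(marker = names(x$phiA), phiA = unname(x$phiA),
             phiB = unname(x$phiB), deltaPhi = unname(x$deltaPhi),
             common = names(x$phiA) %in% x$common,
             stringsAsFactors = FALSE)
}

# whether each common marker occurs exactly once in each genome
is_singular_pair <- function(cn) {
  all(cn$phiA[cn$common] == 1L & cn$phiB[cn$common] == 1L)
}

# --- PHYLIP distance matrix -------------------------------------------------

#' Write a PHYLIP square distance matrix
#'
#' @param names taxon names.
#' @param D symmetric numeric matrix with zero diagonal.
#' @param path optional output file.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_distance_matrix <- function(names, D, path = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != length(names) || ncol(D) != length(names))
    stop("matrix dimensions do not match the number of names")
  if (any(D != t(D))) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  nm <- formatC(names, width = 10, flag = "-")
  lines <- c(as.character(length(names)),
             vapply(seq_along(names), function(i)
               paste0(nm[i], paste(D[i, ], collapse = " ")), character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a PHYLIP square distance matrix
#'
#' @param input path, or character lines with `text = TRUE`.
#' @param text logical.
#' @return numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(input, text = FALSE) {
  lines <- if (text) input else readLines(input)
  lines <- lines[trimws(lines) != ""]
  n <- as.integer(trimws(lines[1]))
  vals <- matrix(0, n, n)
  nms <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    nms[i] <- parts[1]
    vals[i, ] <- as.numeric(parts[-1])
  }
  dimnames(vals) <- list(nms, nms)
  vals
}
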