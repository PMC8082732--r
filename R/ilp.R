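# ILP for an optimal consistent cycle decomposition of the capped
# multi-relational diagram. Variables:
#   x_e  edge selected (adjacency and artificial edges are fixed to 1)
#   y_i  cycle label of vertex i, 0 <= y_i <= i; equal along selected
#        edges, forced to 0 on indel-enclosing cycles
#   z_i  1 only if y_i = i: counts indel-free cycles
#   r_v  run label (0 = A-run, 1 = B-run)
#   t_e  transition observed on an A-adjacency next to an A-indel edge
#   s_k  circular chromosome k is a singleton
# Objective: maximize sum z - 1/2 sum t - sum s; the DCJ-indel distance is
# n* + p* - objective.

#' Build the ILP over a capped multi-relational diagram
#'
#' @param diagram a capped `dcj_diagram` from
#'   `build_multi_relational(A, B, capped = TRUE)`.
#' @return object of class `dcj_ilp`: variable table, sparse constraint
#'   triplets, row metadata and bookkeeping for decoding solutions.
#' @export
build_ilp <- function(diagram) {
  if (!diagram$capped) stop("build_ilp() needs a capped diagram")
  ed <- diagram$edges
  vt <- diagram$vertices
  nE <- nrow(ed)
  nV <- nrow(vt)

  forced <- ed$kind %in% c("adjacency", "artificial")

  # variable bookkeeping: index into a single variable vector
  var_name <- character(0); var_type <- character(0)
  var_lb <- numeric(0); var_ub <- numeric(0); var_obj <- numeric(0)
  new_var <- function(name, type, lb, ub, obj) {
    var_name <<- c(var_name, name); var_type <<- c(var_type, type)
    var_lb <<- c(var_lb, lb); var_ub <<- c(var_ub, ub); var_obj <<- c(var_obj, obj)
    length(var_name)
  }
  x_of <- rep(NA_integer_, nE)
  for (e in which(!forced))
    x_of[e] <- new_var(paste0("x", e), "B", 0, 1, 0)
  y_of <- vapply(seq_len(nV), function(i)
    new_var(paste0("y", i), "I", 0, i, 0), integer(1))
  z_of <- vapply(seq_len(nV), function(i)
    new_var(paste0("z", i), "B", 0, 1, 1), integer(1))
  r_of <- vapply(seq_len(nV), function(i)
    new_var(paste0("r", i), "B", 0, 1, 0), integer(1))

  # transition-eligible edges: A-adjacencies sharing a vertex with an
  # A-indel edge (the canonization places every transition there)
  indel_vertsA <- unique(c(ed$v1[ed$kind == "indel" & ed$genome == "A"],
                           ed$v2[ed$kind == "indel" & ed$genome == "A"]))
  indel_verts <- unique(c(ed$v1[ed$kind == "indel"], ed$v2[ed$kind == "indel"]))
  eligible <- which(ed$kind == "adjacency" & ed$genome == "A" &
                    (ed$v1 %in% indel_vertsA | ed$v2 %in% indel_vertsA))
  t_of <- rep(NA_integer_, nE)
  for (e in eligible)
    t_of[e] <- new_var(paste0("t", e), "B", 0, 1, -0.5)

  # circular chromosomes in which every occurrence carries an indel edge
  # (the only candidates for circular singletons)
  sk <- list()
  occ_sides <- list(A = occurrence_table(diagram$A), B = occurrence_table(diagram$B))
  for (side in c("A", "B")) {
    g <- if (side == "A") diagram$A else diagram$B
    occ <- occ_sides[[side]]
    dphi <- diagram$census$deltaPhi
    for (ci in seq_along(g$chromosomes)) {
      if (!g$chromosomes[[ci]]$circular) next
      mk <- occ$marker[occ$chrom == ci]
      over <- if (side == "A") all(dphi[mk] > 0L) else all(dphi[mk] < 0L)
      if (!over) next
      e_k <- which(ed$kind == "indel" & ed$genome == side & ed$chrom == ci)
      sk[[length(sk) + 1L]] <- list(
        var = new_var(paste0("s", side, ci), "B", 0, 1, -1),
        edges = e_k)
    }
  }

  # sparse constraints: triplets (row, var, coef) + row sense/rhs
  ri <- integer(0); vi <- integer(0); cf <- numeric(0)
  sense <- character(0); rhs <- numeric(0); nrow_ <- 0L
  add_row <- function(vars, coefs, sns, b) {
    nrow_ <<- nrow_ + 1L
    ri <<- c(ri, rep.int(nrow_, length(vars)))
    vi <<- c(vi, vars); cf <<- c(cf, coefs)
    sense <<- c(sense, sns); rhs <<- c(rhs, b)
  }

  # C.02 vertex degree 2 (forced edges contribute constants)
  inc <- vector("list", nV)
  base_deg <- integer(nV)
  for (e in seq_len(nE)) {
    for (v in c(ed$v1[e], ed$v2[e])) {
      if (forced[e]) base_deg[v] <- base_deg[v] + 1L
      else inc[[v]] <- c(inc[[v]], x_of[e])
    }
  }
  for (v in seq_len(nV)) {
    if (length(inc[[v]]) == 0L) {
      if (base_deg[v] != 2L) stop("vertex ", v, " cannot reach degree 2")
      next
    }
    add_row(inc[[v]], rep(1, length(inc[[v]])), "E", 2 - base_deg[v])
  }

  # C.03 siblings selected together
  for (e in which(ed$kind == "extremity")) {
    s <- ed$sib[e]
    if (e < s) add_row(c(x_of[e], x_of[s]), c(1, -1), "E", 0)
  }

  # C.04 equal labels along selected edges: y_i <= y_j + i (1 - x_e)
  for (e in seq_len(nE)) {
    i <- ed$v1[e]; j <- ed$v2[e]
    yi <- y_of[i]; yj <- y_of[j]
    if (forced[e]) {
      add_row(c(yi, yj), c(1, -1), "E", 0)
    } else {
      add_row(c(yi, yj, x_of[e]), c(1, -1, i), "L", i)
      add_row(c(yj, yi, x_of[e]), c(1, -1, j), "L", j)
    }
  }

  # C.05 selected indel edge zeroes its cycle label
  for (e in which(ed$kind == "indel")) {
    for (v in c(ed$v1[e], ed$v2[e]))
      add_row(c(y_of[v], x_of[e]), c(1, v), "L", v)
  }

  # C.06 z_i = 1 only if y_i = i
  for (i in seq_len(nV))
    add_row(c(z_of[i], y_of[i]), c(i, -1), "L", 0)

  # C.07 run labels pinned at selected indel edges (0 in A, 1 in B)
  for (e in which(ed$kind == "indel")) {
    for (v in c(ed$v1[e], ed$v2[e])) {
      if (ed$genome[e] == "A") add_row(c(r_of[v], x_of[e]), c(1, 1), "L", 1)
      else add_row(c(x_of[e], r_of[v]), c(1, -1), "L", 0)
    }
  }

  # C.08 transitions recorded on eligible edges (always selected)
  for (e in eligible) {
    u <- ed$v1[e]; v <- ed$v2[e]
    add_row(c(r_of[u], r_of[v], t_of[e]), c(1, -1, -1), "L", 0)
    add_row(c(r_of[v], r_of[u], t_of[e]), c(1, -1, -1), "L", 0)
  }

  # C.09 run label constant across adjacencies not touching an indel edge
  for (e in which(forced)) {
    if (ed$v1[e] %in% indel_verts || ed$v2[e] %in% indel_verts) next
    if (e %in% eligible) next
    add_row(c(r_of[ed$v1[e]], r_of[ed$v2[e]]), c(1, -1), "E", 0)
  }

  # C.10 label changes prohibited on selected non-adjacency edges
  # (indel edges are already pinned by C.07)
  for (e in which(ed$kind %in% c("extremity", "cap"))) {
    u <- ed$v1[e]; v <- ed$v2[e]
    add_row(c(r_of[u], r_of[v], x_of[e]), c(1, -1, 1), "L", 1)
    add_row(c(r_of[v], r_of[u], x_of[e]), c(1, -1, 1), "L", 1)
  }
  # ... and on B-adjacencies that do touch an indel edge
  for (e in which(forced)) {
    if (ed$genome[e] != "B") next
    if (!(ed$v1[e] %in% indel_verts || ed$v2[e] %in% indel_verts)) next
    add_row(c(r_of[ed$v1[e]], r_of[ed$v2[e]]), c(1, -1), "E", 0)
  }

  # C.11 circular singleton detection
  for (s in sk) {
    if (length(s$edges) == 0L) next
    add_row(c(x_of[s$edges], s$var), c(rep(1, length(s$edges)), -1),
            "L", length(s$edges) - 1)
  }

  structure(list(
    vars = data.frame(name = var_name, type = var_type, lb = var_lb,
                      ub = var_ub, obj = var_obj, stringsAsFactors = FALSE),
    con = list(row = ri, var = vi, coef = cf, sense = sense, rhs = rhs,
               n = nrow_),
    x_of = x_of, forced = forced, t_of = t_of,
    s_vars = vapply(sk, function(s) s$var, integer(1)),
    diagram = diagram,
    n_star = diagram$census$n_star, p_star = diagram$census$p_star
  ), class = "dcj_ilp")
}

#' @export
print.dcj_ilp <- function(x, ...) {
  cat("DCJ-indel ILP:", nrow(x$vars), "variables,", x$con$n, "constraints\n")
  invisible(x)
}

#' Solve a DCJ-indel ILP with the GLPK standalone solver
#'
#' @param model a `dcj_ilp` from [build_ilp()].
#' @param time_limit time limit in seconds (`Inf` for none).
#' @param threads accepted for interface compatibility; glpsol is
#'   single-threaded.
#' @param seed accepted for interface compatibility; glpsol's
#'   branch-and-cut is deterministic.
#' @param glpsol path to the glpsol binary.
#' @param relax solve the LP relaxation instead of the MIP (bound check).
#' @param keep_files optional directory to keep the LP/solution files in.
#' @return object of class `dcj_ilp_solution`: `status` (optimal,
#'   feasible_gap, infeasible, timeout_no_solution), `objective`,
#'   `distance`, `gap`, `bounds`, the selected edge set, the decoded
#'   component summary, and diagnostics.
#' @export
solve_ilp <- function(model, time_limit = Inf, threads = 1L, seed = NULL,
                      glpsol = Sys.which("glpsol"), relax = FALSE,
                      keep_files = NULL) {
  if (!nzchar(glpsol)) stop("glpsol binary not found; install GLPK")
  dir <- if (is.null(keep_files)) tempfile("dcjilp") else keep_files
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- file.path(dir, "model.lp")
  sol <- file.path(dir, "model.sol")
  writeLines(write_lp(model), lp)
  args <- c("--lp", lp, "-o", sol)
  if (relax) args <- c(args, "--nomip")
  if (is.finite(time_limit)) args <- c(args, "--tmlim", as.integer(time_limit))
  t0 <- Sys.time()
  log <- suppressWarnings(system2(glpsol, args, stdout = TRUE, stderr = TRUE))
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!file.exists(sol)) stop("glpsol produced no solution file:\n",
                              paste(utils::tail(log, 5), collapse = "\n"))
  parsed <- parse_glpsol_solution(readLines(sol))
  if (relax) {
    if (is.null(keep_files)) unlink(dir, recursive = TRUE)
    return(structure(list(status = tolower(parsed$status),
                          objective = parsed$objective, relaxation = TRUE,
                          runtime = runtime),
                     class = "dcj_ilp_solution"))
  }
  status <- switch(parsed$status,
                   "INTEGER OPTIMAL" = "optimal",
                   "INTEGER NON-OPTIMAL" = "feasible_gap",
                   "INTEGER EMPTY" = "infeasible",
                   "timeout_no_solution")
  if (!status %in% c("optimal", "feasible_gap")) parsed$objective <- NA_real_
  out <- list(status = status, objective = parsed$objective,
              gap = parse_glpsol_gap(log, status),
              n_star = model$n_star, p_star = model$p_star,
              distance = NA_integer_, bounds = c(NA_real_, NA_real_),
              runtime = runtime,
              n_variables = nrow(model$vars), n_constraints = model$con$n,
              solver = "glpsol", threads = 1L)
  if (status %in% c("optimal", "feasible_gap")) {
    vals <- parsed$values[model$vars$name]
    sel <- which(model$forced)
    xs <- model$x_of[!is.na(model$x_of)]
    sel <- sort(c(sel, which(!is.na(model$x_of))[vals[model$vars$name[xs]] > 0.5]))
    comps <- decompose(model$diagram, sel)
    out$selected <- sel
    out$components <- components_summary(comps)
    ed <- model$diagram$edges
    out$selected_siblings <- sel[ed$kind[sel] == "extremity"]
    out$selected_caps <- sel[ed$kind[sel] == "cap"]
    d <- model$n_star + model$p_star - parsed$objective
    out$distance <- as.integer(round(d))
    if (status == "feasible_gap") {
      # primal gives an upper bound on the distance, dual a lower bound
      out$bounds <- c(model$n_star + model$p_star - parsed$dual_bound,
                      d)
    }
  }
  if (is.null(keep_files)) unlink(dir, recursive = TRUE)
  structure(out, class = "dcj_ilp_solution")
}

#' @export
print.dcj_ilp_solution <- function(x, ...) {
  cat("ILP solution: status =", x$status,
      " distance =", x$distance,
      " objective =", x$objective,
      " gap =", x$gap, "\n")
  invisible(x)
}

#' DCJ-indel distance of natural genomes
#'
#' Convenience composition: marker census, capped multi-relational diagram,
#' ILP construction and solve.
#'
#' @param A,B `dcj_genome` objects (arbitrary marker multiplicities).
#' @param time_limit,threads,seed,glpsol passed to [solve_ilp()].
#' @return a `dcj_ilp_solution` with additional census fields
#'   (`n_star`, `p_star`, duplicate-occurrence statistics).
#' @export
distance_natural <- function(A, B, time_limit = Inf, threads = 1L,
                             seed = NULL, glpsol = Sys.which("glpsol")) {
  dg <- build_multi_relational(A, B, capped = TRUE)
  model <- build_ilp(dg)
  out <- solve_ilp(model, time_limit = time_limit, threads = threads,
                   seed = seed, glpsol = glpsol)
  cn <- dg$census
  dupA <- cn$phiA[cn$phiA > 1L]
  dupB <- cn$phiB[cn$phiB > 1L]
  out$duplicate_markers <- length(unique(c(names(dupA), names(dupB))))
  out$duplicate_occurrences <- sum(dupA) + sum(dupB)
  out$max_multiplicity <- max(c(cn$phiA, cn$phiB))
  out
}

#' Machine-readable report of an ILP solution
#' @param sol a `dcj_ilp_solution`.
#' @return list ready for JSON serialization.
#' @export
solution_report <- function(sol) {
  list(schema = "dcjindel/report/1",
       distance = sol$distance, status = sol$status, gap = sol$gap,
       bounds = sol$bounds,
       n_star = sol$n_star, p_star = sol$p_star,
       duplicate_markers = sol$duplicate_markers,
       duplicate_occurrences = sol$duplicate_occurrences,
       max_multiplicity = sol$max_multiplicity,
       objective = sol$objective, runtime = sol$runtime,
       n_variables = sol$n_variables, n_constraints = sol$n_constraints,
       solver = sol$solver)
}
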