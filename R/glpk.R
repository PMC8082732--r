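# CPLEX-LP writing and glpsol output parsing.

#' Serialize a `dcj_ilp` model in CPLEX LP format
#' @param model a `dcj_ilp`.
#' @return character vector of LP-file lines.
#' @export
write_lp <- function(model) {
  v <- model$vars
  term <- function(coef, name) {
    sprintf("%s %s %s", ifelse(coef < 0, "-", "+"),
            format(abs(coef), scientific = FALSE), name)
  }
  obj_idx <- which(v$obj != 0)
  obj_line <- if (length(obj_idx) == 0L) "+ 0 y1"
              else paste(term(v$obj[obj_idx], v$name[obj_idx]), collapse = " ")

  con <- model$con
  ord <- order(con$row)
  row_terms <- vapply(split(paste(term(con$coef[ord], v$name[con$var[ord]])),
                            con$row[ord]),
                      paste, "", collapse = " ")
  sense_txt <- c(E = "=", L = "<=", G = ">=")[con$sense]
  con_lines <- sprintf(" c%s: %s %s %s", seq_len(con$n),
                       row_terms[as.character(seq_len(con$n))],
                       sense_txt, format(con$rhs, scientific = FALSE))

  int_idx <- which(v$type == "I")
  bin_idx <- which(v$type == "B")
  bound_lines <- sprintf(" 0 <= %s <= %s", v$name[int_idx],
                         format(v$ub[int_idx], scientific = FALSE))
  c("Maximize",
    paste(" obj:", obj_line),
    "Subject To",
    con_lines,
    "Bounds",
    bound_lines,
    "Generals",
    paste(" ", v$name[int_idx]),
    "Binaries",
    paste(" ", v$name[bin_idx]),
    "End")
}

# parse a glpsol "-o" solution file: status, objective, column activities
parse_glpsol_solution <- function(lines) {
  status <- sub("^Status:\\s*", "", grep("^Status:", lines, value = TRUE)[1])
  obj_line <- grep("^Objective:", lines, value = TRUE)[1]
  objective <- as.numeric(sub(".*=\\s*([-0-9.eE+]+)\\s*\\(.*", "\\1", obj_line))
  col_hdr <- grep("No\\. +Column name", lines)
  values <- numeric(0)
  if (length(col_hdr) == 1L) {
    i <- col_hdr + 2L
    nms <- character(0); act <- numeric(0)
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      # fields: No, name, [status marker(s),] activity, [bounds...]
      a <- suppressWarnings(as.numeric(f[3]))
      a <- if (is.na(a)) f[4] else f[3]
      nms <- c(nms, f[2]); act <- c(act, as.numeric(a))
      i <- i + 1L
    }
    values <- stats::setNames(act, nms)
  }
  list(status = trimws(status), objective = objective, values = values,
       dual_bound = NA_real_)
}

# best-effort optimality gap from the glpsol log (percentage/100);
# 0 for proven optima
parse_glpsol_gap <- function(log, status) {
  if (identical(status, "optimal")) return(0)
  hits <- regmatches(log, regexpr("[0-9.]+%", log))
  hits <- hits[lengths(regmatches(log, gregexpr("%", log))) > 0]
  pct <- suppressWarnings(as.numeric(sub("%", "", unlist(hits))))
  pct <- pct[is.finite(pct)]
  if (length(pct) == 0L) return(NA_real_)
  utils::tail(pct, 1) / 100
}
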