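#' Sparse node-pair similarity
#'
#' Holds nonnegative similarities `sim(u, v)` in \[0, 1\] between query-side
#' and target-side nodes. Absent pairs have similarity 0. Duplicated pairs
#' keep the maximum value (with a warning).
#'
#' @param entries data frame with columns `q`, `t`, `s`.
#' @return an object of class `rnq_sim`.
#' @export
similarity_matrix <- function(entries = NULL) {
  if (is.null(entries) || nrow(entries) == 0) {
    entries <- data.frame(q = character(), t = character(), s = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    entries <- as.data.frame(entries, stringsAsFactors = FALSE)
    if (!all(c("q", "t", "s") %in% names(entries)))
      abort_validation("similarity entries need columns q, t, s")
    entries$q <- as.character(entries$q)
    entries$t <- as.character(entries$t)
    entries$s <- as.numeric(entries$s)
    if (anyNA(entries$s) || any(entries$s < 0 | entries$s > 1))
      abort_validation("similarity values must lie in [0, 1]")
    key <- paste(entries$q, entries$t, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate similarity pairs: keeping the maximum value",
              call. = FALSE)
      s <- tapply(entries$s, key, max)
      parts <- strsplit(names(s), "\r", fixed = TRUE)
      entries <- data.frame(q = vapply(parts, `[`, "", 1L),
                            t = vapply(parts, `[`, "", 2L),
                            s = as.numeric(s), stringsAsFactors = FALSE)
    }
    entries <- entries[order(entries$q, entries$t), , drop = FALSE]
    entries <- data.frame(q = entries$q, t = entries$t, s = entries$s,
                          stringsAsFactors = FALSE)   # drop stray attributes
  }
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(entries)))
  if (nrow(entries) > 0)
    for (i in seq_len(nrow(entries)))
      assign(paste(entries$q[i], entries$t[i], sep = "\r"), entries$s[i],
             envir = env)
  structure(list(entries = entries, env = env), class = "rnq_sim")
}

#' @export
print.rnq_sim <- function(x, ...) {
  cat(sprintf("<similarity: %d stored pairs>\n", nrow(x$entries)))
  invisible(x)
}

#' Look up a similarity value
#'
#' @param sim an `rnq_sim`.
#' @param q,t node identifiers (query side / target side).
#' @return the stored similarity, or 0 for an absent pair.
#' @export
sim_value <- function(sim, q, t) {
  val <- get0(paste(q, t, sep = "\r"), envir = sim$env, ifnotfound = 0)
  val
}

# dense matrix view for a given node ordering; absent pairs are 0
sim_dense <- function(sim, qnodes, tnodes) {
  m <- matrix(0, nrow = length(qnodes), ncol = length(tnodes),
              dimnames = list(qnodes, tnodes))
  e <- sim$entries
  keep <- e$q %in% qnodes & e$t %in% tnodes
  e <- e[keep, , drop = FALSE]
  if (nrow(e) > 0) m[cbind(match(e$q, qnodes), match(e$t, tnodes))] <- e$s
  m
}

# restrict the stored pairs to given query-side and/or target-side nodes
restrict_sim <- function(sim, qnodes = NULL, tnodes = NULL) {
  e <- sim$entries
  if (!is.null(qnodes)) e <- e[e$q %in% qnodes, , drop = FALSE]
  if (!is.null(tnodes)) e <- e[e$t %in% tnodes, , drop = FALSE]
  similarity_matrix(e)
}

#' Read a similarity table from a 3-column TSV file
#'
#' Each line is `q_node<TAB>t_node<TAB>sim`. Duplicate pairs keep the
#' maximum value with a warning; values outside \[0, 1\] are an error.
#'
#' @param path file path.
#' @return an `rnq_sim`.
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  qs <- character(0); ts <- character(0); ss <- numeric(0)
  for (i in idx) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 3)
      abort_parse(sprintf("line %d: expected 'q t sim'", i))
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s)) abort_parse(sprintf("line %d: similarity not numeric", i))
    if (s < 0 || s > 1)
      abort_validation(sprintf("line %d: similarity %g outside [0, 1]", i, s))
    qs <- c(qs, f[1]); ts <- c(ts, f[2]); ss <- c(ss, s)
  }
  similarity_matrix(data.frame(q = qs, t = ts, s = ss,
                               stringsAsFactors = FALSE))
}

#' Write a similarity table to a 3-column TSV file
#'
#' @param sim an `rnq_sim`.
#' @param path output file path.
#' @export
write_similarity <- function(sim, path) {
  e <- sim$entries
  lines <- sprintf("%s\t%s\t%s", e$q, e$t,
                   formatC(e$s, format = "g", digits = 17))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(x) FALSE, warning = function(x) FALSE)
  if (!ok) abort_io(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Convert BLAST-style E-values to normalized similarities
#'
#' Similarity is the normalized negative logarithm of the E-value:
#' `sim = max(0, -log10(max(E, floor))) / -log10(floor)`, so `E <= floor`
#' maps to 1 and `E >= 1` maps to 0. The floor is the E-value treated as
#' maximal similarity.
#'
#' @param evalues data frame with columns `q`, `t`, `evalue` (positive).
#' @param floor E-value floor, default `1e-180`.
#' @return an `rnq_sim`.
#' @export
similarity_from_evalues <- function(evalues, floor = 1e-180) {
  evalues <- as.data.frame(evalues, stringsAsFactors = FALSE)
  if (!all(c("q", "t", "evalue") %in% names(evalues)))
    abort_validation("evalues needs columns q, t, evalue")
  e <- as.numeric(evalues$evalue)
  if (anyNA(e) || any(e <= 0))
    abort_validation("E-values must be positive")
  if (floor <= 0 || floor >= 1) abort_validation("floor must be in (0, 1)")
  raw <- -log10(pmax(e, floor))
  s <- pmax(raw, 0) / (-log10(floor))
  similarity_matrix(data.frame(q = as.character(evalues$q),
                               t = as.character(evalues$t),
                               s = s, stringsAsFactors = FALSE))
}
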