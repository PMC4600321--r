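#' Scoring parameters for tree alignment
#'
#' Per-node insertion and deletion penalties (nonpositive), caps on the
#' number of indels, and the color-coding confidence level.
#'
#' @param delta_ins per-insertion penalty, `<= 0`. Default -0.5.
#' @param delta_del per-deletion penalty, `<= 0`. Default -0.5.
#' @param max_ins maximum number of inserted target nodes. Default 2.
#' @param max_del maximum number of deleted query nodes. Default 2.
#' @param confidence probability that the returned alignment is optimal,
#'   in (0, 1). Default 0.99.
#' @return an object of class `rnq_params`.
#' @export
scoring_params <- function(delta_ins = -0.5, delta_del = -0.5,
                           max_ins = 2L, max_del = 2L, confidence = 0.99) {
  if (delta_ins > 0 || delta_del > 0)
    abort_validation("indel penalties must be <= 0")
  if (max_ins < 0 || max_del < 0)
    abort_validation("indel caps must be >= 0")
  if (confidence <= 0 || confidence >= 1)
    abort_validation("confidence must lie in (0, 1)")
  structure(list(delta_ins = delta_ins, delta_del = delta_del,
                 max_ins = as.integer(max_ins), max_del = as.integer(max_del),
                 confidence = confidence),
            class = "rnq_params")
}

#' Construct an alignment object
#'
#' An alignment maps query nodes to target nodes (`matched`), deletes the
#' remaining query nodes, and may use inserted target nodes to bridge query
#' edges whose endpoint images are non-adjacent. The alignment subnetwork is
#' the target subgraph induced on the matched images plus insertions.
#'
#' @param matched named character vector: names are query nodes, values the
#'   target nodes they map to.
#' @param deleted_query character vector of deleted query nodes.
#' @param inserted_target character vector of inserted target nodes (in
#'   discovery order).
#' @param score alignment score.
#' @return an object of class `rnq_alignment`.
#' @export
alignment <- function(matched, deleted_query = character(),
                      inserted_target = character(), score = NA_real_) {
  matched <- unlist(matched)
  if (length(matched) > 0 && anyDuplicated(matched))
    abort_validation("matched mapping is not injective")
  structure(list(matched = matched,
                 deleted_query = as.character(deleted_query),
                 inserted_target = as.character(inserted_target),
                 score = score,
                 subnetwork_nodes = sort(unique(c(unname(matched),
                                                  inserted_target)))),
            class = "rnq_alignment")
}

#' @export
print.rnq_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d matched, %d deleted, %d inserted, score %.4f>\n",
              length(x$matched), length(x$deleted_query),
              length(x$inserted_target), x$score))
  invisible(x)
}

#' Score an alignment
#'
#' The score sums (i) the similarity of each matched pair, (ii) the target
#' edge weight of every query edge whose endpoint images are adjacent in the
#' target, and (iii) the indel penalties `n_ins * delta_ins +
#' n_del * delta_del`.
#'
#' @param a an `rnq_alignment`.
#' @param q the query tree.
#' @param t the target network.
#' @param sim an `rnq_sim` similarity.
#' @param p an `rnq_params`.
#' @return the alignment score (numeric scalar).
#' @export
score_alignment <- function(a, q, t, sim, p = scoring_params()) {
  if (length(a$matched) > 0 && anyDuplicated(unname(a$matched)))
    abort_validation("matched mapping is not injective")
  s <- 0
  for (u in names(a$matched)) s <- s + sim_value(sim, u, a$matched[[u]])
  if (nrow(q$edges) > 0 && length(a$matched) > 0) {
    wenv <- edge_weight_env(t)
    for (i in seq_len(nrow(q$edges))) {
      eu <- q$edges$u[i]; ev <- q$edges$v[i]
      if (eu %in% names(a$matched) && ev %in% names(a$matched)) {
        w <- edge_weight(wenv, a$matched[[eu]], a$matched[[ev]])
        if (!is.na(w)) s <- s + w
      }
    }
  }
  s + length(a$inserted_target) * p$delta_ins +
    length(a$deleted_query) * p$delta_del
}

#' Validate an alignment against its instance
#'
#' Checks the structural invariants: matched and deleted nodes partition the
#' query nodes, the mapping is injective, indel counts respect the caps, the
#' alignment subnetwork is connected in the target, and the stored score
#' agrees with [score_alignment()] recomputed from the fields.
#'
#' @inheritParams score_alignment
#' @return `TRUE` invisibly; aborts with a validation error otherwise.
#' @export
validate_alignment <- function(a, q, t, sim, p = scoring_params()) {
  qn <- sort(c(names(a$matched), a$deleted_query))
  if (!identical(qn, q$nodes))
    abort_validation("matched and deleted nodes do not partition the query")
  if (anyDuplicated(unname(a$matched)))
    abort_validation("matched mapping is not injective")
  if (length(a$inserted_target) > p$max_ins)
    abort_validation("too many insertions")
  if (length(a$deleted_query) > p$max_del)
    abort_validation("too many deletions")
  sub <- a$subnetwork_nodes
  if (!all(sub %in% t$nodes))
    abort_validation("subnetwork nodes missing from target")
  if (length(sub) > 1) {
    g <- igraph::induced_subgraph(as_igraph(t), sub)
    if (igraph::components(g)$no != 1)
      abort_validation("alignment subnetwork is not connected")
  }
  rescore <- score_alignment(a, q, t, sim, p)
  if (!isTRUE(all.equal(rescore, a$score, tolerance = 1e-9)))
    abort_validation(sprintf("stored score %.12g != recomputed %.12g",
                             a$score, rescore))
  invisible(TRUE)
}

#' Write an alignment to a TSV file
#'
#' One row per query node and per insertion, with columns
#' `(query_node, target_node | "-", role)` where role is `match`, `del` or
#' `ins`; a header comment carries the score (and z-score if supplied).
#'
#' @param a an `rnq_alignment`.
#' @param path output file path.
#' @param z optional z-score recorded in the header.
#' @export
write_alignment <- function(a, path, z = NULL) {
  lines <- sprintf("#score=%.10g", a$score)
  if (!is.null(z) && is.finite(z)) lines <- c(lines, sprintf("#z=%.6g", z))
  for (u in names(a$matched))
    lines <- c(lines, sprintf("%s\t%s\tmatch", u, a$matched[[u]]))
  for (u in a$deleted_query) lines <- c(lines, sprintf("%s\t-\tdel", u))
  for (v in a$inserted_target) lines <- c(lines, sprintf("-\t%s\tins", v))
  writeLines(lines, path)
  invisible(path)
}
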