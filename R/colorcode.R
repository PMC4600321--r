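#' Number of color-coding trials for a confidence level
#'
#' A fixed set of `c` target nodes receives all-distinct colors under a
#' uniform c-coloring with probability `p = c!/c^c`. Repeating `t`
#' independent trials finds a colorful optimum with probability
#' `1 - (1-p)^t`, so `t = ceil(log(1 - confidence) / log(1 - p))` trials
#' give at least the requested confidence. This uses the conservative `p`
#' for a full-size set even when fewer nodes are used, so the stated
#' confidence is a lower bound.
#'
#' @param num_colors number of colors `c >= 1`.
#' @param confidence desired probability of optimality, in (0, 1).
#' @return integer number of trials.
#' @export
trials_for_confidence <- function(num_colors, confidence) {
  if (num_colors < 1) abort_validation("num_colors must be >= 1")
  if (confidence <= 0 || confidence >= 1)
    abort_validation("confidence must lie in (0, 1)")
  p <- factorial(num_colors) / num_colors^num_colors
  if (p >= 1) return(1L)
  as.integer(ceiling(log(1 - confidence) / log(1 - p)))
}

#' Plan the colors and trials for a color-coding run
#'
#' @param num_colors number of colors.
#' @param confidence desired confidence.
#' @param rng_seed seed for the per-trial colorings.
#' @return list with `num_colors`, `num_trials`, `rng_seed`.
#' @export
color_trial_plan <- function(num_colors, confidence = 0.99, rng_seed = 1L) {
  list(num_colors = as.integer(num_colors),
       num_trials = trials_for_confidence(num_colors, confidence),
       rng_seed = as.integer(rng_seed))
}

# Deterministic root: maximum degree, ties to the lexicographically
# smallest node id. Shared by the DP, the brute-force oracle and the
# null-model embedder so all three walk the same rooted tree.
tree_root <- function(q) {
  if (length(q$nodes) == 1) return(q$nodes[1])
  deg <- stats::setNames(rep(0L, length(q$nodes)), q$nodes)
  tab <- table(c(q$edges$u, q$edges$v))
  deg[names(tab)] <- as.integer(tab)
  cand <- names(deg)[deg == max(deg)]
  sort(cand)[1]
}

# rooted structure: parent per node (NA for root) and BFS order from root
rooted_tree <- function(q) {
  root <- tree_root(q)
  adj <- adjacency_list(q)
  parent <- stats::setNames(rep(NA_character_, length(q$nodes)), q$nodes)
  order <- character(0)
  queue <- root
  seen <- stats::setNames(rep(FALSE, length(q$nodes)), q$nodes)
  seen[root] <- TRUE
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    order <- c(order, u)
    for (v in adj[[u]]) if (!seen[v]) {
      seen[v] <- TRUE
      parent[v] <- u
      queue <- c(queue, v)
    }
  }
  list(root = root, parent = parent, bfs = order, postorder = rev(order))
}

check_forced <- function(forced, q, t) {
  if (is.null(forced) || length(forced) == 0) return(NULL)
  forced <- unlist(forced)
  if (is.null(names(forced)) || any(!nzchar(names(forced))))
    abort_validation("forced map must be named by query nodes")
  if (!all(names(forced) %in% q$nodes))
    abort_validation("forced query nodes missing from the query")
  if (!all(forced %in% t$nodes))
    abort_validation("forced target nodes missing from the target")
  if (anyDuplicated(unname(forced)))
    abort_validation("forced map is not injective")
  forced
}

#' Confidence-bounded color-coding tree alignment
#'
#' Aligns a tree query against an arbitrary weighted target with bounded
#' insertions and deletions. Runs `num_trials` independent random colorings
#' of the target; each trial solves the rooted tree dynamic program exactly
#' over (query node, host, used-color subset, insertions, deletions) and the
#' best colorful alignment over all trials is returned. With the default
#' trial count the returned score is optimal with probability at least
#' `p$confidence`.
#'
#' When `forced` pins query nodes to target nodes (the induced alignment of
#' query processing), the color count drops to the number of unmapped query
#' nodes plus `max_ins`; forced hosts are never insertion sites and never
#' host other query nodes.
#'
#' @param q query tree (`rnq_query_tree`).
#' @param t target network.
#' @param sim similarity between query and target nodes.
#' @param p scoring parameters.
#' @param forced optional named character vector of fixed query-to-target
#'   pairs (injective).
#' @param seed integer seed; trial `j` colors with seed `seed + j`.
#' @param num_trials optional trial-count override (testing / exploration).
#' @return an `rnq_alignment`, or `NULL` when no feasible alignment exists.
#' @export
colorcode_align <- function(q, t, sim, p = scoring_params(), forced = NULL,
                            seed = 1L, num_trials = NULL) {
  assert_tree(q)
  forced <- check_forced(forced, q, t)
  qnodes <- q$nodes                      # sorted
  tnodes <- t$nodes                      # sorted -> index order == lexicographic
  m <- length(qnodes); n <- length(tnodes)
  if (n == 0) return(NULL)

  free <- setdiff(qnodes, names(forced))
  ncol_eff <- max(1L, length(free) + p$max_ins)
  if (ncol_eff > 12)
    abort_size("query too large for the color-coding engine (needs > 12 colors)")
  if (is.null(num_trials))
    num_trials <- trials_for_confidence(ncol_eff, p$confidence)

  rt <- rooted_tree(q)
  parent_idx <- ifelse(is.na(rt$parent[qnodes]), -1L,
                       match(rt$parent[qnodes], qnodes) - 1L)
  post_idx <- match(rt$postorder, qnodes) - 1L

  # CSR adjacency over sorted target nodes
  ui <- match(t$edges$u, tnodes); vi <- match(t$edges$v, tnodes)
  from <- c(ui, vi); to <- c(vi, ui); w2 <- c(t$edges$w, t$edges$w)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w2 <- w2[o]
  ptr <- integer(n + 1)
  cnt <- tabulate(from, nbins = n)
  ptr[1] <- 0L
  for (i in seq_len(n)) ptr[i + 1] <- ptr[i] + cnt[i]

  forced_idx <- rep(-1L, m)
  if (!is.null(forced))
    forced_idx[match(names(forced), qnodes)] <- match(unname(forced), tnodes) - 1L

  smat <- sim_dense(sim, qnodes, tnodes)
  res <- cc_align_cpp(m, post_idx, parent_idx, n, ptr, to - 1L, w2, smat,
                      forced_idx, p$max_ins, p$max_del,
                      p$delta_ins, p$delta_del,
                      ncol_eff, as.integer(num_trials), as.numeric(seed))
  if (!isTRUE(res$found)) return(NULL)

  match_vec <- res$matched
  matched_mask <- match_vec >= 0
  matched <- stats::setNames(tnodes[match_vec[matched_mask] + 1L],
                             qnodes[matched_mask])
  deleted <- qnodes[!matched_mask]
  inserted <- if (length(res$inserted) > 0) tnodes[res$inserted + 1L]
              else character()
  alignment(matched = matched, deleted_query = deleted,
            inserted_target = inserted, score = res$score)
}
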