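#' Align a query against one reference network
#'
#' Both networks are small, so the color-coding alignment is cheap. The
#' reference is rejected when the alignment score falls below a threshold;
#' by default the threshold is `theta` times an ideal score (every query
#' node at its best similarity and every query edge at the reference's
#' maximum edge weight).
#'
#' @param q query tree.
#' @param r an `rnq_reference`.
#' @param sim_qr query-vs-reference similarity (reference nodes are target
#'   node ids).
#' @param p scoring parameters.
#' @param theta screening fraction of the ideal score. Default 0.5.
#' @param threshold absolute score threshold overriding `theta`.
#' @param seed RNG seed.
#' @return list with `psi` (the `rnq_alignment`), `score`, `threshold`,
#'   `ideal`; or `NULL` when the reference is rejected.
#' @export
align_to_reference <- function(q, r, sim_qr, p = scoring_params(),
                               theta = 0.5, threshold = NULL, seed = 1L) {
  smat <- sim_dense(sim_qr, q$nodes, r$tree$nodes)
  ideal_nodes <- sum(apply(smat, 1, function(row)
    if (length(row) > 0) max(row) else 0))
  max_w <- if (nrow(r$tree$edges) > 0) max(r$tree$edges$w) else 0
  # at most k-1 query edges can land on reference edges, and a query larger
  # than the reference is forced into |V_Q| - k deletions
  k <- length(r$tree$nodes)
  ideal <- ideal_nodes + min(nrow(q$edges), max(0L, k - 1L)) * max_w +
    max(0L, length(q$nodes) - k) * p$delta_del
  if (is.null(threshold)) threshold <- theta * ideal
  # no homological evidence at all: the reference cannot represent the query
  if (ideal_nodes == 0) return(NULL)
  psi <- colorcode_align(q, r$tree, sim_qr, p, seed = seed)
  if (is.null(psi) || psi$score < threshold) return(NULL)
  list(psi = psi, score = psi$score, threshold = threshold, ideal = ideal)
}

#' Compose a query-to-reference alignment with a stored reference-to-target
#' mapping
#'
#' Query node `u` is forced to target node `phi(psi(u))` whenever both
#' alignment steps match it; query nodes broken by a deletion in either step
#' stay free. (The sign condition on the similarity is vacuous for
#' similarities in \[0, 1\] and is recorded as always true.)
#'
#' @param psi an `rnq_alignment` of the query onto the reference.
#' @param phi a stored mapping (list with `phi` named vector).
#' @param q the query tree.
#' @param ref_id,mapping_index provenance.
#' @return an `rnq_indirect` with `forced` (named vector), `S`, `S_prime`,
#'   `free_query`, `ref_id`, `mapping_index`.
#' @export
compose_indirect <- function(psi, phi, q, ref_id = NA_character_,
                             mapping_index = NA_integer_) {
  forced <- character(0)
  nm <- character(0)
  for (u in names(psi$matched)) {
    w <- psi$matched[[u]]
    if (w %in% names(phi$phi)) {
      forced <- c(forced, phi$phi[[w]])
      nm <- c(nm, u)
    }
  }
  forced <- stats::setNames(forced, nm)
  structure(list(forced = forced,
                 S = nm,
                 S_prime = unname(forced),
                 free_query = setdiff(q$nodes, nm),
                 ref_id = ref_id,
                 mapping_index = mapping_index),
            class = "rnq_indirect")
}

# Exact maximum-weight bipartite matching for a few rows (bitmask DP over
# rows, scan over columns). Rows may stay unmatched at weight 0.
max_weight_matching_value <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  if (nr == 0 || nc == 0) return(0)
  if (nr > 12) abort_size("matching limited to <= 12 free query nodes")
  M <- bitwShiftL(1L, nr)
  best <- rep(-Inf, M)
  best[1] <- 0
  bits <- bitwShiftL(1L, seq_len(nr) - 1L)
  for (j in seq_len(nc)) {
    nxt <- best
    for (s in which(best > -Inf) - 1L) {
      for (r in seq_len(nr)) {
        if (bitwAnd(s, bits[r]) == 0L) {
          s2 <- bitwOr(s, bits[r])
          cand <- best[s + 1L] + W[r, j]
          if (cand > nxt[s2 + 1L]) nxt[s2 + 1L] <- cand
        }
      }
    }
    best <- nxt
  }
  max(best)
}

#' Upper bound on the induced-alignment score
#'
#' Relaxes the constrained alignment to a maximum-weight bipartite matching:
#' each forced query node contributes its forced similarity; each free query
#' node may match any target node outside the forced images; indel penalties
#' are dropped. Because the matching ignores topology, an allowance for the
#' aligned-interaction weights is added on top: each query edge with both
#' endpoints forced contributes its realized target edge weight (0 when the
#' images are non-adjacent), and every other query edge contributes the
#' maximum target edge weight. The result dominates the score of every
#' alignment that respects the indirect mapping.
#'
#' @param q query tree.
#' @param t target network.
#' @param sim similarity.
#' @param im an `rnq_indirect`.
#' @return numeric upper bound.
#' @export
upper_bound <- function(q, t, sim, im) {
  forced_sum <- 0
  for (u in im$S) forced_sum <- forced_sum + sim_value(sim, u, im$forced[[u]])
  free <- im$free_query
  cols <- setdiff(t$nodes, im$S_prime)
  match_val <- if (length(free) > 0 && length(cols) > 0)
    max_weight_matching_value(sim_dense(sim, free, cols))
  else 0
  edge_term <- 0
  if (nrow(q$edges) > 0) {
    w_max <- if (nrow(t$edges) > 0) max(t$edges$w) else 0
    wenv <- edge_weight_env(t)
    for (i in seq_len(nrow(q$edges))) {
      eu <- q$edges$u[i]; ev <- q$edges$v[i]
      if (eu %in% im$S && ev %in% im$S) {
        w <- edge_weight(wenv, im$forced[[eu]], im$forced[[ev]])
        if (!is.na(w)) edge_term <- edge_term + w
      } else {
        edge_term <- edge_term + w_max
      }
    }
  }
  forced_sum + match_val + edge_term
}

#' Induced alignment under an indirect mapping
#'
#' Runs [colorcode_align()] with the indirect mapping's pairs forced, which
#' reduces the color count to the number of free query nodes plus
#' `max_ins` (and hence the trial count for the same confidence).
#'
#' @inheritParams upper_bound
#' @param p scoring parameters.
#' @param seed RNG seed.
#' @return an `rnq_alignment` or `NULL` when infeasible.
#' @export
induced_align <- function(q, t, sim, im, p = scoring_params(), seed = 1L) {
  colorcode_align(q, t, sim, p, forced = im$forced, seed = seed)
}

#' Query a target network through its reference index
#'
#' Screens every reference with [align_to_reference()], composes indirect
#' mappings with each stored reference-to-target mapping, skips candidates
#' whose upper bound cannot beat the current best score, and refines the
#' rest with [induced_align()]. References are processed in descending
#' screening-score order so strong candidates set a high bar early.
#'
#' @param q query tree.
#' @param t target network.
#' @param ix an `rnq_index` built for `t`.
#' @param sim_qt query-vs-target similarity.
#' @param p scoring parameters.
#' @param theta screening fraction. Default 0.5.
#' @param seed RNG seed. Candidate seeds derive from the reference position
#'   and mapping index, so pruned and unpruned runs align identically.
#' @param n_null null-sample size for the final z-score.
#' @param prune disable to examine every candidate (testing the bound).
#' @return an `rnq_query_result` with `best` (alignment or `NULL`), `z`,
#'   `pruned_by_screen`, `pruned_by_bound`, `examined`, `total_candidates`
#'   and a per-candidate `log` data frame.
#' @export
query_index <- function(q, t, ix, sim_qt, p = scoring_params(), theta = 0.5,
                        seed = 1L, n_null = 10000L, prune = TRUE) {
  if (!identical(ix$target_checksum, network_checksum(t)))
    abort_stale_index("index does not match the supplied target network")
  refs <- ix$references
  total <- sum(vapply(refs, function(x) length(x$mappings$mappings), 0L))
  pruned_screen <- 0L; pruned_bound <- 0L; examined <- 0L
  log <- list()
  screens <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    r <- refs[[i]]$ref
    sim_qr <- restrict_sim(sim_qt, qnodes = q$nodes, tnodes = r$tree$nodes)
    screens[i] <- list(align_to_reference(q, r, sim_qr, p, theta = theta,
                                          seed = seed + 31L * i))
    if (is.null(screens[[i]]))
      pruned_screen <- pruned_screen + length(refs[[i]]$mappings$mappings)
  }
  accepted <- which(!vapply(screens, is.null, TRUE))
  accepted <- accepted[order(-vapply(accepted,
                                     function(i) screens[[i]]$score, 0),
                             accepted)]
  best <- NULL
  best_score <- -Inf
  for (i in accepted) {
    psi <- screens[[i]]$psi
    maps <- refs[[i]]$mappings$mappings
    for (j in seq_along(maps)) {
      im <- compose_indirect(psi, maps[[j]], q,
                             ref_id = refs[[i]]$ref$ref_id, mapping_index = j)
      ub <- upper_bound(q, t, sim_qt, im)
      if (prune && ub <= best_score) {
        pruned_bound <- pruned_bound + 1L
        log[[length(log) + 1L]] <- data.frame(
          ref_id = refs[[i]]$ref$ref_id, mapping_index = j, ub = ub,
          examined = FALSE, score = NA_real_, stringsAsFactors = FALSE)
        next
      }
      examined <- examined + 1L
      a <- induced_align(q, t, sim_qt, im, p, seed = seed + 97L * i + j)
      sc <- if (is.null(a)) NA_real_ else a$score
      log[[length(log) + 1L]] <- data.frame(
        ref_id = refs[[i]]$ref$ref_id, mapping_index = j, ub = ub,
        examined = TRUE, score = sc, stringsAsFactors = FALSE)
      if (!is.null(a) && a$score > best_score) {
        best <- a
        best_score <- a$score
      }
    }
  }
  z <- NA_real_
  if (!is.null(best)) {
    null <- sample_null_scores(q, t, sim_qt, p, n_null = n_null,
                               seed = seed + 555L)
    z <- z_score_safe(best$score, null)
  }
  structure(list(best = best, z = z,
                 pruned_by_screen = pruned_screen,
                 pruned_by_bound = pruned_bound,
                 examined = examined,
                 total_candidates = total,
                 log = if (length(log) > 0) do.call(rbind, log)
                       else data.frame()),
            class = "rnq_query_result")
}

#' @export
print.rnq_query_result <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<query result: no alignment found>\n")
  } else {
    cat(sprintf(
      "<query result: score %.4f, z %.2f; %d examined, %d bound-pruned, %d screen-pruned>\n",
      x$best$score, x$z, x$examined, x$pruned_by_bound, x$pruned_by_screen))
  }
  invisible(x)
}
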