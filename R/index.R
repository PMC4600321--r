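#' Sample a reference subtree by random walk
#'
#' Starts from a uniformly random seed node and repeatedly adds a uniformly
#' random target edge incident to the current reference (with its outside
#' endpoint) until the reference has `k` nodes. Only the walk edges are kept,
#' so the reference is a k-node subtree of the target. A stalled walk (no
#' outside neighbour) restarts from a fresh seed node.
#'
#' @param t target network.
#' @param k reference size in nodes. Default 6.
#' @param seed RNG seed.
#' @param ref_id identifier for the reference.
#' @return an `rnq_reference` with fields `ref_id`, `tree` (an
#'   `rnq_query_tree` whose node ids are target node ids) and `seed`.
#' @export
sample_reference <- function(t, k = 6L, seed = 1L, ref_id = "R1") {
  k <- as.integer(k)
  if (k < 1) abort_validation("k must be >= 1")
  comp <- igraph::components(as_igraph(t))
  if (max(comp$csize) < k)
    abort_build(sprintf("no connected component of size >= %d", k))
  adjT <- adjacency_list(t)
  wenv <- edge_weight_env(t)
  tree <- with_seed(seed, {
    out <- NULL
    for (attempt in 1:100) {
      sd_node <- t$nodes[sample.int(length(t$nodes), 1L)]
      in_ref <- sd_node
      eu <- character(0); ev <- character(0)
      while (length(in_ref) < k) {
        # incident edges with an outside endpoint
        cand_from <- character(0); cand_to <- character(0)
        for (x in in_ref) {
          outs <- setdiff(adjT[[x]], in_ref)
          if (length(outs) > 0) {
            cand_from <- c(cand_from, rep(x, length(outs)))
            cand_to <- c(cand_to, outs)
          }
        }
        if (length(cand_to) == 0) break
        pick <- sample.int(length(cand_to), 1L)
        eu <- c(eu, cand_from[pick]); ev <- c(ev, cand_to[pick])
        in_ref <- c(in_ref, cand_to[pick])
      }
      if (length(in_ref) == k) {
        w <- if (length(eu) > 0)
          vapply(seq_along(eu),
                 function(i) edge_weight(wenv, eu[i], ev[i]), 0)
          else numeric(0)
        out <- query_tree(nodes = in_ref,
                          edges = data.frame(u = eu, v = ev, w = w,
                                             stringsAsFactors = FALSE),
                          id = ref_id)
        break
      }
    }
    if (is.null(out))
      abort_build("random walk failed to reach k nodes within retry budget")
    out
  })
  structure(list(ref_id = ref_id, tree = tree, seed = as.integer(seed)),
            class = "rnq_reference")
}

#' Extract the non-overlapping significant mappings of a reference
#'
#' Iteratively aligns the reference against a working copy of the target
#' with [colorcode_align()]; each statistically significant alignment is
#' recorded and its subnetwork nodes (matched images plus insertions) are
#' removed from the working copy before the next round. Stops at the first
#' non-significant (or infeasible) alignment. Significance is always tested
#' against a null sampled on the original target.
#'
#' @param r an `rnq_reference`.
#' @param t target network.
#' @param sim_rt target-vs-target similarity (rows for the reference nodes).
#' @param p scoring parameters.
#' @param cutoff z-score cut-off for storing a mapping. Default 3.
#' @param seed RNG seed.
#' @param n_null null-sample size. Default 10000.
#' @param null optional precomputed `rnq_null` (shared across calls).
#' @return an `rnq_mapping_set`: list of mappings, each with `phi` (named
#'   vector reference node -> target node, deletions absent), `deleted`,
#'   `inserted`, `score`, `z`, `subnetwork`.
#' @export
extract_mappings <- function(r, t, sim_rt, p = scoring_params(), cutoff = 3,
                             seed = 1L, n_null = 10000L, null = NULL) {
  if (is.null(null))
    null <- sample_null_scores(r$tree, t, sim_rt, p, n_null = n_null,
                               seed = seed + 1L)
  work <- t
  mappings <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (length(work$nodes) < 1) break
    a <- colorcode_align(r$tree, work,
                         restrict_sim(sim_rt, tnodes = work$nodes),
                         p, seed = seed + 10L + iter)
    if (is.null(a)) break
    z <- z_score_safe(a$score, null)
    if (!(z >= cutoff)) break
    mappings[[iter]] <- list(phi = a$matched, deleted = a$deleted_query,
                             inserted = a$inserted_target,
                             score = a$score, z = z,
                             subnetwork = a$subnetwork_nodes)
    work <- network_delete_nodes(work, a$subnetwork_nodes)
  }
  structure(list(ref_id = r$ref_id, mappings = mappings),
            class = "rnq_mapping_set")
}

# coverage of one reference = union of its mappings' subnetwork node sets
mapping_cover <- function(ms) {
  if (length(ms$mappings) == 0) return(character())
  sort(unique(unlist(lapply(ms$mappings, `[[`, "subnetwork"))))
}

#' Build the initial reference set
#'
#' Repeats [sample_reference()] + [extract_mappings()] until the union of
#' the references' coverages reaches `eta` percent of the target nodes (or a
#' hard cap on the number of references, reported with a warning).
#'
#' @param t target network.
#' @param sim_tt target-vs-target similarity.
#' @param p scoring parameters.
#' @param k reference size. Default 6.
#' @param eta coverage goal in percent, in (0, 100\]. Default 70.
#' @param cutoff significance cut-off. Default 3.
#' @param seed RNG seed.
#' @param n_null null-sample size per reference.
#' @param max_refs cap on the initial set size. Default 500.
#' @return list with `references` (list of `list(ref, mappings)`), `cover`
#'   (covered target nodes) and `complete` (logical: coverage goal met).
#' @export
build_initial_set <- function(t, sim_tt, p = scoring_params(), k = 6L,
                              eta = 70, cutoff = 3, seed = 1L,
                              n_null = 10000L, max_refs = 500L) {
  if (eta <= 0 || eta > 100) abort_validation("eta must be in (0, 100]")
  goal <- ceiling(eta / 100 * length(t$nodes))
  refs <- list()
  cover <- character()
  i <- 0L
  while (length(cover) < goal && i < max_refs) {
    i <- i + 1L
    r <- sample_reference(t, k, seed = seed + 7L * i,
                          ref_id = sprintf("R%03d", i))
    ms <- extract_mappings(r, t, sim_tt, p, cutoff = cutoff,
                           seed = seed + 1000L + 13L * i, n_null = n_null)
    refs[[i]] <- list(ref = r, mappings = ms)
    cover <- sort(unique(c(cover, mapping_cover(ms))))
  }
  complete <- length(cover) >= goal
  if (!complete)
    warning(sprintf(
      "coverage goal not reached: %d/%d nodes covered after %d references",
      length(cover), goal, i), call. = FALSE)
  list(references = refs, cover = cover, complete = complete)
}

#' Greedy set-cover reduction to the final reference set
#'
#' Starting from an empty set, repeatedly adds the reference whose coverage
#' enlarges the combined coverage the most (ties broken by earlier creation
#' order) until `eta` percent of the target nodes are covered. The greedy
#' choice is the classic O(ln n)-approximation to the optimal set cover.
#'
#' @param initial list of `list(ref, mappings)` from [build_initial_set()].
#' @param eta coverage goal in percent.
#' @param n_target_nodes number of nodes in the target.
#' @return the selected sublist (in selection order).
#' @export
select_final_set <- function(initial, eta, n_target_nodes) {
  goal <- ceiling(eta / 100 * n_target_nodes)
  covers <- lapply(initial, function(x) mapping_cover(x$mappings))
  total <- sort(unique(unlist(covers)))
  if (length(total) < goal) {
    warning("initial set does not reach the coverage goal; returning all",
            call. = FALSE)
    return(initial)
  }
  chosen <- integer(0)
  cover <- character(0)
  remaining <- seq_along(initial)
  while (length(cover) < goal) {
    gains <- vapply(remaining,
                    function(i) length(union(cover, covers[[i]])), 0L)
    pick <- remaining[which.max(gains)]   # which.max keeps earliest on ties
    chosen <- c(chosen, pick)
    cover <- sort(union(cover, covers[[pick]]))
    remaining <- setdiff(remaining, pick)
  }
  initial[chosen]
}

#' Build a reference index over a target network
#'
#' Runs the two index-construction steps end to end: the random-walk initial
#' set with its non-overlapping significant mappings, then the greedy
#' set-cover reduction to the final reference set.
#'
#' @inheritParams build_initial_set
#' @return an `rnq_index` with `target_checksum`, `params`, `initial_size`,
#'   `references` (final set), `cover_nodes` and `complete`.
#' @export
build_index <- function(t, sim_tt, p = scoring_params(), k = 6L, eta = 70,
                        cutoff = 3, seed = 1L, n_null = 10000L,
                        max_refs = 500L) {
  ini <- build_initial_set(t, sim_tt, p, k = k, eta = eta, cutoff = cutoff,
                           seed = seed, n_null = n_null, max_refs = max_refs)
  fin <- if (ini$complete)
    select_final_set(ini$references, eta, length(t$nodes))
  else ini$references
  cover_nodes <- sort(unique(unlist(
    lapply(fin, function(x) mapping_cover(x$mappings)))))
  structure(list(
    target_checksum = network_checksum(t),
    params = list(k = as.integer(k), eta = eta, cutoff = cutoff,
                  confidence = p$confidence, delta_ins = p$delta_ins,
                  delta_del = p$delta_del, max_ins = p$max_ins,
                  max_del = p$max_del, n_null = as.integer(n_null),
                  seed = as.integer(seed), max_refs = as.integer(max_refs)),
    initial_size = length(ini$references),
    references = fin,
    cover_nodes = cover_nodes,
    complete = ini$complete), class = "rnq_index")
}

#' @export
print.rnq_index <- function(x, ...) {
  cat(sprintf("<reference index: %d/%d references, %d nodes covered%s>\n",
              length(x$references), x$initial_size, length(x$cover_nodes),
              if (x$complete) "" else " (coverage goal NOT met)"))
  invisible(x)
}

index_to_list <- function(ix) {
  list(
    format = "refnetq-index-v1",
    target_checksum = ix$target_checksum,
    params = ix$params,
    initial_size = ix$initial_size,
    complete = ix$complete,
    references = lapply(ix$references, function(x) {
      r <- x$ref
      list(ref_id = r$ref_id,
           nodes = as.list(r$tree$nodes),
           edges = lapply(seq_len(nrow(r$tree$edges)), function(i)
             list(r$tree$edges$u[i], r$tree$edges$v[i], r$tree$edges$w[i])),
           seed = r$seed,
           mappings = lapply(x$mappings$mappings, function(mp) {
             phi <- c(
               lapply(names(mp$phi), function(u) list(u, mp$phi[[u]])),
               lapply(mp$deleted, function(u) list(u, NULL)))
             list(phi = phi, inserted = as.list(mp$inserted),
                  score = mp$score, z = mp$z,
                  subnetwork = as.list(mp$subnetwork))
           }))
    }),
    cover_nodes = as.list(ix$cover_nodes))
}

#' Save a reference index as JSON
#'
#' @param ix an `rnq_index`.
#' @param path output file path.
#' @export
save_index <- function(ix, path) {
  # digits = I(17): significant-digit formatting that round-trips doubles
  jsonlite::write_json(index_to_list(ix), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a reference index from JSON
#'
#' Verifies the stored target checksum against the supplied target network
#' and refuses a mismatch (stale-index error).
#'
#' @param path index JSON path.
#' @param t the target network the index was built for.
#' @return an `rnq_index`.
#' @export
load_index <- function(path, t) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_parse(paste("malformed index JSON:",
                                                        conditionMessage(e))))
  if (!identical(raw$format, "refnetq-index-v1"))
    abort_parse("not a refnetq index file")
  if (!identical(raw$target_checksum, network_checksum(t)))
    abort_stale_index("index was built for a different target network")
  refs <- lapply(raw$references, function(rr) {
    edges <- if (length(rr$edges) > 0)
      data.frame(u = vapply(rr$edges, function(e) e[[1]], ""),
                 v = vapply(rr$edges, function(e) e[[2]], ""),
                 w = vapply(rr$edges, function(e) as.numeric(e[[3]]), 0),
                 stringsAsFactors = FALSE)
    else NULL
    tree <- query_tree(nodes = unlist(rr$nodes), edges = edges,
                       id = rr$ref_id)
    ref <- structure(list(ref_id = rr$ref_id, tree = tree,
                          seed = as.integer(rr$seed)),
                     class = "rnq_reference")
    mappings <- lapply(rr$mappings, function(mp) {
      pairs <- mp$phi
      keep <- !vapply(pairs, function(pr) is.null(pr[[2]]), TRUE)
      phi <- stats::setNames(
        vapply(pairs[keep], function(pr) pr[[2]], ""),
        vapply(pairs[keep], function(pr) pr[[1]], ""))
      list(phi = phi,
           deleted = vapply(pairs[!keep], function(pr) pr[[1]], character(1)),
           inserted = as.character(unlist(mp$inserted)),
           score = as.numeric(mp$score), z = as.numeric(mp$z),
           subnetwork = as.character(unlist(mp$subnetwork)))
    })
    list(ref = ref,
         mappings = structure(list(ref_id = rr$ref_id, mappings = mappings),
                              class = "rnq_mapping_set"))
  })
  structure(list(target_checksum = raw$target_checksum,
                 params = raw$params,
                 initial_size = as.integer(raw$initial_size),
                 references = refs,
                 cover_nodes = sort(as.character(unlist(raw$cover_nodes))),
                 complete = isTRUE(raw$complete)),
            class = "rnq_index")
}
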