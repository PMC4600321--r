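#' Exhaustive tree-alignment oracle
#'
#' Enumerates every deletion subset (within `max_del`, root excluded), every
#' injective placement of the remaining query nodes, and every bridging-path
#' completion (within `max_ins`) that keeps the alignment subnetwork
#' connected, and returns the exact maximum-score alignment. Guard-railed to
#' small instances; intended as an independent testing oracle for
#' [colorcode_align()].
#'
#' @inheritParams colorcode_align
#' @return an `rnq_alignment` or `NULL` when no feasible alignment exists.
#' @export
brute_force_align <- function(q, t, sim, p = scoring_params(), forced = NULL) {
  assert_tree(q)
  if (length(q$nodes) > 6 || length(t$nodes) > 14)
    abort_size("brute-force oracle limited to |V_Q| <= 6 and |V_T| <= 14")
  forced <- check_forced(forced, q, t)

  qnodes <- q$nodes
  tnodes <- t$nodes
  rt <- rooted_tree(q)
  adjT <- adjacency_list(t)
  wenv <- edge_weight_env(t)
  qedge_key <- character(0)
  if (nrow(q$edges) > 0)
    qedge_key <- paste(pmin(q$edges$u, q$edges$v),
                       pmax(q$edges$u, q$edges$v), sep = "\r")
  is_qedge <- function(a, b)
    paste(min(a, b), max(a, b), sep = "\r") %in% qedge_key
  forced_hosts <- unname(forced)

  best <- NULL
  best_key <- NULL   # list(score, indels, lexvec)

  consider <- function(matchmap, ins_nodes, n_del) {
    sc <- sum(vapply(names(matchmap),
                     function(u) sim_value(sim, u, matchmap[[u]]), 0)) +
      length(ins_nodes) * p$delta_ins + n_del * p$delta_del
    if (nrow(q$edges) > 0)
      for (i in seq_len(nrow(q$edges))) {
        eu <- q$edges$u[i]; ev <- q$edges$v[i]
        if (eu %in% names(matchmap) && ev %in% names(matchmap)) {
          w <- edge_weight(wenv, matchmap[[eu]], matchmap[[ev]])
          if (!is.na(w)) sc <- sc + w
        }
      }
    lexvec <- vapply(qnodes, function(u)
      if (u %in% names(matchmap)) matchmap[[u]] else "￿", "")
    indels <- length(ins_nodes) + n_del
    if (is.null(best) ||
        sc > best_key$score + 1e-12 ||
        (abs(sc - best_key$score) <= 1e-12 &&
         (indels < best_key$indels ||
          (indels == best_key$indels &&
           paste(lexvec, collapse = "\r") <
             paste(best_key$lexvec, collapse = "\r"))))) {
      best <<- alignment(matched = unlist(matchmap),
                         deleted_query = setdiff(qnodes, names(matchmap)),
                         inserted_target = ins_nodes, score = sc)
      best_key <<- list(score = sc, indels = indels, lexvec = lexvec)
    }
  }

  # all simple paths a -> b with <= maxlen edges, interiors avoiding `avoid`
  paths_between <- function(a, b, maxlen, avoid) {
    out <- list()
    walk <- function(cur, interior) {
      for (nb in adjT[[cur]]) {
        if (nb == b) {
          out[[length(out) + 1L]] <<- interior
        } else if (length(interior) + 2L <= maxlen &&
                   !(nb %in% avoid) && !(nb %in% interior) && nb != a) {
          walk(nb, c(interior, nb))
        }
      }
    }
    if (maxlen >= 1) walk(a, character())
    out
  }

  del_candidates <- setdiff(qnodes, c(rt$root, names(forced)))

  try_deletion_set <- function(dset) {
    kept <- setdiff(qnodes, dset)
    # contracted parent: nearest kept ancestor
    cparent <- stats::setNames(rep(NA_character_, length(kept)), kept)
    corig <- stats::setNames(rep(FALSE, length(kept)), kept)
    for (u in setdiff(kept, rt$root)) {
      a <- rt$parent[[u]]
      while (a %in% dset) a <- rt$parent[[a]]
      cparent[u] <- a
      corig[u] <- identical(rt$parent[[u]], a)
    }
    # pre-order of kept nodes along contracted tree
    ckids <- split(names(cparent)[!is.na(cparent)],
                   cparent[!is.na(cparent)])
    pre <- character(0)
    stack <- rt$root
    while (length(stack) > 0) {
      u <- stack[1]; stack <- stack[-1]
      pre <- c(pre, u)
      ks <- ckids[[u]]
      if (!is.null(ks)) stack <- c(sort(ks), stack)
    }
    img <- new.env(parent = emptyenv())
    assign_node <- function(i, used, ins_used, ins_nodes) {
      if (i > length(pre)) {
        mm <- stats::setNames(
          vapply(pre, function(u) get(u, envir = img), ""), pre)
        consider(as.list(mm), ins_nodes, length(dset))
        return(invisible(NULL))
      }
      u <- pre[i]
      cands <- if (u %in% names(forced)) forced[[u]]
               else setdiff(tnodes, c(used, forced_hosts))
      if (i == 1) {
        for (v in cands) {
          assign(u, v, envir = img)
          assign_node(i + 1, c(used, v), ins_used, ins_nodes)
        }
      } else {
        pv <- get(cparent[[u]], envir = img)
        budget <- p$max_ins - ins_used
        for (v in cands) {
          if (v == pv) next
          ps <- paths_between(pv, v, 1 + budget,
                              avoid = unique(c(used, forced_hosts, v)))
          for (interior in ps) {
            if (any(interior %in% used)) next
            assign(u, v, envir = img)
            assign_node(i + 1, c(used, v, interior),
                        ins_used + length(interior),
                        c(ins_nodes, interior))
          }
        }
      }
      invisible(NULL)
    }
    assign_node(1, character(), 0L, character())
  }

  try_deletion_set(character())
  if (p$max_del > 0 && length(del_candidates) > 0) {
    for (k in seq_len(min(p$max_del, length(del_candidates)))) {
      cmb <- utils::combn(del_candidates, k, simplify = FALSE)
      for (dset in cmb) try_deletion_set(dset)
    }
  }
  best
}
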