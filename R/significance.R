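#' Sample a null distribution of random topology-preserving alignments
#'
#' Each null sample embeds the query tree into the target by a seeded random
#' realization: the root image is uniform over target nodes, then every query
#' edge maps to a uniformly random unused neighbour of the parent's image
#' (dead ends discard the attempt and resample, up to a retry cap). The
#' embedding is indel-free and scored with the alignment score formula
#' (similarities plus realized edge weights).
#'
#' @param q query tree.
#' @param t target network.
#' @param sim similarity.
#' @param p scoring parameters (penalties unused: embeddings are indel-free).
#' @param n_null number of null scores. Default 10000.
#' @param seed RNG seed.
#' @return an `rnq_null` with fields `scores`, `mean`, `sd`, `n`, `seed`.
#' @export
sample_null_scores <- function(q, t, sim, p = scoring_params(),
                               n_null = 10000L, seed = 1L) {
  assert_tree(q)
  if (n_null < 2) abort_validation("n_null must be >= 2")
  if (length(t$nodes) < length(q$nodes))
    abort_null_model("target smaller than the query: no embedding exists")
  rt <- rooted_tree(q)
  adjT <- adjacency_list(t)
  wenv <- edge_weight_env(t)
  qorder <- rt$bfs
  parents <- rt$parent
  smat <- sim_dense(sim, q$nodes, t$nodes)
  m <- length(qorder)

  scores <- numeric(n_null)
  cap <- 100L * as.integer(n_null)
  attempts <- 0L
  got <- 0L
  with_seed(seed, {
    while (got < n_null) {
      if (attempts >= cap)
        abort_null_model(sprintf(
          "null model: only %d/%d embeddings found within the retry cap",
          got, n_null))
      attempts <- attempts + 1L
      img <- character(m)
      names(img) <- qorder
      img[1] <- t$nodes[sample.int(length(t$nodes), 1L)]
      ok <- TRUE
      if (m > 1) {
        for (i in 2:m) {
          u <- qorder[i]
          nbrs <- setdiff(adjT[[img[[parents[[u]]]]]], img[seq_len(i - 1L)])
          if (length(nbrs) == 0) { ok <- FALSE; break }
          img[i] <- nbrs[sample.int(length(nbrs), 1L)]
        }
      }
      if (!ok) next
      got <- got + 1L
      s <- sum(smat[cbind(match(qorder, q$nodes), match(img, t$nodes))])
      if (nrow(q$edges) > 0)
        for (j in seq_len(nrow(q$edges)))
          s <- s + edge_weight(wenv, img[[q$edges$u[j]]], img[[q$edges$v[j]]])
      scores[got] <- s
    }
  })
  structure(list(scores = scores, mean = mean(scores), sd = stats::sd(scores),
                 n = as.integer(n_null), seed = as.integer(seed)),
            class = "rnq_null")
}

#' @export
print.rnq_null <- function(x, ...) {
  cat(sprintf("<null distribution: n=%d, mean=%.4f, sd=%.4f>\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' z-score of an alignment score against a null distribution
#'
#' @param s observed alignment score.
#' @param null an `rnq_null` from [sample_null_scores()].
#' @return `(s - mean) / sd`. A degenerate null (`sd == 0`) is an error;
#'   [is_significant()] implements the caller-side contract for that case.
#' @export
z_score <- function(s, null) {
  if (!inherits(null, "rnq_null")) abort_validation("null must be an rnq_null")
  if (null$sd == 0)
    rnq_abort("null distribution has zero standard deviation",
              "rnq_undefined_z_error")
  (s - null$mean) / null$sd
}

# internal: z with the sigma = 0 contract folded in (+-Inf)
z_score_safe <- function(s, null) {
  if (null$sd == 0) return(if (s > null$mean) Inf else -Inf)
  (s - null$mean) / null$sd
}

#' Test an alignment for statistical significance
#'
#' Significant iff the z-score of the alignment score against the random
#' topology-preserving null reaches `cutoff` (boundary inclusive). With a
#' degenerate null (`sd == 0`), a score above the null mean counts as
#' significant and a score at or below it does not.
#'
#' @param a an `rnq_alignment`.
#' @inheritParams sample_null_scores
#' @param cutoff z-score cut-off. Default 3.
#' @return list with `significant` (logical) and `z` (may be `Inf`/`-Inf`
#'   for a degenerate null).
#' @export
is_significant <- function(a, q, t, sim, p = scoring_params(), cutoff = 3,
                           n_null = 10000L, seed = 1L) {
  null <- sample_null_scores(q, t, sim, p, n_null = n_null, seed = seed)
  z <- z_score_safe(a$score, null)
  list(significant = z >= cutoff, z = z)
}
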