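#' Generate a synthetic target network
#'
#' Random-graph stand-in for a protein-protein interaction network. Two
#' standard models are offered; density presets mirror the interaction
#' densities of well-studied bacterial and mouse interactomes (about 4.7,
#' 4.1 and 2.5 interactions per protein). Edge weights are uniform on
#' \[0.5, 1\] and only the largest connected component is kept (its size is
#' reported via a message when nodes are dropped).
#'
#' @param n_nodes number of nodes before trimming to the largest component.
#' @param model `"preferential_attachment"` or `"erdos_renyi"`.
#' @param avg_degree target mean degree (interactions per protein).
#' @param preset optional density preset: `"ecoli"` (4.7), `"hpylori"`
#'   (4.1) or `"mouse"` (2.5); overrides `avg_degree`.
#' @param seed RNG seed.
#' @param id network label.
#' @return an `rnq_network`.
#' @export
generate_target <- function(n_nodes = 200L,
                            model = c("preferential_attachment",
                                      "erdos_renyi"),
                            avg_degree = 2.5, preset = NULL, seed = 1L,
                            id = "target") {
  model <- match.arg(model)
  if (!is.null(preset)) {
    presets <- c(ecoli = 4.7, hpylori = 4.1, mouse = 2.5)
    if (!preset %in% names(presets))
      abort_config(sprintf("unknown density preset '%s'", preset))
    avg_degree <- presets[[preset]]
  }
  if (n_nodes < 2) abort_validation("n_nodes must be >= 2")
  if (avg_degree <= 0 || avg_degree >= n_nodes)
    abort_config("avg_degree must be in (0, n_nodes)")
  with_seed(seed, {
    g <- if (model == "erdos_renyi") {
      igraph::sample_gnp(n_nodes, p = avg_degree / (n_nodes - 1))
    } else {
      igraph::sample_pa(n_nodes, m = max(1L, round(avg_degree / 2)),
                        directed = FALSE)
    }
    igraph::V(g)$name <- sprintf("t%03d", seq_len(n_nodes))
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    if (length(keep) < n_nodes)
      message(sprintf("keeping largest component: %d of %d nodes",
                      length(keep), n_nodes))
    g <- igraph::induced_subgraph(g, keep)
    el <- igraph::as_data_frame(g, what = "edges")
    w <- stats::runif(nrow(el), 0.5, 1)
    network(nodes = igraph::V(g)$name,
            edges = data.frame(u = el$from, v = el$to, w = w,
                               stringsAsFactors = FALSE),
            id = id)
  })
}

#' Sample a query tree from a target by random walk
#'
#' Identical construction to [sample_reference()] with `k = m`: queries are
#' walk-grown subtrees of the target. Node ids stay target node ids, so the
#' planted location is known by construction.
#'
#' @param t target network.
#' @param m query size in nodes. Default 6.
#' @param seed RNG seed.
#' @param id query label.
#' @return an `rnq_query_tree`.
#' @export
sample_query <- function(t, m = 6L, seed = 1L, id = "query") {
  r <- sample_reference(t, k = m, seed = seed, ref_id = id)
  r$tree
}

#' Perturb the topology of a query tree
#'
#' Three tree-preserving edits: `insert_leaf` attaches a new node to a
#' random node; `split_edge` replaces a random edge (u, v) with (u, w) and
#' (w, v) through a new node w; `delete_node` removes a random node of
#' degree 1 (with its edge) or degree 2 (reconnecting its neighbours).
#' New edges get weight 1.
#'
#' @param q query tree.
#' @param op one of `"insert_leaf"`, `"split_edge"`, `"delete_node"`.
#' @param seed RNG seed.
#' @return a perturbed `rnq_query_tree`.
#' @export
perturb_topology <- function(q, op = c("insert_leaf", "split_edge",
                                       "delete_node"), seed = 1L) {
  op <- match.arg(op)
  with_seed(seed, {
    new_id <- function() {
      i <- 1L
      repeat {
        cand <- sprintf("n%03d", i)
        if (!cand %in% q$nodes) return(cand)
        i <- i + 1L
      }
    }
    if (op == "insert_leaf") {
      v <- q$nodes[sample.int(length(q$nodes), 1L)]
      w <- new_id()
      query_tree(nodes = c(q$nodes, w),
                 edges = rbind(q$edges,
                               data.frame(u = v, v = w, w = 1.0)),
                 id = q$id)
    } else if (op == "split_edge") {
      if (nrow(q$edges) == 0)
        abort_validation("cannot split an edge of an edgeless tree")
      i <- sample.int(nrow(q$edges), 1L)
      u <- q$edges$u[i]; v <- q$edges$v[i]
      w <- new_id()
      query_tree(nodes = c(q$nodes, w),
                 edges = rbind(q$edges[-i, , drop = FALSE],
                               data.frame(u = c(u, w), v = c(w, v),
                                          w = c(1.0, 1.0))),
                 id = q$id)
    } else {
      deg <- stats::setNames(rep(0L, length(q$nodes)), q$nodes)
      tab <- table(c(q$edges$u, q$edges$v))
      deg[names(tab)] <- as.integer(tab)
      cand <- names(deg)[deg %in% c(1L, 2L)]
      if (length(cand) == 0)
        abort_validation("no degree-1 or degree-2 node to delete")
      w <- cand[sample.int(length(cand), 1L)]
      inc <- q$edges$u == w | q$edges$v == w
      nbrs <- setdiff(unique(c(q$edges$u[inc], q$edges$v[inc])), w)
      edges <- q$edges[!inc, , drop = FALSE]
      if (length(nbrs) == 2)
        edges <- rbind(edges, data.frame(u = nbrs[1], v = nbrs[2], w = 1.0))
      query_tree(nodes = setdiff(q$nodes, w), edges = edges, id = q$id)
    }
  })
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate random amino-acid sequences
#'
#' @param nodes names for the sequences (one per node).
#' @param length sequence length. Default 300.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
random_sequences <- function(nodes, length = 300L, seed = 1L) {
  with_seed(seed, {
    stats::setNames(vapply(seq_along(nodes), function(i)
      paste(sample(aa_alphabet, length, replace = TRUE), collapse = ""), ""),
      nodes)
  })
}

#' Mutate amino-acid sequences at a given rate
#'
#' Each residue is independently replaced with probability `mu_percent/100`
#' by a uniform choice among the 19 other amino acids (a replacement always
#' differs from the original).
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param mu_percent mutation percentage in \[0, 100\].
#' @param seed RNG seed.
#' @return the mutated named character vector.
#' @export
mutate_sequences <- function(seqs, mu_percent, seed = 1L) {
  if (mu_percent < 0 || mu_percent > 100)
    abort_validation("mu_percent must be in [0, 100]")
  with_seed(seed, {
    out <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      if (!all(ch %in% aa_alphabet))
        abort_validation("sequence contains a non amino-acid letter")
      hit <- stats::runif(length(ch)) < mu_percent / 100
      if (any(hit)) {
        ch[hit] <- vapply(ch[hit], function(a) {
          others <- aa_alphabet[aa_alphabet != a]
          others[sample.int(19L, 1L)]
        }, "")
      }
      paste(ch, collapse = "")
    }, "")
    stats::setNames(out, names(seqs))
  })
}

#' Sequence-identity similarity
#'
#' Similarity between two sequences is the fraction of agreeing positions
#' over the longer length (a BLAST-free surrogate; E-value tables enter via
#' [similarity_from_evalues()] instead).
#'
#' @param q_seqs,t_seqs named character vectors of sequences.
#' @return an `rnq_sim` over all pairs.
#' @export
similarity_from_sequences <- function(q_seqs, t_seqs) {
  rows <- list()
  for (qn in names(q_seqs)) for (tn in names(t_seqs)) {
    a <- strsplit(q_seqs[[qn]], "")[[1]]
    b <- strsplit(t_seqs[[tn]], "")[[1]]
    L <- min(length(a), length(b))
    s <- if (L == 0) 0 else sum(a[seq_len(L)] == b[seq_len(L)]) /
      max(length(a), length(b))
    rows[[length(rows) + 1L]] <- data.frame(q = qn, t = tn, s = s,
                                            stringsAsFactors = FALSE)
  }
  similarity_matrix(do.call(rbind, rows))
}

#' Decay a similarity matrix toward background noise
#'
#' Sequence-free surrogate for homology perturbation: each stored entry
#' moves toward a uniform \[0, 0.1\] background,
#' `sim' = sim * (1 - mu/100) + background * mu/100`.
#'
#' @param sim an `rnq_sim`.
#' @param mu_percent decay percentage in \[0, 100\].
#' @param seed RNG seed.
#' @return the perturbed `rnq_sim`.
#' @export
perturb_similarity <- function(sim, mu_percent, seed = 1L) {
  if (mu_percent < 0 || mu_percent > 100)
    abort_validation("mu_percent must be in [0, 100]")
  e <- sim$entries
  if (nrow(e) == 0) return(sim)
  with_seed(seed, {
    bg <- stats::runif(nrow(e), 0, 0.1)
    e$s <- e$s * (1 - mu_percent / 100) + bg * (mu_percent / 100)
    similarity_matrix(e)
  })
}

#' Self-similarity of a target network
#'
#' The within-network homology table used when aligning references (drawn
#' from the target) back to the target: identity pairs at similarity 1,
#' optional paralog pairs (duplicated-gene surrogates) at high similarity,
#' and sparse uniform \[0, 0.1\] background pairs.
#'
#' @param t target network.
#' @param paralog_pairs number of random symmetric high-similarity pairs.
#' @param background_pairs number of random background pairs.
#' @param seed RNG seed.
#' @return an `rnq_sim`.
#' @export
self_similarity <- function(t, paralog_pairs = 0L, background_pairs = 0L,
                            seed = 1L) {
  rows <- data.frame(q = t$nodes, t = t$nodes, s = 1.0,
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    if (paralog_pairs > 0) {
      for (i in seq_len(paralog_pairs)) {
        pr <- sample(t$nodes, 2L)
        s <- stats::runif(1, 0.7, 1)
        rows <- rbind(rows,
                      data.frame(q = pr, t = rev(pr), s = s,
                                 stringsAsFactors = FALSE))
      }
    }
    if (background_pairs > 0) {
      for (i in seq_len(background_pairs)) {
        pr <- sample(t$nodes, 2L)
        rows <- rbind(rows,
                      data.frame(q = pr[1], t = pr[2],
                                 s = stats::runif(1, 0, 0.1),
                                 stringsAsFactors = FALSE))
      }
    }
    suppressWarnings(similarity_matrix(rows))
  })
}

#' Plant a query motif into a target network
#'
#' Embeds the query as a subtree at a random walk-sampled site (adding any
#' missing edges at weight 1), sets the similarity of each query node to its
#' planted image to 1 and all other query-target pairs to uniform
#' \[0, 0.1\] background. The planted site is returned as ground truth.
#'
#' @param t target network.
#' @param q query tree (smaller than the target).
#' @param seed RNG seed.
#' @return list with `target` (modified network), `sim_qt`, `site` (named
#'   vector query node -> planted target node).
#' @export
plant_motif <- function(t, q, seed = 1L) {
  if (length(q$nodes) >= length(t$nodes))
    abort_validation("query must be smaller than the target")
  site_tree <- sample_query(t, m = length(q$nodes), seed = seed)
  site_nodes <- site_tree$nodes
  # map query nodes onto the site so that every query edge exists: walk the
  # query tree and the site tree in parallel root-down
  qrt <- rooted_tree(q)
  srt <- rooted_tree(site_tree)
  # simple order-based pairing may need new edges; add the missing ones
  site <- stats::setNames(srt$bfs[seq_along(qrt$bfs)], qrt$bfs)
  edges <- t$edges
  wenv <- edge_weight_env(t)
  add_u <- character(0); add_v <- character(0)
  for (i in seq_len(nrow(q$edges))) {
    a <- site[[q$edges$u[i]]]; b <- site[[q$edges$v[i]]]
    if (is.na(edge_weight(wenv, a, b))) {
      add_u <- c(add_u, a); add_v <- c(add_v, b)
    }
  }
  if (length(add_u) > 0)
    edges <- rbind(edges, data.frame(u = add_u, v = add_v, w = 1.0,
                                     stringsAsFactors = FALSE))
  target2 <- network(nodes = t$nodes, edges = edges, id = t$id)
  with_seed(seed + 1L, {
    rows <- data.frame(q = names(site), t = unname(site), s = 1.0,
                       stringsAsFactors = FALSE)
    for (qn in q$nodes) {
      others <- setdiff(target2$nodes, site[[qn]])
      rows <- rbind(rows, data.frame(q = qn, t = others,
                                     s = stats::runif(length(others), 0, 0.1),
                                     stringsAsFactors = FALSE))
    }
    list(target = target2, sim_qt = similarity_matrix(rows), site = site)
  })
}

#' Generate a complete synthetic study instance
#'
#' A reproducible bundle emulating the experimental constructions: a random
#' target, walk-sampled queries, the target self-similarity (with paralog
#' pairs so references can have multiple significant mappings), the
#' query-target similarity (queries are target subtrees, so their rows come
#' from the self-similarity), and the planted ground-truth sites.
#'
#' @param n_nodes target size. Default 200.
#' @param model target random-graph model.
#' @param avg_degree target density.
#' @param n_queries number of base queries. Default 10.
#' @param m query size. Default 6.
#' @param paralog_pairs paralog pairs in the self-similarity (default 5% of
#'   the node count).
#' @param seed RNG seed.
#' @return an `rnq_instance` list with `target`, `queries`, `sim_tt`,
#'   `sim_qt`, `planted`, `seed`, `config`.
#' @export
synthetic_instance <- function(n_nodes = 200L,
                               model = "preferential_attachment",
                               avg_degree = 2.5, n_queries = 10L, m = 6L,
                               paralog_pairs = round(0.05 * n_nodes),
                               seed = 1L) {
  target <- generate_target(n_nodes, model, avg_degree, seed = seed)
  sim_tt <- self_similarity(target, paralog_pairs = paralog_pairs,
                            background_pairs = round(0.1 * n_nodes),
                            seed = seed + 1L)
  queries <- lapply(seq_len(n_queries), function(i)
    sample_query(target, m = m, seed = seed + 100L + i,
                 id = sprintf("Q%02d", i)))
  qnodes <- sort(unique(unlist(lapply(queries, `[[`, "nodes"))))
  sim_qt <- restrict_sim(sim_tt, qnodes = qnodes)
  planted <- lapply(queries, function(qq)
    stats::setNames(qq$nodes, qq$nodes))
  names(planted) <- vapply(queries, `[[`, "", "id")
  structure(list(target = target, queries = queries, sim_tt = sim_tt,
                 sim_qt = sim_qt, planted = planted, seed = as.integer(seed),
                 config = list(n_nodes = n_nodes, model = model,
                               avg_degree = avg_degree,
                               n_queries = n_queries, m = m,
                               paralog_pairs = paralog_pairs)),
            class = "rnq_instance")
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort_io("reading FASTA requires the Biostrings package")
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write amino-acid sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort_io("writing FASTA requires the Biostrings package")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
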