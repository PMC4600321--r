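# Shared in-code fixtures: everything is generated, nothing is stored.

# connected Erdos-Renyi target with weighted edges and sorted ids
rnd_target <- function(n, p_edge = 0.35, seed = 1, prefix = "t") {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge)
  while (igraph::components(g)$no > 1) g <- igraph::sample_gnp(n, p_edge)
  el <- igraph::as_edgelist(g)
  tn <- sprintf("%s%02d", prefix, seq_len(n))
  network(nodes = tn,
          edges = data.frame(u = tn[el[, 1]], v = tn[el[, 2]],
                             w = round(stats::runif(nrow(el), 0.5, 1), 3)),
          id = "t")
}

rnd_tree <- function(m, seed = 1, prefix = "q") {
  set.seed(seed)
  qn <- sprintf("%s%d", prefix, seq_len(m))
  if (m == 1) return(query_tree(nodes = qn))
  el <- igraph::as_edgelist(igraph::sample_tree(m))
  query_tree(nodes = qn,
             edges = data.frame(u = qn[el[, 1]], v = qn[el[, 2]], w = 1))
}

rnd_sim <- function(qnodes, tnodes, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(q = qnodes, t = tnodes, stringsAsFactors = FALSE)
  grid$s <- round(stats::runif(nrow(grid)), 3)
  similarity_matrix(grid)
}

# one random small instance for oracle comparisons
mk_instance <- function(seed, m_range = 3:5, n_range = 8:12) {
  set.seed(seed)
  m <- sample(m_range, 1)
  n <- sample(n_range, 1)
  q <- rnd_tree(m, seed = seed + 1)
  t <- rnd_target(n, seed = seed + 2)
  sim <- rnd_sim(q$nodes, t$nodes, seed = seed + 3)
  list(q = q, t = t, sim = sim, m = m, n = n)
}

# a random injective forced map of `k` pairs
rnd_forced <- function(q, t, k, seed) {
  set.seed(seed)
  stats::setNames(sample(t$nodes, k), sample(q$nodes, k))
}

# small synthetic instance + built index, used by index/query tests
build_demo_index <- function(seed, n_nodes = 25, k = 3, eta = 60,
                             cutoff = 3, n_null = 200,
                             p = scoring_params(max_ins = 1, max_del = 1)) {
  inst <- synthetic_instance(n_nodes = n_nodes, avg_degree = 3,
                             n_queries = 2, m = 4,
                             paralog_pairs = 3, seed = seed)
  ix <- suppressWarnings(
    build_index(inst$target, inst$sim_tt, p, k = k, eta = eta,
                cutoff = cutoff, seed = seed + 50, n_null = n_null))
  list(inst = inst, ix = ix, p = p)
}
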