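test_that("reference screening rejects zero similarity and accepts isomorphs", {
  q <- rnd_tree(3, seed = 1)
  t <- rnd_target(12, seed = 2)
  r <- sample_reference(t, k = 3, seed = 3)
  p <- scoring_params(max_ins = 1, max_del = 1)
  expect_null(align_to_reference(q, r, similarity_matrix(NULL), p,
                                 theta = 0.5, seed = 1))
  # identity similarity 1 between the query and the reference nodes in
  # BFS-parallel order gives (near-)ideal score at theta <= 1 when the
  # shapes are both paths
  path_q <- query_tree(edges = data.frame(u = c("a", "b"), v = c("b", "c"),
                                          w = 1))
  ref_tree <- query_tree(edges = data.frame(u = c("x", "y"), v = c("y", "z"),
                                            w = 1))
  ref <- structure(list(ref_id = "R", tree = ref_tree, seed = 1L),
                   class = "rnq_reference")
  sim_iso <- similarity_matrix(data.frame(q = c("a", "b", "c"),
                                          t = c("x", "y", "z"), s = 1))
  acc <- align_to_reference(path_q, ref, sim_iso,
                            scoring_params(max_ins = 0, max_del = 0),
                            theta = 1.0, seed = 2)
  expect_false(is.null(acc))
  expect_equal(acc$score, acc$ideal)
})

test_that("acceptance flips exactly once as theta sweeps upward", {
  q <- rnd_tree(3, seed = 11)
  t <- rnd_target(12, seed = 12)
  r <- sample_reference(t, k = 4, seed = 13)
  sim <- rnd_sim(q$nodes, r$tree$nodes, seed = 14)
  p <- scoring_params(max_ins = 1, max_del = 1)
  acc <- vapply(seq(0.05, 1, by = 0.05), function(th)
    !is.null(align_to_reference(q, r, sim, p, theta = th, seed = 5)), TRUE)
  expect_true(all(diff(acc) <= 0))   # TRUE...TRUE FALSE...FALSE
})

test_that("indirect mappings compose through the reference", {
  psi <- alignment(matched = c(a = "e", b = "f"), deleted_query = "c")
  phi <- list(phi = c(e = "h", f = "g"))
  q <- query_tree(edges = data.frame(u = c("a", "b"), v = c("b", "c"), w = 1))
  im <- compose_indirect(psi, phi, q, ref_id = "R1", mapping_index = 1L)
  expect_equal(im$forced[["b"]], "g")     # psi(b)=f, phi(f)=g
  expect_equal(im$forced[["a"]], "h")
  expect_setequal(im$free_query, "c")     # deletion breaks the chain
  expect_setequal(im$S_prime, c("h", "g"))

  # identity compositions force everything
  psi_id <- alignment(matched = c(a = "a", b = "b", c = "c"))
  phi_id <- list(phi = c(a = "a", b = "b", c = "c"))
  im_id <- compose_indirect(psi_id, phi_id, q)
  expect_length(im_id$free_query, 0)
  expect_identical(unname(im_id$forced), c("a", "b", "c"))

  # a reference node deleted in phi also leaves the query node free
  phi_del <- list(phi = c(e = "h"))
  im_del <- compose_indirect(psi, phi_del, q)
  expect_setequal(im_del$free_query, c("b", "c"))
})

test_that("the bipartite matching value is exact on enumerable cases", {
  # independent oracle: enumerate all assignments of rows to columns
  enum_best <- function(W) {
    nr <- nrow(W); nc <- ncol(W)
    cols <- seq_len(nc)
    best <- 0
    pick <- function(r, used, acc) {
      if (r > nr) { best <<- max(best, acc); return(invisible(NULL)) }
      pick(r + 1, used, acc)                    # leave row unmatched
      for (j in setdiff(cols, used))
        pick(r + 1, c(used, j), acc + W[r, j])
      invisible(NULL)
    }
    pick(1, integer(0), 0)
    best
  }
  set.seed(3)
  for (rep in 1:8) {
    nr <- sample(2:4, 1); nc <- sample(2:5, 1)
    W <- matrix(stats::runif(nr * nc), nrow = nr)
    expect_equal(refnetq:::max_weight_matching_value(W), enum_best(W))
  }
})

test_that("a fully forced indirect mapping bounds with realized edge weights", {
  q <- query_tree(edges = data.frame(u = "a", v = "b", w = 1))
  t <- network(edges = data.frame(u = c("x", "y"), v = c("y", "z"),
                                  w = c(0.8, 0.6)))
  sim <- similarity_matrix(data.frame(q = c("a", "b"), t = c("x", "y"),
                                      s = c(0.5, 0.4)))
  im <- structure(list(forced = c(a = "x", b = "y"), S = c("a", "b"),
                       S_prime = c("x", "y"), free_query = character(),
                       ref_id = "R", mapping_index = 1L),
                  class = "rnq_indirect")
  # forced sims + the realized weight of the a-b edge (x-y adjacent)
  expect_equal(upper_bound(q, t, sim, im), 0.5 + 0.4 + 0.8)

  # one free node: forced sum + its best similarity outside S' + allowance
  q3 <- query_tree(edges = data.frame(u = c("a", "b"), v = c("b", "c"),
                                      w = 1))
  sim3 <- similarity_matrix(data.frame(
    q = c("a", "b", "c", "c"), t = c("x", "y", "z", "x"),
    s = c(0.5, 0.4, 0.3, 0.9)))
  im3 <- structure(list(forced = c(a = "x", b = "y"), S = c("a", "b"),
                        S_prime = c("x", "y"), free_query = "c",
                        ref_id = "R", mapping_index = 1L),
                   class = "rnq_indirect")
  # c's best column outside {x, y} is z (0.3); x at 0.9 is excluded;
  # edge terms: (a,b) realized 0.8, (b,c) free so max target weight 0.8
  expect_equal(upper_bound(q3, t, sim3, im3), 0.5 + 0.4 + 0.3 + 0.8 + 0.8)
})

test_that("the upper bound dominates the constrained brute-force optimum", {
  p <- scoring_params(max_ins = 1, max_del = 1)
  for (s in 1:40) {
    inst <- mk_instance(5000 + s, m_range = 3:4, n_range = 8:10)
    nf <- sample(1:2, 1)
    forced <- rnd_forced(inst$q, inst$t, nf, seed = s)
    im <- structure(list(forced = forced, S = names(forced),
                         S_prime = unname(forced),
                         free_query = setdiff(inst$q$nodes, names(forced)),
                         ref_id = "R", mapping_index = 1L),
                    class = "rnq_indirect")
    ub <- upper_bound(inst$q, inst$t, inst$sim, im)
    bf <- brute_force_align(inst$q, inst$t, inst$sim, p, forced = forced)
    if (!is.null(bf)) expect_gte(ub, bf$score - 1e-9)
  }
})

test_that("induced alignment respects forcing, bridges or fails as required", {
  q <- query_tree(edges = data.frame(u = "a", v = "b", w = 1))
  tn <- sprintf("n%d", 1:6)
  chain <- network(edges = data.frame(u = tn[1:5], v = tn[2:6], w = 1))
  sim <- similarity_matrix(data.frame(q = c("a", "b"), t = c("n1", "n3"),
                                      s = 1))
  p1 <- scoring_params(max_ins = 1, max_del = 0)
  im <- structure(list(forced = c(a = "n1", b = "n3"), S = c("a", "b"),
                       S_prime = c("n1", "n3"), free_query = character(),
                       ref_id = "R", mapping_index = 1L),
                  class = "rnq_indirect")
  a <- induced_align(q, chain, sim, im, p1, seed = 1)
  expect_identical(a$inserted_target, "n2")
  expect_equal(a$score, 1 + 1 + p1$delta_ins)

  # distance 4 cannot be bridged with max_ins = 2
  im_far <- structure(list(forced = c(a = "n1", b = "n5"), S = c("a", "b"),
                           S_prime = c("n1", "n5"), free_query = character(),
                           ref_id = "R", mapping_index = 1L),
                      class = "rnq_indirect")
  expect_null(induced_align(q, chain,
                            similarity_matrix(data.frame(
                              q = c("a", "b"), t = c("n1", "n5"), s = 1)),
                            im_far, scoring_params(max_ins = 2, max_del = 0),
                            seed = 1))
})

test_that("induced alignment matches the constrained oracle", {
  p <- scoring_params(max_ins = 1, max_del = 1)
  agree <- 0L; feasible <- 0L
  for (s in 1:20) {
    inst <- mk_instance(6000 + s, m_range = 3:4, n_range = 8:10)
    forced <- rnd_forced(inst$q, inst$t, sample(1:2, 1), seed = s)
    im <- structure(list(forced = forced, S = names(forced),
                         S_prime = unname(forced),
                         free_query = setdiff(inst$q$nodes, names(forced)),
                         ref_id = "R", mapping_index = 1L),
                    class = "rnq_indirect")
    bf <- brute_force_align(inst$q, inst$t, inst$sim, p, forced = forced)
    cc <- induced_align(inst$q, inst$t, inst$sim, im, p, seed = s)
    if (is.null(bf)) { expect_null(cc); next }
    feasible <- feasible + 1L
    if (!is.null(cc) && abs(cc$score - bf$score) < 1e-9) agree <- agree + 1L
    if (!is.null(cc)) expect_lte(cc$score, bf$score + 1e-9)
  }
  expect_gte(agree, ceiling(0.85 * feasible))
})

test_that("querying an empty index reports no alignment and zero counters", {
  demo <- build_demo_index(121)
  ix <- demo$ix
  ix$references <- list()
  ix$cover_nodes <- character()
  res <- query_index(demo$inst$queries[[1]], demo$inst$target, ix,
                     demo$inst$sim_qt, demo$p, seed = 1, n_null = 100)
  expect_null(res$best)
  expect_equal(res$examined, 0L)
  expect_equal(res$total_candidates, 0L)
})

test_that("pruning counters account for every stored candidate", {
  demo <- build_demo_index(131)
  res <- query_index(demo$inst$queries[[1]], demo$inst$target, demo$ix,
                     demo$inst$sim_qt, demo$p, seed = 7, n_null = 200)
  expect_equal(res$pruned_by_screen + res$pruned_by_bound + res$examined,
               res$total_candidates)
  # bound dominance on every examined candidate
  ex <- res$log[res$log$examined & !is.na(res$log$score), , drop = FALSE]
  if (nrow(ex) > 0) expect_true(all(ex$ub >= ex$score - 1e-9))
})

test_that("bound pruning never changes the final best score", {
  for (s in c(141, 151)) {
    demo <- build_demo_index(s)
    for (qi in 1:2) {
      r1 <- query_index(demo$inst$queries[[qi]], demo$inst$target, demo$ix,
                        demo$inst$sim_qt, demo$p, seed = s, n_null = 100,
                        prune = TRUE)
      r2 <- query_index(demo$inst$queries[[qi]], demo$inst$target, demo$ix,
                        demo$inst$sim_qt, demo$p, seed = s, n_null = 100,
                        prune = FALSE)
      expect_equal(is.null(r1$best), is.null(r2$best))
      if (!is.null(r1$best))
        expect_equal(r1$best$score, r2$best$score, tolerance = 1e-12)
    }
  }
})

test_that("query results are deterministic under a fixed seed", {
  demo <- build_demo_index(161)
  r1 <- query_index(demo$inst$queries[[2]], demo$inst$target, demo$ix,
                    demo$inst$sim_qt, demo$p, seed = 3, n_null = 150)
  r2 <- query_index(demo$inst$queries[[2]], demo$inst$target, demo$ix,
                    demo$inst$sim_qt, demo$p, seed = 3, n_null = 150)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$z, r2$z)
})

test_that("a stale index is refused at query time", {
  demo <- build_demo_index(171)
  other <- rnd_target(20, seed = 1)
  expect_error(query_index(demo$inst$queries[[1]], other, demo$ix,
                           demo$inst$sim_qt, demo$p),
               class = "rnq_stale_index_error")
})
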