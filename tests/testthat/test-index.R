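test_that("random-walk references are k-node subtrees of the target", {
  t <- rnd_target(20, seed = 5)
  r <- sample_reference(t, k = 5, seed = 9, ref_id = "R1")
  expect_s3_class(r$tree, "rnq_query_tree")
  expect_length(r$tree$nodes, 5)
  expect_true(all(r$tree$nodes %in% t$nodes))
  wenv <- edge_weight_env(t)
  for (i in seq_len(nrow(r$tree$edges)))
    expect_false(is.na(edge_weight(wenv, r$tree$edges$u[i],
                                   r$tree$edges$v[i])))
  # k = 1 degenerates to a single node
  r1 <- sample_reference(t, k = 1, seed = 2)
  expect_length(r1$tree$nodes, 1)
  expect_equal(nrow(r1$tree$edges), 0)
})

test_that("on a path target every walk-grown reference is a subpath", {
  tn <- sprintf("p%02d", 1:10)
  path <- network(edges = data.frame(u = tn[1:9], v = tn[2:10], w = 1))
  for (s in 1:10) {
    r <- sample_reference(path, k = 4, seed = s)
    idx <- sort(match(r$tree$nodes, tn))
    expect_identical(idx, seq(min(idx), max(idx)))   # contiguous interval
  }
  expect_error(sample_reference(network(nodes = c("a", "b")), k = 3),
               class = "rnq_build_error")
})

test_that("extract_mappings recovers two disjoint planted copies", {
  # target: two copies of a 3-node path plus a connector chain, reference
  # equal to the first copy with similarity 1 to both copies
  dch <- sprintf("d%02d", 1:12)
  t <- network(edges = data.frame(
    u = c("a1", "a2", "b1", "b2", "a3", "c1", "c2", "c2",
          dch[1:11]),
    v = c("a2", "a3", "b2", "b3", "c1", "c2", "b1", dch[1],
          dch[2:12]),
    w = 1))
  ref_tree <- query_tree(edges = data.frame(u = c("a1", "a2"),
                                            v = c("a2", "a3"), w = 1))
  r <- structure(list(ref_id = "R1", tree = ref_tree, seed = 1L),
                 class = "rnq_reference")
  sim <- similarity_matrix(data.frame(
    q = rep(c("a1", "a2", "a3"), 2),
    t = c("a1", "a2", "a3", "b1", "b2", "b3"),
    s = 1))
  p <- scoring_params(max_ins = 0, max_del = 0)
  ms <- extract_mappings(r, t, sim, p, cutoff = 3, seed = 4, n_null = 300)
  expect_gte(length(ms$mappings), 2)
  sites <- lapply(ms$mappings, `[[`, "subnetwork")
  expect_true(any(vapply(sites, function(s) setequal(s, c("a1", "a2", "a3")),
                         TRUE)))
  expect_true(any(vapply(sites, function(s) setequal(s, c("b1", "b2", "b3")),
                         TRUE)))
  # non-overlap
  expect_equal(anyDuplicated(unlist(sites)), 0)
})

test_that("an all-zero similarity yields an empty mapping set", {
  t <- rnd_target(15, seed = 3)
  r <- sample_reference(t, k = 3, seed = 1)
  ms <- extract_mappings(r, t, similarity_matrix(NULL),
                         scoring_params(max_ins = 1, max_del = 1),
                         cutoff = 3, seed = 2, n_null = 200)
  expect_length(ms$mappings, 0)
})

test_that("initial-set construction stops at the coverage goal", {
  demo <- build_demo_index(61)
  inst <- demo$inst; p <- demo$p
  ini <- build_initial_set(inst$target, inst$sim_tt, p, k = 3, eta = 40,
                           cutoff = 3, seed = 21, n_null = 200)
  goal <- ceiling(0.40 * length(inst$target$nodes))
  expect_gte(length(ini$cover), goal)
  expect_true(ini$complete)
  # dropping the last reference must leave coverage below the goal
  # (the loop stops at the first reference reaching it)
  if (length(ini$references) > 1) {
    cover_wo <- sort(unique(unlist(lapply(
      ini$references[-length(ini$references)],
      function(x) refnetq:::mapping_cover(x$mappings)))))
    expect_lt(length(cover_wo), goal)
  }
})

test_that("greedy set cover picks the textbook solution", {
  mk <- function(id, cover) {
    list(ref = structure(list(ref_id = id,
                              tree = query_tree(nodes = "x"), seed = 1L),
                         class = "rnq_reference"),
         mappings = structure(list(ref_id = id, mappings = list(
           list(phi = c(x = cover[1]), deleted = character(),
                inserted = character(), score = 1, z = 5,
                subnetwork = cover))), class = "rnq_mapping_set"))
  }
  initial <- list(mk("R1", c("1", "2", "3")), mk("R2", c("3", "4")),
                  mk("R3", c("1", "2")))
  fin <- select_final_set(initial, eta = 100, n_target_nodes = 4)
  expect_length(fin, 2)
  expect_identical(vapply(fin, function(x) x$ref$ref_id, ""), c("R1", "R2"))

  # one reference covering everything is selected alone
  big <- list(mk("R1", c("1", "2")), mk("R2", c("1", "2", "3", "4")))
  fin2 <- select_final_set(big, eta = 100, n_target_nodes = 4)
  expect_length(fin2, 1)
  expect_identical(fin2[[1]]$ref$ref_id, "R2")

  # unreachable goal returns everything with a warning
  expect_warning(all3 <- select_final_set(initial, eta = 100,
                                          n_target_nodes = 10))
  expect_length(all3, 3)
})

test_that("built indexes satisfy their structural invariants", {
  demo <- build_demo_index(77)
  ix <- demo$ix
  expect_lte(length(ix$references), ix$initial_size)
  if (ix$complete) {
    goal <- ceiling(ix$params$eta / 100 * length(demo$inst$target$nodes))
    expect_gte(length(ix$cover_nodes), goal)
  }
  for (entry in ix$references) {
    sites <- lapply(entry$mappings$mappings, `[[`, "subnetwork")
    expect_equal(anyDuplicated(unlist(sites)), 0)       # disjoint
    for (mp in entry$mappings$mappings)
      expect_gte(mp$z, ix$params$cutoff)
  }
})

test_that("index JSON round trips and rejects a stale target", {
  demo <- build_demo_index(91)
  ix <- demo$ix
  f <- withr::local_tempfile(fileext = ".json")
  save_index(ix, f)
  back <- load_index(f, demo$inst$target)
  expect_identical(back$target_checksum, ix$target_checksum)
  expect_identical(back$initial_size, ix$initial_size)
  expect_equal(length(back$references), length(ix$references))
  expect_identical(back$cover_nodes, ix$cover_nodes)
  for (i in seq_along(ix$references)) {
    expect_identical(back$references[[i]]$ref$tree$edges,
                     ix$references[[i]]$ref$tree$edges)
    expect_equal(back$references[[i]]$mappings$mappings,
                 ix$references[[i]]$mappings$mappings, tolerance = 1e-12)
  }
  other <- rnd_target(10, seed = 99)
  expect_error(load_index(f, other), class = "rnq_stale_index_error")
})

test_that("rebuilding with the same seed is byte-identical", {
  d1 <- build_demo_index(101)
  d2 <- build_demo_index(101)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_index(d1$ix, f1); save_index(d2$ix, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cutoff-6 mapping sets are contained in cutoff-3 sets", {
  demo <- build_demo_index(55)
  inst <- demo$inst; p <- demo$p
  r <- sample_reference(inst$target, k = 3, seed = 8)
  null <- sample_null_scores(r$tree, inst$target, inst$sim_tt, p,
                             n_null = 300, seed = 12)
  ms3 <- extract_mappings(r, inst$target, inst$sim_tt, p, cutoff = 3,
                          seed = 13, null = null)
  ms6 <- extract_mappings(r, inst$target, inst$sim_tt, p, cutoff = 6,
                          seed = 13, null = null)
  expect_lte(length(ms6$mappings), length(ms3$mappings))
  if (length(ms6$mappings) > 0)
    for (i in seq_along(ms6$mappings))
      expect_identical(ms6$mappings[[i]]$phi, ms3$mappings[[i]]$phi)
})
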