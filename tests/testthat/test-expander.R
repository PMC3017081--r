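# The extension algorithm: candidate pool, filter conditions (1)-(4),
# compactness score and the greedy growth loop.

test_that("candidate set is the neighbourhood union minus the members", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  expect_setequal(candidate_set(star, "c"), paste0("l", 1:4))

  iso <- igraph::make_graph(~ a - b) + igraph::vertices("x", "y")
  expect_length(candidate_set(iso, c("x", "y")), 0)

  tg <- random_test_graph(12, 0.3, seed = 11)
  mapped <- rownames(tg$adj)[1:4]
  brute <- sort(setdiff(
    rownames(tg$adj)[colSums(tg$adj[mapped, , drop = FALSE]) > 0], mapped))
  expect_identical(candidate_set(tg$graph, mapped), brute)
})

test_that("filter conditions follow the strict-inequality definitions", {
  cfg <- extension_config()
  # v: 3 links into the set, 1 outside -> condition 2 passes (3 > 1*1)
  g <- igraph::make_graph(~ v - s1, v - s2, v - s3, v - o1,
                          s1 - s2, s2 - s3)
  st <- evaluate_candidate(g, c("s1", "s2", "s3"),
                           candidate_set(g, c("s1", "s2", "s3")), "v", cfg)
  expect_equal(st$process_links, 3)
  expect_equal(st$outside_links, 1)
  expect_true(st$cond2)

  # 2 in / 2 out -> strict inequality fails
  g2 <- igraph::make_graph(~ v - s1, v - s2, v - o1, v - o2, s1 - s2)
  st2 <- evaluate_candidate(g2, c("s1", "s2"),
                            candidate_set(g2, c("s1", "s2")), "v", cfg)
  expect_false(st2$cond2)

  # 10-member set, v adjacent to 4 -> coverage 0.4 > 0.3, condition 4 passes
  edges <- c(rbind("v", paste0("s", 1:4)))
  g3 <- igraph::make_graph(edges, directed = FALSE) +
    igraph::vertices(paste0("s", 5:10))
  mapped <- paste0("s", 1:10)
  st3 <- evaluate_candidate(g3, mapped, candidate_set(g3, mapped), "v", cfg)
  expect_true(st3$cond4)
  expect_equal(st3$process_links / st3$process_node_count, 0.4)

  # one realised triangle out of one possible -> ratio 1 > 0.1, condition 3
  g4 <- igraph::make_graph(~ v - u, v - w, u - w, u - x, x - y, w - z)
  mapped4 <- c("u", "x")
  pool4 <- candidate_set(g4, mapped4)
  expect_true("w" %in% pool4)
  st4 <- evaluate_candidate(g4, mapped4, pool4, "v", cfg)
  expect_equal(st4$triangle_links, 1)
  expect_equal(st4$possible_triangles, 1)
  expect_true(st4$cond3)

  expect_error(evaluate_candidate(g4, mapped4, pool4, "zzz", cfg),
               "candidate pool")
})

test_that("first filter admits condition 1 AND any of 2-4", {
  cfg <- extension_config()
  # degree-1 candidate with its only link into the set: rejected by (1)
  g <- igraph::make_graph(~ v - s1, s1 - s2)
  ff <- first_filter(g, c("s1", "s2"), cfg)
  expect_false(ff$admitted[ff$candidate == "v"])
  expect_true(ff$cond2[ff$candidate == "v"])

  # brute-force agreement on random graphs
  for (seed in 1:25) {
    tg <- random_test_graph(sample(8:15, 1), runif(1, 0.2, 0.5), seed = seed)
    mapped <- sample(rownames(tg$adj), sample(3:5, 1))
    ff <- first_filter(tg$graph, mapped, cfg)
    expect_identical(sort(ff$candidate[ff$admitted]),
                     oracle_filter(tg$adj, mapped, cfg))
    # bookkeeping invariants
    expect_true(all(ff$process_links + ff$outside_links == ff$degree))
    expect_true(all(ff$triangle_links <= ff$possible_triangles))
  }
})

test_that("compactness score averages full-network distances with penalty", {
  cfg <- extension_config()
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  expect_equal(compact_score(k3, c("a", "b", "c"), cfg), 1)

  p3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(compact_score(p3, c("a", "b", "c"), cfg), 4 / 3)

  # unreachable pair contributes |V| in node_count mode
  g <- igraph::make_graph(~ a - b) + igraph::vertices(paste0("z", 1:18))
  g <- igraph::add_edges(g, c("z1", "z2"))
  expect_equal(igraph::vcount(g), 20)
  expect_equal(compact_score(g, c("a", "z1"), cfg), 20)
  cfg_fixed <- extension_config(penalty_mode = "fixed", penalty_value = 7)
  expect_equal(compact_score(g, c("a", "z1"), cfg_fixed), 7)

  expect_error(compact_score(k3, "a", cfg), "at least 2")

  # distances are full-network: two set members joined via an outside node
  chain <- igraph::make_graph(~ a - m, m - b)
  expect_equal(compact_score(chain, c("a", "b"), cfg), 2)
})

test_that("greedy extension matches the exhaustive oracle on random graphs", {
  cfg <- extension_config(t3 = 0.3, min_set_size = 2)
  for (seed in 1:40) {
    tg <- random_test_graph(sample(6:12, 1), runif(1, 0.25, 0.55),
                            seed = 1000 + seed)
    mapped <- sample(rownames(tg$adj), sample(2:5, 1))
    res <- extend_set(tg$graph, mapped, cfg)
    orc <- oracle_extend(tg$adj, mapped, cfg)
    expect_identical(res$added, orc$added)
    expect_equal(res$trajectory, orc$trajectory, tolerance = 1e-12)
  }
})

test_that("a bridging candidate joining two components is added first", {
  # two disconnected triangles plus one hub adjacent to all six members
  g <- igraph::make_graph(~ a1 - a2, a2 - a3, a3 - a1,
                          b1 - b2, b2 - b3, b3 - b1,
                          h - a1, h - a2, h - a3, h - b1, h - b2, h - b3)
  mapped <- c("a1", "a2", "a3", "b1", "b2", "b3")
  res <- extend_set(g, mapped, extension_config())
  expect_equal(res$added[1], "h")
  expect_lt(res$trajectory[2], res$trajectory[1])
  orc <- oracle_extend(adj_of(g), mapped, extension_config())
  expect_identical(res$added, orc$added)
})

test_that("extension results satisfy the core invariants", {
  fx <- default_fixture()
  cfg <- extension_config()
  ext <- extend_collection(fx$network, fx$sets, cfg)
  expect_gt(length(ext$results), 0)
  for (res in ext$results) {
    # strict monotone decrease after index 0
    expect_true(all(diff(res$trajectory) < 0))
    expect_equal(length(res$trajectory), length(res$added) + 1)
    # added nodes are distinct, outside the original set, inside the pool
    expect_false(anyDuplicated(res$added) > 0)
    expect_length(intersect(res$added, res$original_mapped), 0)
    pool <- candidate_set(fx$network, res$original_mapped)
    expect_true(all(res$added %in% pool))
    # every added node passed condition 1 and at least one of 2-4
    # against the ORIGINAL set
    d <- res$diagnostics
    for (v in res$added) {
      row <- d[d$candidate == v, ]
      expect_true(row$cond1)
      expect_true(row$cond2 || row$cond3 || row$cond4)
    }
  }
  # determinism: same inputs, same result
  ext2 <- extend_collection(fx$network, fx$sets, cfg)
  expect_identical(ext, ext2)
})

test_that("collection summary applies size floors and counts additions", {
  g <- default_fixture()$network
  small <- list(tiny = list(set_id = "tiny", name = "",
                            members = c("C1_01", "C1_02", "C1_03",
                                        "C1_04", "C1_05")))
  out <- extend_collection(g, small, extension_config(min_set_size = 10))
  expect_equal(out$summary$examined, 0)

  # two sets gaining the same protein: total 2, unique 1.  In each set the
  # third member is reachable only through the hub h, so adding h is the
  # unique compactness improvement for both.
  tri <- igraph::make_graph(~ a1 - a2, b1 - b2,
                            h - a1, h - a2, h - a3, h - b1, h - b2, h - b3)
  sets <- list(A = list(set_id = "A", name = "", members = c("a1", "a2", "a3")),
               B = list(set_id = "B", name = "", members = c("b1", "b2", "b3")))
  out2 <- extend_collection(tri, sets, extension_config(min_set_size = 2))
  expect_equal(out2$summary$total_added, 2)
  expect_equal(out2$summary$unique_added, 1)
  expect_identical(out2$results$A$added, "h")

  exts <- extended_gene_sets(sets, out2)
  expect_setequal(exts$A$members, c("a1", "a2", "a3", "h"))
})

test_that("extension config validates its thresholds", {
  expect_error(extension_config(t3 = 1), "t3")
  expect_error(extension_config(t1 = 0))
  expect_error(extension_config(t2 = 0))
  expect_error(extension_config(min_set_size = 1))
  expect_error(extension_config(penalty_mode = "fixed"), "penalty_value")
})
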