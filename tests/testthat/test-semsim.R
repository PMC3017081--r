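# Ontology I/O, information content, Jiang-Conrath distance and the
# semantic-similarity validation of extensions.

# Hand-built 7-term DAG:  root -> {a, b}; a -> {a1, a2}; b -> {b1}; and a
# cross-parent term ab with is_a a and is_a b.
toy_onto <- function() {
  terms <- c("root", "a", "b", "a1", "a2", "b1", "ab")
  parents <- list(root = character(), a = "root", b = "root",
                  a1 = "a", a2 = "a", b1 = "b", ab = c("a", "b"))
  structure(list(terms = terms, parents = parents,
                 namespace = stats::setNames(
                   rep("biological_process", 7), terms),
                 name = stats::setNames(paste("term", terms), terms)),
            class = "pe_ontology")
}

toy_ann <- function() {
  list(p1 = "a1", p2 = "a2", p3 = "b1", p4 = "ab",
       p5 = c("a1", "b1"), p6 = "a", p7 = "b", p8 = "root")
}

test_that("OBO and annotation files round-trip through the readers", {
  onto <- toy_onto()
  f <- withr::local_tempfile()
  write_obo(onto, f)
  back <- read_obo(f)
  expect_identical(back$terms, onto$terms)
  expect_identical(back$parents[order(names(back$parents))],
                   onto$parents[order(names(onto$parents))])
  expect_identical(unname(back$namespace[back$terms]),
                   unname(onto$namespace[onto$terms]))

  ann <- toy_ann()
  f2 <- withr::local_tempfile()
  write_annotations(ann, f2)
  back2 <- read_annotations(f2)
  expect_identical(back2[order(names(back2))], ann[order(names(ann))])

  # is_a lines with trailing "! name" comments parse; obsolete terms drop
  f3 <- withr::local_tempfile()
  writeLines(c("format-version: 1.2", "", "[Term]", "id: X:1",
               "namespace: ns", "", "[Term]", "id: X:2",
               "namespace: ns", "is_a: X:1 ! the root", "",
               "[Term]", "id: X:3", "is_obsolete: true"), f3)
  o3 <- read_obo(f3)
  expect_setequal(o3$terms, c("X:1", "X:2"))
  expect_identical(o3$parents[["X:2"]], "X:1")
})

test_that("GAF-style annotation files are detected and aspect-filtered", {
  f <- withr::local_tempfile()
  gafrow <- function(prot, term, asp)
    paste(c("DB", prot, prot, "", term, "REF", "IEA", "", asp,
            rep("", 8)), collapse = "\t")
  writeLines(c("!gaf-version: 2.1",
               gafrow("p1", "a1", "P"), gafrow("p1", "b1", "F"),
               gafrow("p2", "a2", "P")), f)
  ann <- read_annotations(f, aspect = "P")
  expect_identical(ann$p1, "a1")
  expect_identical(ann$p2, "a2")
  ann_all <- read_annotations(f)
  expect_setequal(ann_all$p1, c("a1", "b1"))
})

test_that("information content matches descendant-closure counting", {
  onto <- toy_onto()
  ann <- toy_ann()
  idx <- semsim_index(onto, ann)
  expect_equal(information_content(idx, NULL, "root"), 0)
  # term 'b' covers p3 (b1), p4 (ab), p5 (b1), p7 (b): 4 of 8 -> ln 2
  expect_equal(information_content(idx, NULL, "b"), log(2))
  for (t in onto$terms)
    expect_equal(information_content(idx, NULL, t), oracle_ic(onto, ann, t),
                 tolerance = 1e-12)
  # IC monotone non-decreasing from root to leaves
  for (t in onto$terms) for (p in onto$parents[[t]])
    expect_gte(information_content(idx, NULL, t),
               information_content(idx, NULL, p))
})

test_that("Jiang-Conrath distance matches ancestor-enumeration oracle", {
  onto <- toy_onto()
  ann <- toy_ann()
  idx <- semsim_index(onto, ann)
  for (t in onto$terms) expect_equal(jc_distance(idx, NULL, t, t), 0)
  # siblings whose only common ancestor is the root: d = IC1 + IC2
  expect_equal(jc_distance(idx, NULL, "a", "b"),
               information_content(idx, NULL, "a") +
                 information_content(idx, NULL, "b"))
  pairs <- t(utils::combn(onto$terms, 2))
  for (r in seq_len(nrow(pairs))) {
    t1 <- pairs[r, 1]; t2 <- pairs[r, 2]
    expect_equal(jc_distance(idx, NULL, t1, t2),
                 oracle_jc(onto, ann, t1, t2), tolerance = 1e-12)
    expect_equal(jc_distance(idx, NULL, t1, t2),
                 jc_distance(idx, NULL, t2, t1))
  }
  # the multi-parent term 'ab' must use the more informative of a and b
  expect_equal(jc_distance(idx, NULL, "ab", "b1"),
               information_content(idx, NULL, "ab") +
                 information_content(idx, NULL, "b1") -
                 2 * information_content(idx, NULL, "b"))
  # different namespaces -> no common ancestor
  onto2 <- toy_onto()
  onto2$terms <- c(onto2$terms, "other")
  onto2$parents$other <- character()
  onto2$namespace["other"] <- "molecular_function"
  onto2$name["other"] <- "other"
  ann2 <- c(toy_ann(), list(p9 = "other"))
  expect_error(jc_distance(onto2, ann2, "a", "other"), "common ancestor")
})

test_that("set similarity averages sim = 1/(1+d) over distinct term pairs", {
  onto <- toy_onto()
  ann <- toy_ann()
  idx <- semsim_index(onto, ann)
  # identical single annotations on both sides -> similarity 1
  expect_equal(set_similarity(idx, NULL, "p1", "p1"), 1)
  expect_equal(set_similarity(idx, NULL, "p1", "p5"),
               mean(c(1, 1 / (1 + jc_distance(idx, NULL, "a1", "b1")))))
  # duplicating a protein must not change the value (term-pair weighting)
  expect_equal(set_similarity(idx, NULL, c("p1", "p1"), "p3"),
               set_similarity(idx, NULL, "p1", "p3"))
  # unannotated side errors
  expect_error(set_similarity(idx, NULL, "p1", "nope"), "undefined")
  expect_true(set_similarity(idx, NULL, c("p1", "p2"), c("p3", "p4")) > 0)
  expect_true(set_similarity(idx, NULL, c("p1", "p2"), c("p3", "p4")) <= 1)
})

test_that("community-specific annotations separate real from random draws", {
  fx <- default_fixture()
  idx <- semsim_index(fx$ontology, fx$annotations)
  # within-community similarity exceeds between-community similarity
  c1 <- fx$truth$communities$community_1
  c2 <- fx$truth$communities$community_2
  within <- set_similarity(idx, NULL, c1[1:10], c1[11:20])
  between <- set_similarity(idx, NULL, c1[1:10], c2[1:10])
  expect_gt(within, between)

  ext <- extend_collection(fx$network, fx$sets, extension_config())
  rep <- semsim_validation(fx$network, ext$results, idx$ontology,
                           fx$annotations, n_random = 30, seed = 8)
  expect_true(all(rep$per_set$empirical_p >= 0 &
                    rep$per_set$empirical_p <= 1))
  # added proteins are true community members, so the real similarity
  # should beat the random-candidate mean
  expect_true(all(rep$per_set$real_similarity >
                    rep$per_set$mean_random_similarity))
  # reproducibility
  rep2 <- semsim_validation(fx$network, ext$results, idx$ontology,
                            fx$annotations, n_random = 30, seed = 8)
  expect_identical(rep$per_set, rep2$per_set)
})
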