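test_that("ctax of a partition with itself is 1, and symmetric in general", {
  a <- part("A A B B C", "a")
  expect_equal(ctax_pair(a, a)$ctax, 1)
  b <- part("A A B B B", "b")
  ab <- ctax_pair(a, b); ba <- ctax_pair(b, a)
  expect_equal(ab$ctax, ba$ctax)
  expect_gte(ab$ctax, 0); expect_lte(ab$ctax, 1)
})

test_that("a hand-enumerated pair gives identical counts in both modes", {
  # A = {ab | cd}, B = {a | b | cd} on ((a,b),(c,d)):
  # events(A) = {root}, events(B) = {root, anc(a,b)} -> shared 1, union 2
  gt <- guide_tree(ape::read.tree(text = "((a,b),(c,d));"))
  A <- species_partition(c(a = "1", b = "1", c = "2", d = "2"), "A")
  B <- species_partition(c(a = "1", b = "2", c = "3", d = "3"), "B")
  for (pc in list(ctax_pair(A, B, mode = "free"),
                  ctax_pair(A, B, mode = "tree", tree = gt))) {
    expect_equal(pc$n_shared, 1L)
    expect_equal(pc$n_union, 2L)
    expect_equal(pc$ctax, 0.5)
  }
})

test_that("for a coarsening pair ctax is (k_coarse-1)/(k_fine-1) exactly", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(5:25, 1)
    gt <- generate_guide_tree(n, seed = 100 + i)
    ks <- sort(sample(2:n, 2))
    tc <- generate_nested_taxonomies(gt, ks, seed = i, chain = TRUE)
    pc <- ctax_pair(tc$partitions[[1]], tc$partitions[[2]])
    expect_equal(pc$ctax, (ks[1] - 1) / (ks[2] - 1))
  }
})

test_that("conservation n_shared + n_union = n_a + n_b holds on every pair", {
  set.seed(12)
  gt <- generate_guide_tree(15, seed = 3)
  for (i in 1:20) {
    tc <- generate_nested_taxonomies(gt, sample(2:15, 2), seed = i,
                                     chain = FALSE)
    pc <- ctax_pair(tc$partitions[[1]], tc$partitions[[2]])
    expect_equal(pc$n_shared + pc$n_union, pc$n_a + pc$n_b)
  }
})

test_that("incompatible pairs are refused in free mode, citing the witness", {
  a <- part("A A B B", "a")
  b <- part("A B A B", "b")
  expect_error(ctax_pair(a, b, mode = "free"), "incompatible")
  expect_error(ctax_pair(a, b, mode = "free"), "crosses")
  expect_error(ctax_pair(a, b, mode = "tree"), "guide tree")
})

test_that("two single-species taxonomies get ctax 1 with a warning", {
  a <- part("A A A", "a"); b <- part("B B B", "b")
  expect_warning(pc <- ctax_pair(a, b), "single species")
  expect_equal(pc$ctax, 1)
})

test_that("rtax is the per-method share of the union event set", {
  # two-method nesting: the refinement attains 1
  coarse <- part("A A B B B", "coarse")
  fine <- part("A A B B C", "fine")
  tc <- taxonomy_collection(list(coarse, fine))
  r <- rtax(tc)
  expect_equal(unname(r[["fine"]]), 1)
  expect_equal(unname(r[["coarse"]]), 1 / 2)
  # nested chain k = 2, 3, 5: rtax = (1/4, 2/4, 1)
  gt <- generate_guide_tree(8, seed = 2)
  tc3 <- generate_nested_taxonomies(gt, c(2, 3, 5), seed = 9, chain = TRUE)
  r3 <- rtax(tc3, mode = "free")
  expect_equal(as.numeric(r3), c(1, 2, 4) / 4)
  expect_equal(as.numeric(rtax(tc3, mode = "tree", tree = gt)),
               c(1, 2, 4) / 4)
})

test_that("mean_ctax averages the off-diagonal values involving a method", {
  m <- matrix(1, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  expect_equal(mean_ctax(m, "B"), 1)
  two <- taxonomy_collection(list(part("A A B B", "x"), part("A B C C", "y")))
  rep2 <- compare_taxonomies(two)
  expect_equal(mean_ctax(rep2, "x"), rep2$ctax["x", "y"])
  m[2, 3] <- NA
  expect_error(mean_ctax(m, "B"), "missing pairwise")
  expect_error(mean_ctax(m, "Z"), "unknown method")
})

test_that("1 - ctax is a Jaccard distance: triangle inequality on triples", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    gt <- generate_guide_tree(n, seed = 200 + i)
    tc <- generate_nested_taxonomies(gt, sample(2:n, 3, replace = TRUE),
                                     seed = i, chain = FALSE)
    p <- tc$partitions
    d <- function(x, y) 1 - ctax_pair(p[[x]], p[[y]])$ctax
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
  }
})

test_that("ctax equals 1 exactly when the event sets coincide", {
  gt <- generate_guide_tree(12, seed = 4)
  tc <- generate_nested_taxonomies(gt, c(4, 4, 7), seed = 5, chain = TRUE)
  p <- tc$partitions
  # same k on a chain: identical partitions, identical event sets
  expect_identical(canon(p[[1]]), canon(p[[2]]))
  expect_equal(ctax_pair(p[[1]], p[[2]])$ctax, 1)
  # different event sets: strictly below 1
  pc <- ctax_pair(p[[1]], p[[3]])
  expect_lt(pc$ctax, 1)
  e1 <- extract_event_nodes(p[[1]], gt); e3 <- extract_event_nodes(p[[3]], gt)
  expect_false(setequal(e1, e3))
})

test_that("compare_taxonomies returns a symmetric unit-diagonal report", {
  gt <- generate_guide_tree(10, seed = 6)
  tc <- generate_nested_taxonomies(gt, c(3, 5, 8), seed = 7, chain = FALSE)
  rep <- compare_taxonomies(tc, mode = "tree", tree = gt)
  expect_identical(rep$ctax, t(rep$ctax))
  expect_equal(unname(diag(rep$ctax)), rep(1, 3))
  expect_true(all(rep$rtax > 0 & rep$rtax <= 1))
  # csv/json serialization round-trips the headline numbers
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_report(rep, csv); write_report(rep, js, format = "json")
  got <- utils::read.csv(csv)
  expect_equal(got$Nb_species, unname(rep$n_species))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$n_total_events, rep$n_total_events)
  expect_equal(unname(unlist(parsed$rtax)), unname(rep$rtax))
})

test_that("rand index matches pair enumeration and mclust's ARI", {
  a <- part("A A B B", "a")
  expect_equal(rand_index(a, a), 1)
  b <- part("A B A B", "b")
  expect_equal(rand_index(a, b), 2 / 6)   # 6 pairs, only 2 classified alike
  set.seed(14)
  for (i in 1:10) {
    ids <- paste0("u", 1:12)
    x <- random_partition(ids, 4, "x"); y <- random_partition(ids, 3, "y")
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x$assignment[ids],
                                           y$assignment[ids]))
  }
})

test_that("duplicating a cluster's specimens moves rand but not ctax", {
  a <- part("A A B B", "a")
  b <- part("A B C C", "b")
  base_rand <- rand_index(a, b)
  base_ctax <- ctax_pair(a, b)$ctax
  # replicate the specimens of cluster {s3, s4} five-fold in both methods
  tc <- taxonomy_collection(list(a, b))
  infl <- inflate_specimens(tc, per_specimen = c(s3 = 5, s4 = 5))
  a2 <- infl$partitions[[1]]; b2 <- infl$partitions[[2]]
  expect_false(isTRUE(all.equal(rand_index(a2, b2), base_rand)))
  expect_equal(ctax_pair(a2, b2)$ctax, base_ctax)
})
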