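test_that("mutation scores match hand-computed values on small matrices", {
  one <- new_mutation_matrix(matrix(1L, 1, 1, dimnames = list("g", "p")))
  sc1 <- mutation_scores(one)
  expect_equal(sc1$score, 1.0)
  expect_equal(attr(sc1, "bms"), 1.0)

  # columns p1..p3 carry 2, 2, 0 mutated genes; weights 1/2 each
  sc <- mutation_scores(tiny_mutation_matrix())
  expect_equal(stats::setNames(sc$score, sc$gene),
               c(g1 = 1.0, g2 = 0.5, g3 = 0.5))
  expect_equal(attr(sc, "bms"), 0.5)
})

test_that("never-mutated genes receive the background score", {
  # column sums are (1, 2): N_max = 2, so z gets BMS = 1/2
  m <- new_mutation_matrix(matrix(
    c(1L, 1L,
      0L, 1L,
      0L, 0L), 3, byrow = TRUE,
    dimnames = list(c("a", "b", "z"), c("p1", "p2"))))
  sc <- mutation_scores(m)
  expect_true(sc$is_bms[sc$gene == "z"])
  expect_equal(sc$score[sc$gene == "z"], 1 / 2)
})

test_that("all-zero matrices are rejected (background score undefined)", {
  m <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("p1", "p2")))
  class(m) <- c("mutation_matrix", class(m))
  expect_error(mutation_scores(m), "all-zero")
})

test_that("every score is at least the background score on random matrices", {
  set.seed(42)
  for (rep in 1:200) {
    m <- random_mutation_matrix(sample(2:12, 1), sample(2:10, 1), p = runif(1, 0.05, 0.6))
    sc <- mutation_scores(m)
    expect_true(all(sc$score >= attr(sc, "bms") - 1e-12))
  }
})

test_that("an added mutation never decreases the score of an already-mutated gene", {
  # the sum in the score gains one strictly positive term; existing terms are
  # untouched because the flip sits in a different patient column
  set.seed(43)
  for (rep in 1:50) {
    m <- random_mutation_matrix(6, 8, p = 0.3)
    zeros <- which(unclass(m) == 0L & rowSums(m)[row(unclass(m))] > 0,
                   arr.ind = TRUE)
    if (nrow(zeros) == 0) next
    pick <- zeros[sample.int(nrow(zeros), 1), ]
    m2 <- unclass(m); m2[pick[1], pick[2]] <- 1L
    m2 <- new_mutation_matrix(m2)
    g <- rownames(m)[pick[1]]
    s1 <- mutation_scores(m); s2 <- mutation_scores(m2)
    expect_gte(s2$score[s2$gene == g], s1$score[s1$gene == g])
  }
})

test_that("gene_distance is Euclidean and equals sqrt(Hamming) on binary rows", {
  expect_equal(gene_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(gene_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(gene_distance(c(1, 0), c(1, 0, 1)), "length")
  set.seed(44)
  for (rep in 1:50) {
    n <- sample(3:20, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    expect_equal(gene_distance(x, y), sqrt(sum(x != y)))
  }
})

test_that("MIF matches direct substitution and is symmetric in both modes", {
  # d = 1 fixed point: both modes give M(i) * M(j)
  m <- new_mutation_matrix(matrix(c(1L, 1L, 1L, 0L), 2, byrow = TRUE,
                                  dimnames = list(c("i", "j"), c("p1", "p2"))))
  sc <- mutation_scores(m)
  mi <- sc$score[sc$gene == "i"]; mj <- sc$score[sc$gene == "j"]
  expect_equal(compute_mif(sc, m, "i", "j", "gravity"), mi * mj)
  expect_equal(compute_mif(sc, m, "i", "j", "literal"), mi * mj)

  # filler rows tune the column sums so M(i)=1, M(j)=0.5 while d(i,j)=2:
  # gravity 1*0.5/4 = 0.125, literal 1*0.5*4 = 2
  m2 <- new_mutation_matrix(matrix(
    c(1L, 1L, 0L, 0L,
      0L, 0L, 1L, 1L,
      0L, 0L, 1L, 1L,
      0L, 0L, 1L, 1L,
      0L, 0L, 1L, 1L,
      1L, 1L, 0L, 0L), 6, byrow = TRUE,
    dimnames = list(c("i", "j", "f1", "f2", "f3", "f4"), paste0("p", 1:4))))
  sc2 <- mutation_scores(m2)
  expect_equal(sc2$score[sc2$gene == "i"], 1)
  expect_equal(sc2$score[sc2$gene == "j"], 0.5)
  expect_equal(compute_mif(sc2, m2, "i", "j", "gravity"), 0.125)
  expect_equal(compute_mif(sc2, m2, "i", "j", "literal"), 2)

  set.seed(45)
  for (rep in 1:20) {
    mm <- random_mutation_matrix(5, 6)
    scm <- mutation_scores(mm)
    pair <- sample(rownames(mm), 2)
    for (mode in c("gravity", "literal")) {
      expect_equal(compute_mif(scm, mm, pair[1], pair[2], mode),
                   compute_mif(scm, mm, pair[2], pair[1], mode))
      expect_gt(compute_mif(scm, mm, pair[1], pair[2], mode), 0)
    }
  }
  expect_error(compute_mif(sc2, m2, "i", "i"), "distinct")
})

test_that("gravity MIF decreases as profile dissimilarity grows, literal increases", {
  # hold scores fixed, vary only the Hamming distance between two rows
  n <- 10
  mk <- function(k) {
    new_mutation_matrix(matrix(
      c(rep(1L, n),
        c(rep(0L, k), rep(1L, n - k))), 2, byrow = TRUE,
      dimnames = list(c("a", "b"), paste0("p", 1:n))))
  }
  sc <- mutation_scores(mk(3))  # scores for fixed reference
  grav <- vapply(1:5, function(k) compute_mif(sc, mk(k), "a", "b", "gravity"),
                 numeric(1))
  lit <- vapply(1:5, function(k) compute_mif(sc, mk(k), "a", "b", "literal"),
                numeric(1))
  expect_true(all(diff(grav) < 0))
  expect_true(all(diff(lit) > 0))
})
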