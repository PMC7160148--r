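ped_df <- function(...) as_pedigree(data.frame(...))

test_that("A matrix reproduces textbook values", {
  # two unrelated founders
  p2 <- ped_df(animal = c("a", "b"), sire = "0", dam = "0")
  expect_equal(unclass(build_A(p2)), diag(2), ignore_attr = TRUE)
  # parent-offspring with unrelated parents
  p3 <- ped_df(animal = c("s", "d", "o"), sire = c("0", "0", "s"),
               dam = c("0", "0", "d"))
  A <- build_A(p3)
  expect_equal(A["s", "o"], 0.5)
  expect_equal(diag(unclass(A)), c(s = 1, d = 1, o = 1))
  # full-sib mating: offspring diagonal 1.25 (tabular method by hand)
  p5 <- ped_df(animal = c("s", "d", "x", "y", "z"),
               sire = c("0", "0", "s", "s", "x"),
               dam = c("0", "0", "d", "d", "y"))
  A5 <- build_A(p5)
  expect_equal(A5["x", "y"], 0.5)
  expect_equal(A5["z", "z"], 1.25)
})

test_that("A is PSD on random pedigrees and requires topological order", {
  for (s in 1:5) {
    cfg <- sim_config(n_founders = 20, n_generations = 4, n_cg = 4, seed = s)
    A <- build_A(simulate_pedigree(cfg))
    ev <- eigen(unclass(A), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_true(all(diag(unclass(A)) >= 1))
  }
  bad <- data.frame(animal = c("o", "s", "d"), sire = c("s", "0", "0"),
                    dam = c("d", "0", "0"))
  class(bad) <- c("pedigree", "data.frame")  # bypass sorting on purpose
  expect_error(build_A(bad), "topologically")
})

test_that("G matches a hand-computed VanRaden matrix", {
  calls <- matrix(c(0L, 2L, 1L, 2L, 0L, 1L), 3, 2,
                  dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  g <- genotype_matrix(calls, chrom = c(1, 1), pos = c(1, 2))
  expect_equal(unname(g$p), c(0.5, 0.5))
  G <- build_G(g)
  # Mc rows: a (-1,1), b (1,-1), c (0,0); k = 2*(0.25+0.25) = 1
  Gh <- rbind(c(2, -2, 0), c(-2, 2, 0), c(0, 0, 0))
  expect_equal(unclass(G), Gh, ignore_attr = TRUE)
})

test_that("G centering and duplication behave as linear algebra dictates", {
  set.seed(31)
  calls <- sapply(runif(30, .2, .5), function(p) rbinom(12, 2, p))
  rownames(calls) <- sprintf("A%02d", 1:12)
  g <- genotype_matrix(calls, chrom = rep(1, 30), pos = 1:30)
  # an animal sitting exactly at 2p on every SNP has a zero G row
  M <- rbind(calls, X = as.integer(round(2 * g$p)))
  # use frequencies that make the last row exactly 2p
  pfix <- M["X", ] / 2
  gg <- genotype_matrix(M, chrom = rep(1, 30), pos = 1:30)
  G <- build_G(gg, p = pfix)
  expect_equal(max(abs(G["X", ])), 0)
  # duplicated animal rows give identical G rows/diagonals
  M2 <- rbind(calls, dup = calls[1, ])
  g2 <- genotype_matrix(M2, chrom = rep(1, 30), pos = 1:30)
  G2 <- build_G(g2)
  expect_equal(unname(G2["dup", ]), unname(G2["A01", ]))
  expect_equal(G2["dup", "dup"], G2["A01", "A01"])
  # all-monomorphic matrix is rejected
  mono <- genotype_matrix(matrix(2L, 4, 3), chrom = rep(1, 3), pos = 1:3)
  expect_error(build_G(mono), "monomorphic")
})

test_that("mean diag(G) is near 1 for Hardy-Weinberg genotypes", {
  set.seed(33)
  p <- runif(400, 0.1, 0.5)
  calls <- sapply(p, function(pp) rbinom(200, 2, pp))
  rownames(calls) <- sprintf("A%03d", 1:200)
  g <- genotype_matrix(calls, chrom = rep(1, 400), pos = 1:400)
  G <- build_G(g)
  expect_equal(mean(diag(unclass(G))), 1, tolerance = 0.05)
})

test_that("H inverse reduces to A inverse in the degenerate cases", {
  b <- small_bundle()
  Hinv0 <- build_H_inverse(b$Ainv, G = NULL)
  expect_equal(unclass(Hinv0), unclass(b$Ainv), ignore_attr = TRUE)
  # G_blended constructed equal to A22: correction cancels
  A22_as_G <- ssgrn:::relmat(unclass(b$A22), rownames(b$A22), "G")
  Hinv1 <- build_H_inverse(b$Ainv, b$A22, A22_as_G, blend_weight = 1)
  expect_lt(max(abs(unclass(Hinv1) - unclass(b$Ainv))), 1e-8)
})

test_that("H inverse matches the dense-inverse oracle on a small pedigree", {
  p6 <- ped_df(animal = c("a", "b", "c", "d", "e", "f"),
               sire = c("0", "0", "a", "a", "c", "c"),
               dam = c("0", "0", "b", "b", "d", "d"))
  set.seed(35)
  calls <- sapply(runif(40, .2, .5), function(p) rbinom(3, 2, p))
  rownames(calls) <- c("d", "e", "f")
  g <- genotype_matrix(calls, chrom = rep(1, 40), pos = 1:40)
  A <- build_A(p6)
  A22 <- ssgrn:::relmat(unclass(A)[c("d", "e", "f"), c("d", "e", "f")],
                        c("d", "e", "f"), "A22")
  G <- build_G(g)
  Hinv <- build_H_inverse(invert_relmat(A), A22, G, blend_weight = 0.9)
  H <- build_H(A, A22, G, blend_weight = 0.9)
  expect_lt(max(abs(unclass(Hinv) - solve(unclass(H)))), 1e-8)
})
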