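dm3 <- function(ab, ac, bc, labels = c("A", "B", "C")) {
  v <- matrix(c(0, ab, ac, ab, 0, bc, ac, bc, 0), 3, 3,
              dimnames = list(labels, labels))
  distance_matrix(v)
}

test_that("euclidean distances match the elementwise definition", {
  x <- rbind(p = c(0, 0), q = c(3, 4))
  d <- euclidean_distances(x)
  expect_equal(d$values["p", "q"], 5)
  expect_equal(euclidean_distances(rbind(a = 1:3, b = 1:3))$values["a", "b"],
               0)
  set.seed(8)
  y <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("t", 1:5), NULL))
  d2 <- euclidean_distances(y)$values
  for (i in 1:5) for (j in 1:5)
    expect_equal(d2[i, j], sqrt(sum((y[i, ] - y[j, ])^2)))
  y[1, 1] <- NA
  expect_error(euclidean_distances(y), "non-finite")
})

test_that("distance matrix validation catches malformed input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(distance_matrix(bad), "symmetric")
  expect_error(distance_matrix(matrix(0, 2, 3)), "square")
})

test_that("UPGMA agglomerates by mean linkage with halved heights", {
  tr <- upgma(dm3(2, 8, 8))
  C <- cophenetic_matrix(tr)$values
  expect_equal(C["A", "B"], 2)
  expect_equal(C["A", "C"], 8)
  expect_equal(C["B", "C"], 8)
  # leaf-to-leaf patristic distance on the exported tree equals cophenetic
  P <- ape::cophenetic.phylo(tr$phy)
  expect_equal(P[rownames(C), colnames(C)], C)
  # mean linkage on a 4-taxon case, agglomeration worked by hand:
  # AB merge at 2; then d({AB},C) = (6 + 8)/2 = 7 < d to D
  v <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  v["A", "B"] <- v["B", "A"] <- 2
  v["A", "C"] <- v["C", "A"] <- 6
  v["B", "C"] <- v["C", "B"] <- 8
  v["A", "D"] <- v["D", "A"] <- 10
  v["B", "D"] <- v["D", "B"] <- 10
  v["C", "D"] <- v["D", "C"] <- 10
  C4 <- cophenetic_matrix(upgma(distance_matrix(v)))$values
  expect_equal(C4["A", "B"], 2)
  expect_equal(C4["A", "C"], 7)
  expect_equal(C4["B", "C"], 7)
  expect_equal(C4["A", "D"], 10)
})

test_that("UPGMA reproduces ultrametric input exactly", {
  # cophenetic matrix of ((A,B),(C,D)) with heights 1 and 3
  v <- matrix(6, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  v["A", "B"] <- v["B", "A"] <- 2
  v["C", "D"] <- v["D", "C"] <- 2
  diag(v) <- 0
  dm <- distance_matrix(v)
  expect_equal(cophenetic_matrix(upgma(dm))$values, dm$values)
  # fixed point: upgma(cophenetic(T)) has the same cophenetic matrix
  set.seed(12)
  x <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("t", 1:6), NULL))
  t1 <- upgma(euclidean_distances(x))
  c1 <- cophenetic_matrix(t1)
  expect_equal(cophenetic_matrix(upgma(c1))$values, c1$values)
})

test_that("tied distances collapse to the same cophenetic structure", {
  v <- matrix(3, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(v) <- 0
  C <- cophenetic_matrix(upgma(distance_matrix(v)))$values
  expect_equal(unname(C[upper.tri(C)]), rep(3, 6))
})

test_that("UPGMA cophenetic matrices are ultrametric", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(paste0("t", seq_len(n)), NULL))
    C <- cophenetic_matrix(upgma(euclidean_distances(x)))$values
    expect_ultrametric(C)
  }
})

test_that("CPCC is a label-aligned Pearson correlation on triangles", {
  set.seed(4)
  x <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("t", 1:5), NULL))
  D <- euclidean_distances(x)
  expect_equal(cpcc(D, D), 1)
  # affine invariance with positive slope
  D2 <- distance_matrix(2.5 * D$values + 3 * (1 - diag(5)))
  expect_equal(cpcc(D, D2), 1)
  # symmetric and invariant to taxon order
  y <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("t", 1:5), NULL))
  Dy <- euclidean_distances(y)
  expect_equal(cpcc(D, Dy), cpcc(Dy, D))
  perm <- sample(1:5)
  Dp <- distance_matrix(Dy$values[perm, perm])
  expect_equal(cpcc(D, Dp), cpcc(D, Dy))
  expect_error(cpcc(D, distance_matrix(
    matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL)))), "different taxa")
  Dc <- distance_matrix(1 - diag(5) +
    matrix(0, 5, 5, dimnames = list(paste0("t", 1:5), NULL)))
  expect_error(cpcc(Dc, Dc), "zero variance")
})

test_that("reference files round-trip: PHYLIP matrices and Newick trees", {
  set.seed(21)
  x <- matrix(rnorm(4 * 3), 4, 3,
              dimnames = list(c("sp_a", "sp_b", "sp_c", "sp_d"), NULL))
  D <- euclidean_distances(x)
  p <- tempfile()
  write_distance_phylip(D, p)
  D2 <- read_reference(p)
  expect_s3_class(D2, "distance_matrix")
  expect_equal(D2$values[D$taxa, D$taxa], D$values, tolerance = 1e-8)
  # label mapping
  map <- c(sp_a = "A", sp_b = "B", sp_c = "C", sp_d = "D")
  D3 <- read_reference(p, label_map = map)
  expect_setequal(D3$taxa, c("A", "B", "C", "D"))
  expect_error(read_reference(p, label_map = map[-1]), "missing from mapping")
  # Newick with branch lengths gives patristic distances
  tn <- tempfile()
  writeLines("((A:1,B:1):2,C:3);", tn)
  phy <- read_reference(tn)
  expect_s3_class(phy, "phylo")
  expect_equal(cophenetic_matrix(phy)$values["A", "B"], 2)
  # dendrogram Newick round-trip preserves the cophenetic matrix
  tr <- upgma(D)
  nw <- tempfile()
  write_newick(tr, nw)
  back <- read_reference(nw)
  expect_equal(cophenetic_matrix(back)$values[D$taxa, D$taxa],
               cophenetic_matrix(tr)$values[D$taxa, D$taxa],
               tolerance = 1e-6)
})

test_that("clade sets and rooted clade difference", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cl <- clade_sets(phy)
  expect_setequal(names(cl), c("A|B|C|D", "A|B", "C|D"))
  expect_equal(clade_difference(phy, phy), 0L)
  phy2 <- ape::read.tree(text = "(((A:1,C:1):1,B:2):1,D:3);")
  expect_equal(clade_difference(phy, phy2), 4L)
})
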