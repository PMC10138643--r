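test_that("Poisson pairwise-deletion distances follow the closed form", {
  expect_equal(poissonDist(c(a = "ACDG", b = "ACDG"))["a", "b"], 0)
  ## p = 0.5 -> -ln(0.5)
  expect_equal(poissonDist(c(a = "AACC", b = "AAGG"))["a", "b"], -log(0.5))
  ## gapped pair: 3 shared columns, 1 difference
  expect_equal(poissonDist(c(a = "AC-G", b = "AT-G"))["a", "b"], -log(2 / 3))
  ## X is treated as missing, like a gap
  expect_equal(poissonDist(c(a = "ACXG", b = "ATAG"))["a", "b"], -log(2 / 3))
  ## symmetry and zero diagonal on random alignments
  set.seed(71)
  for (k in 1:5) {
    msa <- setNames(vapply(1:4, function(i) randomSeq(30, c("A", "C", "G", "-")),
                           character(1)), paste0("s", 1:4))
    d <- suppressWarnings(poissonDist(msa))
    expect_equal(d, t(d))
    expect_equal(diag(d), setNames(rep(0, 4), paste0("s", 1:4)))
  }
})

test_that("saturated and disjoint pairs are flagged", {
  expect_warning(d <- poissonDist(c(a = "AAAA", b = "CCCC")), "saturated")
  expect_true(is.infinite(d["a", "b"]))
  expect_error(poissonDist(c(a = "AA--", b = "--CC")), "no shared")
  expect_error(njTree(matrix(c(0, Inf, 1, Inf, 0, 1, 1, 1, 0), 3,
                             dimnames = list(letters[1:3], letters[1:3]))),
               "non-finite")
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers additive trees exactly, matching exhaustive search", {
  set.seed(72)
  for (n in c(4, 5, 6, 8)) {
    tr0 <- ape::rtree(n)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.5, 2)
    tr0 <- ape::unroot(tr0)
    dm <- ape::cophenetic.phylo(tr0)
    dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
    tr <- njTree(dm)
    expect_equal(ape::dist.topo(tr, tr0), 0, ignore_attr = TRUE)
    ## patristic distances reproduce the input matrix
    got <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
    expect_equal(got, dm, tolerance = 1e-8)
    if (n == 5) {
      ## exhaustive check: among all 15 unrooted topologies, the zero
      ## least-squares residual one is the NJ topology
      all5 <- phangorn::allTrees(5, rooted = FALSE,
                                 tip.label = rownames(dm))
      resid <- vapply(all5, function(t) {
        f <- phangorn::nnls.tree(dm, t, method = "unrooted")
        sum((ape::cophenetic.phylo(f)[rownames(dm), colnames(dm)] - dm)^2)
      }, numeric(1))
      best <- all5[[which.min(resid)]]
      expect_equal(min(resid), 0, tolerance = 1e-10)
      expect_equal(ape::dist.topo(best, tr), 0, ignore_attr = TRUE)
    }
  }
})

test_that("negative NJ branch estimates are clamped to zero", {
  d <- matrix(c(0, 0.604, 0.807, 1.188,
                0.604, 0, 1.826, 0.483,
                0.807, 1.826, 0, 1.807,
                1.188, 0.483, 1.807, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_message(tr <- njTree(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is seed-stable and splits planted clades", {
  cl <- simulateCladeMsa(2, 4, 0.05, 0.6, 120, seed = 2)
  t1 <- bootstrapTree(cl$msa, 100, seed = 3)
  t2 <- bootstrapTree(cl$msa, 100, seed = 3)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- bipartitionSupport(t1, cl$truth$id[cl$truth$clade == "clade1"])
  expect_gte(sup, 95)
  ## single replicate: support values are 0 or 100
  t3 <- bootstrapTree(cl$msa, 1, seed = 4)
  vals <- as.numeric(t3$node.label[nzchar(t3$node.label)])
  expect_true(all(vals %in% c(0, 100)))
})

test_that("an alignment of identical sequences is reported unresolved", {
  msa <- setNames(rep("ACDGACDG", 4), paste0("s", 1:4))
  expect_warning(tr <- bootstrapTree(msa, 5, seed = 1), "unresolved")
  expect_true(all(tr$edge.length == 0))
})

test_that("newick output round-trips the topology", {
  cl <- simulateCladeMsa(2, 3, 0.05, 0.5, 80, seed = 9)
  tr <- njTree(suppressWarnings(poissonDist(cl$msa)))
  txt <- writeNewickTree(tr)
  back <- ape::read.tree(text = txt)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
  expect_error(writeNewickTree(list()), "phylo")
})

test_that("logo information content follows the entropy closed forms", {
  lm <- logoMatrix(c(a = "GA", b = "GG"))
  expect_equal(lm$information[1], log2(20))
  expect_equal(lm$information[2], log2(20) - 1)
  expect_equal(colSums(lm$frequencies), c(1, 1), ignore_attr = TRUE)
  ## uniform over 20 residues -> zero information
  msa20 <- setNames(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    paste0("s", 1:20))
  lm20 <- logoMatrix(msa20)
  expect_equal(lm20$information[1], 0)
  ## making a column more uniform lowers its information
  skew <- logoMatrix(setNames(c("G", "G", "G", "A"), paste0("s", 1:4)))
  even <- logoMatrix(setNames(c("G", "G", "A", "A"), paste0("s", 1:4)))
  expect_gt(skew$information[1], even$information[1])
  ## all-gap columns are missing
  lmg <- logoMatrix(c(a = "-A", b = "-G"))
  expect_true(is.na(lmg$information[1]))
})

test_that("consensus-region extraction yields a columnwise-comparable block", {
  mo <- defaultMotifs()
  set.seed(73)
  seqs <- setNames(vapply(1:4, function(i)
    paste0(randomSeq(sample(5:25, 1), LETTERS[c(1, 3:8)]),
           fillConsensus(RR1_TEXT, "A"),
           randomSeq(sample(5:25, 1), LETTERS[c(1, 3:8)])), character(1)),
    paste0("p", 1:4))
  reg <- consensusRegion(seqs, mo$rr1, flank = 10)
  expect_length(unique(nchar(reg)), 1)
  expect_equal(nchar(reg[[1]]), nchar(RR1_TEXT) + 20)
  ## the consensus core occupies the same columns in every row
  core <- substr(reg, 11, 10 + nchar(RR1_TEXT))
  expect_true(all(vapply(core, function(s)
    nrow(scanMotif(s, mo$rr1)) == 1, logical(1))))
})
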