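test_that("identity basics: identical sequences, MKV/MAV, symmetry", {
  expect_equal(globalIdentity("MKVILW", "MKVILW")$identity, 1)
  expect_equal(globalIdentity("MKV", "MAV")$identity, 2 / 3)
  set.seed(61)
  for (k in 1:25) {
    a <- randomSeq(sample(3:10, 1)); b <- randomSeq(sample(3:10, 1))
    expect_equal(globalIdentity(a, b)$identity, globalIdentity(b, a)$identity)
    expect_gte(globalIdentity(a, b)$identity, 0)
    expect_lte(globalIdentity(a, b)$identity, 1)
  }
})

test_that("alignment scores match an exhaustive three-state DP oracle", {
  set.seed(62)
  for (k in 1:40) {
    a <- randomSeq(sample(2:8, 1)); b <- randomSeq(sample(2:8, 1))
    got <- globalIdentity(a, b)$score
    want <- bruteAffineScore(a, b, blosum62, 10, 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("alignment scores agree with an established aligner", {
  set.seed(63)
  for (k in 1:15) {
    a <- randomSeq(sample(5:25, 1), LETTERS[c(1, 3:9, 11:14)])
    b <- randomSeq(sample(5:25, 1), LETTERS[c(1, 3:9, 11:14)])
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1))
    expect_equal(globalIdentity(a, b)$score, ref, info = paste(a, b))
  }
})

test_that("terminal gaps are excluded from the identity denominator", {
  ## identical core with a long unmatched tail: identity stays 1
  g <- globalIdentity("MKVILWAA", "MKVILWAAGGGGGGGG")
  expect_equal(g$identity, 1)
  expect_equal(g$columns, 8)
})

test_that("reciprocal best hits recover planted 1:1 ortholog pairs", {
  set.seed(64)
  base <- vapply(1:3, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                 replace = TRUE), collapse = ""), character(1))
  refs <- setNames(base, c("r1", "r2", "r3"))
  qs <- setNames(vapply(base, function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(60, 4)
    ch[i] <- sample(c("A", "G"), 4, TRUE)
    paste(ch, collapse = "")
  }, character(1)), c("q1", "q2", "q3"))
  rbh <- reciprocalBestHits(qs, refs, minIdentity = 0.5)
  one <- rbh[rbh$relation == "1:1", ]
  expect_equal(nrow(one), 3)
  expect_identical(one$reference[match(c("q1", "q2", "q3"), one$query)],
                   c("r1", "r2", "r3"))
  ## a floor above every identity empties the map
  expect_equal(nrow(reciprocalBestHits(qs, refs, minIdentity = 0.999)), 0)
})

test_that("an expanded family collapses into one co-ortholog group", {
  set.seed(65)
  anc <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 80,
                      replace = TRUE), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k, TRUE)
    paste(ch, collapse = "")
  }
  qs <- setNames(vapply(1:6, function(i) mut(anc, 12), character(1)),
                 paste0("q", 1:6))
  refs <- setNames(vapply(1:4, function(i) mut(anc, 12), character(1)),
                   paste0("r", 1:4))
  rbh <- reciprocalBestHits(qs, refs, minIdentity = 0.3)
  ## every query and reference appears somewhere
  expect_setequal(unique(rbh$query), names(qs))
  expect_setequal(unique(rbh$reference), names(refs))
  ## grouping must match an independent union-find over best-hit edges
  idm <- identityMatrix(qs, refs)
  edges <- NULL
  for (q in rownames(idm)) for (r in colnames(idm)[idm[q, ] == max(idm[q, ])])
    edges <- rbind(edges, c(q, r))
  for (r in colnames(idm)) for (q in rownames(idm)[idm[, r] == max(idm[, r])])
    edges <- rbind(edges, c(q, r))
  parent <- setNames(c(names(qs), names(refs)), c(names(qs), names(refs)))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges)))
    parent[[find(edges[i, 1])]] <- find(edges[i, 2])
  comp <- vapply(names(qs), find, character(1))
  grp <- rbh$relation[match(names(qs), rbh$query)]
  ## queries in the same union-find component share a relation label,
  ## provided neither is a 1:1 pair
  co <- !grepl("1:1", grp)
  if (sum(co) > 1) {
    split1 <- split(grp[co], comp[co])
    for (g in split1) expect_length(unique(g), 1)
  }
})

test_that("RBH output is invariant under input permutation and identity floor", {
  set.seed(66)
  qs <- setNames(vapply(1:4, function(i) randomSeq(40, LETTERS[c(1, 3:8)]),
                        character(1)), paste0("q", 1:4))
  refs <- setNames(vapply(1:4, function(i) randomSeq(40, LETTERS[c(1, 3:8)]),
                          character(1)), paste0("r", 1:4))
  a <- reciprocalBestHits(qs, refs, minIdentity = 0.2)
  b <- reciprocalBestHits(qs[c(3, 1, 4, 2)], refs[c(2, 4, 1, 3)],
                          minIdentity = 0.2)
  expect_identical(a, b)
  ## raising the floor never adds a pair
  lo <- reciprocalBestHits(qs, refs, minIdentity = 0.2)
  hi <- reciprocalBestHits(qs, refs, minIdentity = 0.45)
  expect_true(all(paste(hi$query, hi$reference) %in%
                    paste(lo$query, lo$reference)))
})
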