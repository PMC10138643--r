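test_that("pattern notation parses to the expected widths and matches", {
  m <- parseMotif("C-X5-C", "spacing")
  expect_equal(unname(motifWidth(m)), c(7, 7))
  m2 <- parseMotif("KX(4-5)FIKAP", "consensus")
  expect_equal(unname(motifWidth(m2)), c(10, 11))
  m3 <- parseMotif("K[YF]", "consensus")
  expect_equal(nrow(scanMotif("KY", m3)), 1)
  expect_equal(nrow(scanMotif("KF", m3)), 1)
  expect_equal(nrow(scanMotif("KA", m3)), 0)
  ## underscore and slash notation
  m4 <- parseMotif("Cx_14-16_C", "spacing")
  expect_equal(unname(motifWidth(m4)), c(16, 18))
  m5 <- parseMotif("FV/IK", "consensus")
  expect_equal(nrow(scanMotif("FVK", m5)), 1)
  expect_equal(nrow(scanMotif("FIK", m5)), 1)
  expect_equal(nrow(scanMotif("FLK", m5)), 0)
})

test_that("parser rejects malformed patterns and round-trips text", {
  expect_error(parseMotif("Cx(6-2)C", "spacing"), "malformed")
  expect_error(parseMotif("C?C", "spacing"), "unknown character")
  expect_error(parseMotif("C[", "spacing"), "unterminated")
  for (txt in c("Cx(14-16)Cx(5)C", "GxFxY", "AAP[AVL]", "KPEVYxFV/IKY")) {
    m <- parseMotif(txt, "consensus")
    m2 <- parseMotif(motifText(m), "consensus")
    expect_identical(m@elements, m2@elements)
  }
})

test_that("scan reports all and only the matching windows (brute force)", {
  mo <- defaultMotifs()
  set.seed(11)
  cases <- list(
    list(seq = "AACGGGGGCAA", motif = parseMotif("Cx(5)C", "repeat")),
    list(seq = "CAAAAACAAAAAC", motif = mo$cpcfc),
    list(seq = randomSeq(50, c("C", "A", "G")), motif = mo$cpcfc),
    list(seq = randomSeq(40, c("K", "F", "Y", "A")), motif = mo$tweedle1),
    list(seq = paste0("AAA", fillConsensus("Kx(4-5)FIKAP", "A"), "AA"),
         motif = mo$tweedle2))
  for (cs in cases) {
    got <- scanMotif(cs$seq, cs$motif)
    want <- bruteWindows(cs$seq, cs$motif)
    expect_equal(got[, c("start", "end")], want, ignore_attr = TRUE)
    ## every reported window re-tests positively
    if (nrow(got))
      expect_true(all(grepl(motifRegex(cs$motif), got$matched)))
  }
})

test_that("spec scan examples hold", {
  expect_equal(scanMotif("AACGGGGGCAA", parseMotif("Cx(5)C", "repeat"))$start, 3)
  rr1 <- defaultMotifs()$rr1
  hit <- scanMotif(fillConsensus(RR1_TEXT, "A"), rr1)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, nchar(RR1_TEXT))
  two <- scanMotif("CAAAAACAAAAAC", defaultMotifs()$cpcfc)
  expect_equal(two$start, c(1, 7))
})

test_that("X in the protein never satisfies a fixed or alternative position", {
  m <- parseMotif("K[YF]", "consensus")
  expect_equal(nrow(scanMotif("KX", m)), 0)
  expect_equal(nrow(scanMotif("XY", m)), 0)
  ## but X is fine at wildcard positions
  m2 <- parseMotif("KxF", "consensus")
  expect_equal(nrow(scanMotif("KXF", m2)), 1)
})

test_that("mismatch budget applies to informative positions only", {
  m <- parseMotif("Cx(5)C", "repeat")
  expect_equal(nrow(scanMotif("CAAAAAG", m)), 0)
  h <- scanMotif("CAAAAAG", m, maxMismatches = 1)
  expect_equal(h$mismatches, 1)
  ## substitutions inside the gap never count
  expect_equal(scanMotif("CWWWWWC", m)$mismatches, 0)
})

test_that("greedy repeat counting matches the field conventions", {
  mo <- defaultMotifs()
  expect_equal(countNonoverlapping("AAPAAAPVAAPL", mo$cph), 3)
  expect_equal(countNonoverlapping("A", mo$cph), 0)
  ## tandem C-X5-C units share their boundary cysteine
  expect_equal(countNonoverlapping("CAAAAACAAAAAC", mo$cpcfc), 2)
  ## count never exceeds the number of scan hits + is suffix-stable
  set.seed(21)
  for (k in 1:20) {
    s <- randomSeq(40, c("A", "P", "V", "L"))
    n1 <- countNonoverlapping(s, mo$cph)
    expect_lte(n1, max(1, nrow(scanMotif(s, mo$cph))))
    expect_equal(countNonoverlapping(paste0(s, "WWWWW"), mo$cph), n1)
  }
})

test_that("dipeptide counting allows overlaps", {
  expect_equal(countDipeptide("PVPVPY", "PV"), 2)
  expect_equal(countDipeptide("PPP", "PP"), 2)
  expect_equal(countDipeptide("MKV", "PY"), 0)
})

test_that("composition excludes X and errors on all-X input", {
  expect_equal(residueComposition("GGGG"), c(G = 1))
  expect_equal(residueComposition("GAGA"), c(A = 0.5, G = 0.5))
  expect_equal(residueComposition("GGXA"), c(A = 1 / 3, G = 2 / 3))
  expect_error(residueComposition("XXX"), "no informative")
  set.seed(3)
  for (k in 1:10)
    expect_equal(sum(residueComposition(randomSeq(30, c("A", "G", "X")))), 1)
})

test_that("consensus scoring matches a sliding-window brute force", {
  mo <- defaultMotifs()
  ## verbatim consensus scores 1 at its planted location
  self2 <- fillConsensus(RR2_TEXT, "G")
  expect_equal(consensusScore(self2, mo$rr2)$score, 1)
  ## all-A protein: fraction of fixed letters equal to A
  fixedLetters <- strsplit(gsub("x", "", RR1_TEXT), "")[[1]]
  allA <- paste(rep("A", 60), collapse = "")
  expect_equal(consensusScore(allA, mo$rr1)$score,
               mean(fixedLetters == "A"))
  ## protein shorter than the motif scores 0 with no location
  short <- consensusScore(randomSeq(20), mo$rr1)
  expect_equal(short$score, 0)
  expect_true(is.na(short$start))
  ## brute-force equivalence on random proteins
  set.seed(31)
  fixedPos <- which(strsplit(RR1_TEXT, "")[[1]] != "x")
  for (k in 1:10) {
    s <- randomSeq(45, c("G", "F", "Y", "P", "D", "A"))
    chars <- strsplit(s, "")[[1]]
    width <- nchar(RR1_TEXT)
    want <- max(vapply(seq_len(nchar(s) - width + 1), function(st) {
      win <- chars[st:(st + width - 1)]
      mean(win[fixedPos] == fixedLetters & win[fixedPos] != "X")
    }, numeric(1)))
    expect_equal(consensusScore(s, mo$rr1)$score, want)
  }
})

test_that("a perfect consensus score coincides with a zero-mismatch hit", {
  mo <- defaultMotifs()
  set.seed(41)
  for (k in 1:10) {
    core <- fillConsensus(RR1_TEXT, sample(c("A", "G", "S"), 1))
    s <- paste0(randomSeq(sample(5:15, 1)), core, randomSeq(sample(5:15, 1)))
    cs <- consensusScore(s, mo$rr1)
    hit <- scanMotif(s, mo$rr1, maxMismatches = 0)
    expect_equal(cs$score == 1, nrow(hit) >= 1)
  }
})
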