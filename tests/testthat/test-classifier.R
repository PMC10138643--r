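refCat <- simulateReference(seed = 101)
mo <- defaultMotifs()
cfg <- cpConfig()

test_that("planted R&R consensus proteins are called CPR with the right subfamily", {
  set.seed(51)
  rr1 <- paste0(randomSeq(20, LETTERS[1:8]), fillConsensus(RR1_TEXT, "A"),
                randomSeq(20, LETTERS[1:8]))
  call1 <- classifyCpr("p1", rr1, mo, refCat, cfg)
  expect_equal(call1$family, "CPR")
  expect_equal(call1$subfamily, "RR-1")
  rr2 <- fillConsensus(RR2_TEXT, "G")
  call2 <- classifyCpr("p2", rr2, mo, refCat, cfg)
  expect_equal(call2$subfamily, "RR-2")
  expect_null(classifyCpr("p3", paste(rep("A", 80), collapse = ""),
                          mo, refCat, cfg))
})

test_that("near-tied subfamily scores fall back to RR-NC", {
  ## a protein carrying both consensus regions scores 1.0 vs both: tie
  both <- paste0(fillConsensus(RR1_TEXT, "A"), "AAAAA",
                 fillConsensus(RR2_TEXT, "A"))
  call <- classifyCpr("p", both, mo, refCat, cfg)
  expect_equal(call$family, "CPR")
  expect_equal(call$subfamily, "RR-NC")
})

test_that("RR-3 is claimed by exemplar identity beating the consensus evidence", {
  set.seed(52)
  ex <- as.character(refSequences(refSubset(refCat, "CPR", "RR-3")))[[1]]
  chars <- strsplit(ex, "")[[1]]
  mut <- chars
  idx <- sample(length(chars), round(0.1 * length(chars)))
  mut[idx] <- sample(setdiff(LETTERS[1:20], mut[idx]), length(idx), TRUE)
  call <- classifyCpr("p", paste(mut, collapse = ""), mo, refCat, cfg)
  expect_equal(call$subfamily, "RR-3")
})

test_that("ChtBD2 spacing separates CPAP1 from CPAP3 by domain count", {
  set.seed(53)
  inst <- function(m) {
    paste(vapply(m@elements, function(el) switch(el$type,
      fixed = el$residues,
      alt = el$residues[1],
      gap = randomSeq(el$min, LETTERS[1:8])), character(1)), collapse = "")
  }
  one <- paste0(randomSeq(10, LETTERS[1:8]), inst(mo$cpap1),
                randomSeq(10, LETTERS[1:8]))
  expect_equal(classifyCpap("p", one, mo, cfg)$family, "CPAP1")
  three <- paste0(inst(mo$cpap3), randomSeq(10, LETTERS[1:8]),
                  inst(mo$cpap3), randomSeq(10, LETTERS[1:8]), inst(mo$cpap3))
  expect_equal(classifyCpap("p", three, mo, cfg)$family, "CPAP3")
  expect_null(classifyCpap("p", paste(rep("A", 120), collapse = ""), mo, cfg))
})

test_that("Tweedle calls need ordered blocks", {
  b1 <- "KAAY"; b2 <- "KAAAAFIKAP"; b3 <- "TAAYVL"; b4 <- "KPEVYAFVKY"
  sp <- "WWWWW"
  good <- paste0(sp, b1, sp, b2, sp, b3, sp, b4, sp)
  expect_equal(classifyTweedle("p", good, mo, cfg)$family, "CPT")
  shuffled <- paste0(sp, b4, sp, b3, sp, b2, sp, b1, sp)
  expect_null(classifyTweedle("p", shuffled, mo, cfg))
  expect_null(classifyTweedle("p", paste0(sp, b2, sp), mo, cfg))
  ## three ordered blocks suffice under the default
  threeOf4 <- paste0(sp, b1, sp, b2, sp, b4, sp)
  expect_equal(classifyTweedle("p", threeOf4, mo, cfg)$family, "CPT")
})

test_that("low-complexity rules fire in their fixed order", {
  set.seed(54)
  cfc <- paste0("WWWWW", "CAAAAAC", "WWW", "CAAAAAC", "WWWWW")
  expect_equal(classifyLowComplexity("p", cfc, mo, refCat, cfg)$family, "CPCFC")
  lcp <- paste0("AAA", paste(rep(c("PV", "PY"), 8), collapse = ""), "AAA")
  expect_equal(classifyLowComplexity("p", lcp, mo, refCat, cfg)$family, "CPLCP")
  cpg <- paste0("WAWAWAWA", "GGYGG", "AWA", "GGYGG", "AWA", "GGYGG", "AWAWAW")
  expect_equal(classifyLowComplexity("p", cpg, mo, refCat, cfg)$family, "CPG")
  aap <- paste0(randomSeq(30, c("W", "K", "E")), "AAPVAAPVAAPV",
                randomSeq(30, c("W", "K", "E")))
  expect_equal(classifyLowComplexity("p", aap, mo, refCat, cfg)$family, "CPH")
  ## homology route: a mutated copy of a verified CPF member
  cpf <- as.character(refSequences(refSubset(refCat, "CPF")))[[1]]
  expect_equal(classifyLowComplexity("p", cpf, mo, refCat, cfg)$family, "CPF")
})

test_that("the cascade yields exactly one deterministic call per protein", {
  sim <- simulateProteome(nDecoys = 3, mutationRate = 0.02, seed = 17)
  c1 <- classifyProteome(sim$proteome, sim$reference)
  c2 <- classifyProteome(sim$proteome, sim$reference)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), length(sim$proteome))
  expect_false(anyDuplicated(c1$id) > 0)
  ## partition: per-family counts sum to proteome size
  expect_equal(sum(table(c1$family)), length(sim$proteome))
  ## subfamily present iff family is CPR
  expect_true(all(is.na(c1$subfamily) | c1$family == "CPR"))
  expect_true(all(!is.na(c1$subfamily[c1$family == "CPR"])))
  ## evidence recorded for every CP call
  expect_true(all(nzchar(c1$evidence[c1$family != "not-CP"])))
  expect_equal(nrow(classifyProteome(Biostrings::AAStringSet())), 0)
})

test_that("random sequences are overwhelmingly not-CP", {
  set.seed(77)
  seqs <- vapply(1:100, function(i)
    paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ""),
                 100, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("rnd%03d", 1:100)
  calls <- classifyProteome(seqs, refCat)
  expect_gte(mean(calls$family == "not-CP"), 0.95)
})

test_that("strengthening a planted motif never flips the call away", {
  set.seed(78)
  core <- fillConsensus(RR1_TEXT, "A")
  chars <- strsplit(core, "")[[1]]
  weak <- chars
  idx <- sample(which(chars != "A"), 6)
  weak[idx] <- "W"
  weakCall <- classifyCpr("p", paste(weak, collapse = ""), mo, refCat, cfg)
  strongCall <- classifyCpr("p", core, mo, refCat, cfg)
  if (!is.null(weakCall) && weakCall$subfamily == "RR-1")
    expect_equal(strongCall$subfamily, "RR-1")
  expect_equal(strongCall$family, "CPR")
})

test_that("manual overrides are applied and flagged", {
  sim <- simulateProteome(setNames(2L, "RR-1"), nDecoys = 0,
                          mutationRate = 0, seed = 5)
  ov <- data.frame(id = sim$truth$id[1], family = "CPG",
                   subfamily = NA_character_)
  calls <- classifyProteome(sim$proteome, sim$reference, overrides = ov)
  expect_equal(calls$family[1], "CPG")
  expect_true(calls$override[1])
  expect_false(any(calls$override[-1]))
  expect_error(classifyProteome(sim$proteome, sim$reference,
                                overrides = data.frame(id = "nope",
                                                       family = "CPG")),
               "unknown id")
})

test_that("naming inherits ortholog stems and numbers the rest in order", {
  calls <- data.frame(id = c("g1", "g2", "g3"),
                      family = c("CPF", "CPG", "CPG"),
                      subfamily = NA_character_, evidence = "e",
                      stringsAsFactors = FALSE)
  ref <- ReferenceCatalog(
    Biostrings::AAStringSet(c(r1 = "MKVA")), family = "CPF",
    name = "BmorCPF")
  loci <- GenomicRanges::GRanges(c("chr9", "chr5"),
                                 IRanges::IRanges(c(100, 200), c(150, 280)))
  loci$gene_id <- c("g3", "g2")
  named <- assignNames(calls, ref, orthologs = c(g1 = "r1"), loci = loci,
                       prefix = "Ap")
  expect_equal(named$assigned_name, c("ApCPF", "ApCPG1", "ApCPG2"))
  ## duplicated ortholog target -> collision
  expect_error(assignNames(calls, ref, orthologs = c(g2 = "r1", g3 = "r1")),
               "collision")
})
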