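test_that("computeH follows the bitscore-difference definition and the absent-side convention", {
  # equal best scores on both sides
  expect_equal(unname(computeH(makeProfile(S = list(Metazoa = 100, Fungi = 100)))), 0)
  # no metazoan hit: h equals the best non-metazoan bitscore
  expect_equal(unname(computeH(makeProfile(S = list(Eubacteria = 85)))), 85)
  # no non-metazoan hit: h is minus the metazoan bitscore
  expect_equal(unname(computeH(makeProfile(S = list(Metazoa = 120)))), -120)
  # max over non-metazoan taxa, not any particular one
  p <- makeProfile(S = list(Metazoa = 120, Fungi = 150, Eubacteria = 140))
  expect_equal(unname(computeH(p)), 30)
  expect_equal(unname(classifyH(computeH(p))), "foreign")
})

test_that("h is antisymmetric under swapping metazoan and best non-metazoan scores", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 20, 300); b <- runif(1, 20, 300)
    h1 <- computeH(makeProfile(S = list(Metazoa = a, Fungi = b)))
    h2 <- computeH(makeProfile(S = list(Metazoa = b, Fungi = a)))
    expect_equal(unname(h1), -unname(h2))
  }
})

test_that("classifyH boundary semantics match the three-way rule", {
  expect_equal(classifyH(c(30, 0, 15, -5, 29.999, 100)),
               c("foreign", "metazoan", "indeterminate", "metazoan",
                 "indeterminate", "foreign"))
  expect_equal(classifyH(25, theta = 25), "foreign")
  expect_error(classifyH(NaN), "finite")
})

test_that("alien index matches the closed form and clamps symmetrically", {
  p <- makeProfile(S = list(Metazoa = 100, Fungi = 100),
                   E = list(Metazoa = 1e-30, Fungi = 1e-30))
  expect_equal(unname(computeAlienIndex(p)), 0)
  p <- makeProfile(S = list(Metazoa = 100, Fungi = 200),
                   E = list(Metazoa = 1e-50, Fungi = 1e-100))
  # ln(1e-50 + c) - ln(1e-100 + c) = 50 ln 10 up to the negligible clamp
  expect_equal(unname(computeAlienIndex(p)), 50 * log(10), tolerance = 1e-12)
  # double underflow: both sides clamp to c, index 0
  p <- makeProfile(S = list(Metazoa = 500, Fungi = 600),
                   E = list(Metazoa = 0, Fungi = 0))
  expect_equal(unname(computeAlienIndex(p)), 0)
  # absent E treated as 1
  p <- makeProfile(S = list(Eubacteria = 80), E = list(Eubacteria = 1e-20))
  expect_equal(unname(computeAlienIndex(p)), log(1 + 1e-200) - log(1e-20 + 1e-200))
})

test_that("buildProfiles retains top-k by bitscore, filters on the matched-set ceiling, and tallies exclusions", {
  hits <- rbind(
    makeHit("t1", "Eubacteria", bitscore = 100 + 1:7),  # 7 hits, keep best 5
    makeHit("t1", "Metazoa", bitscore = 50),
    makeHit("t2", "Metazoa", bitscore = 20, evalue = 1e-4)  # fails the filter
  )
  prof <- buildProfiles(hits, topK = 5)
  expect_equal(nrow(profiles(prof)), 1L)
  expect_equal(excludedCount(prof), 1L)
  expect_equal(profiles(prof)$S_Eubacteria, 107)
  kept <- retainedHits(prof)
  expect_equal(sum(kept$taxon == "Eubacteria"), 5L)
  expect_equal(sort(kept$bitscore[kept$taxon == "Eubacteria"]), 103:107)
  # single hit passing the ceiling is retained
  prof2 <- buildProfiles(makeHit("t3", "Fungi", bitscore = 40, evalue = 1e-6))
  expect_equal(nrow(profiles(prof2)), 1L)
  # ties on bitscore break by lower E-value
  tied <- rbind(makeHit("t4", "Fungi", bitscore = 80, evalue = 1e-50),
                makeHit("t4", "Fungi", bitscore = 80, evalue = 1e-40))
  p4 <- profiles(buildProfiles(tied, topK = 1))
  expect_equal(p4$E_Fungi, 1e-50)
})

test_that("h equals a brute-force max-scan over retained hits on random profiles", {
  set.seed(7)
  for (rep in 1:30) {
    nHit <- sample(1:12, 1)
    hits <- do.call(rbind, lapply(seq_len(nHit), function(i) {
      makeHit("tx", sample(hgtTaxa(), 1), bitscore = runif(1, 30, 300),
              sseqid = paste0("s", i))
    }))
    prof <- buildProfiles(hits)
    if (!nrow(profiles(prof))) next
    kept <- retainedHits(prof)
    met <- kept$bitscore[kept$taxon == "Metazoa"]
    non <- kept$bitscore[kept$taxon != "Metazoa"]
    oracle <- (if (length(non)) max(non) else 0) -
      (if (length(met)) max(met) else 0)
    expect_equal(unname(computeH(prof)), oracle)
  }
})

test_that("source-taxon attribution takes the max bitscore with documented tie-breaks", {
  p <- makeProfile(S = list(Eubacteria = 140, Fungi = 120))
  expect_equal(unname(attributeSourceTaxon(p)), "Eubacteria")
  # bitscore tie broken by lower E-value
  p <- makeProfile(S = list(Eubacteria = 140, Fungi = 140),
                   E = list(Eubacteria = 1e-50, Fungi = 1e-60))
  expect_equal(unname(attributeSourceTaxon(p)), "Fungi")
  # full tie: fixed taxon order (Eubacteria first)
  p <- makeProfile(S = list(Fungi = 140, Eubacteria = 140),
                   E = list(Fungi = 1e-50, Eubacteria = 1e-50))
  expect_equal(unname(attributeSourceTaxon(p)), "Eubacteria")
})

test_that("sign of h agrees with sign of the alien index when E and S are consistent", {
  set.seed(11)
  mn <- 1e9
  for (rep in 1:40) {
    Smet <- if (runif(1) < 0.8) runif(1, 30, 200) else NA
    Snon <- if (runif(1) < 0.8) runif(1, 30, 200) else NA
    if (is.na(Smet) && is.na(Snon)) next
    S <- list(); E <- list()
    if (!is.na(Smet)) { S$Metazoa <- Smet; E$Metazoa <- mn * 2^(-Smet) }
    if (!is.na(Snon)) { S$Fungi <- Snon; E$Fungi <- mn * 2^(-Snon) }
    p <- makeProfile(S = S, E = E)
    h <- unname(computeH(p)); ai <- unname(computeAlienIndex(p))
    if (h != 0 && ai != 0 && !is.na(Smet) && !is.na(Snon)) {
      expect_equal(sign(h), sign(ai))
    }
  }
})

test_that("summarizeHGT reports counts, composition and stricter-ceiling reanalysis with recomputed bests", {
  # transcript with a weak non-metazoan best that disappears at 1e-10 while a
  # weaker-scoring metazoan hit with a *better* E survives: the stricter
  # reanalysis must recompute bests, flipping the category
  hits <- rbind(
    makeHit("t1", "Eubacteria", bitscore = 90, evalue = 1e-7),
    makeHit("t1", "Metazoa", bitscore = 50, evalue = 1e-12),
    makeHit("t2", "Eubacteria", bitscore = 200, evalue = 1e-40)
  )
  prof <- buildProfiles(hits)
  rec <- hgtRecords(prof)
  s <- summarizeHGT(rec, prof, epsilons = 1e-10)
  expect_equal(s$matched, 2L)
  expect_equal(s$foreign, 2L)
  expect_equal(s$no_metazoan_among_foreign[["count"]], 1)
  expect_equal(unname(s$source_composition["Eubacteria"]), 1)
  expect_equal(s$reanalysis$matched, 2L)
  expect_equal(s$reanalysis$foreign, 1L)  # t1 flips to metazoan at 1e-10
})

test_that("foreign count is non-increasing in theta and matched set non-increasing in epsilon", {
  sim <- simulateHitTable(simParams(nTranscripts = 300, seed = 21))
  prof <- buildProfiles(sim$hits)
  h <- computeH(prof)
  counts <- vapply(c(5, 15, 30, 60, 120), function(th)
    sum(classifyH(h, theta = th) == "foreign"), numeric(1))
  expect_true(all(diff(counts) <= 0))
  matched <- vapply(c(1e-3, 1e-5, 1e-10, 1e-20), function(eps)
    nrow(profiles(buildProfiles(sim$hits, epsilon = eps))), numeric(1))
  expect_true(all(diff(matched) <= 0))
})

test_that("crossrefGeneSet reports per-category match fractions", {
  sim <- simulateHitTable(simParams(nTranscripts = 200, seed = 31))
  rec <- hgtRecords(buildProfiles(sim$hits))
  r <- records(rec)
  empty <- data.frame(qseqid = character(), evalue = numeric())
  x <- crossrefGeneSet(rec, empty)
  expect_true(all(x$fraction_matched == 0))
  # reference matching only metazoan transcripts
  metIds <- r$transcript_id[r$category == "metazoan"]
  ref <- data.frame(qseqid = metIds, evalue = 1e-8)
  x <- crossrefGeneSet(rec, ref, epsilons = 1e-5)
  expect_equal(x$fraction_matched[x$category == "metazoan"], 1)
  expect_equal(x$fraction_matched[x$category == "foreign"], 0)
})

test_that("summary tables round-trip into profiles and records", {
  sim <- simulateHitTable(simParams(nTranscripts = 150, seed = 41))
  prof <- buildProfiles(sim$hits)
  rec1 <- hgtRecords(prof)
  # write a supplementary-style summary table and re-derive the records
  p <- profiles(prof)
  tab <- data.frame(transcript = p$transcript_id, sequence_length = p$length)
  for (tx in hgtTaxa()) {
    tab[[paste0("min_evalue_", tx)]] <- p[[paste0("E_", tx)]]
    tab[[paste0("max_bitscore_", tx)]] <- p[[paste0("S_", tx)]]
  }
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  prof2 <- summaryToProfiles(readSummaryTable(f))
  rec2 <- hgtRecords(prof2)
  expect_equal(records(rec2)$h, records(rec1)$h, tolerance = 1e-8)
  expect_equal(records(rec2)$category, records(rec1)$category)
})
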