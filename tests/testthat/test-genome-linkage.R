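test_that("a single full-length match gives coverage 1 and rule boundaries hold", {
  lens <- c(t1 = 300)
  ctg <- c(c1 = 5000)
  m <- makeMatch("t1", "c1", 1, 300, 1001, 1300, evalue = 1e-50)
  res <- selectAlignmentChain(m, lens, ctg)
  expect_equal(res$coverage$coverage_fraction, 1)
  expect_equal(res$coverage$covered_bp, 300)
  expect_equal(res$coverage$contigs, "c1")

  # E-value above the ceiling is rejected
  bad <- makeMatch("t1", "c1", 1, 300, 1001, 1300, evalue = 0.01)
  expect_equal(selectAlignmentChain(bad, lens, ctg)$coverage$coverage_fraction, 0)
  # exactly at the ceiling is accepted (<=)
  at <- makeMatch("t1", "c1", 1, 300, 1001, 1300, evalue = 1e-3)
  expect_equal(selectAlignmentChain(at, lens, ctg)$coverage$coverage_fraction, 1)

  # 40 bp is NOT longer than 40 bp: rejected; 41 bp accepted
  m40 <- makeMatch("t1", "c1", 1, 40, 1001, 1040)
  m41 <- makeMatch("t1", "c1", 1, 41, 1001, 1041)
  expect_equal(selectAlignmentChain(m40, lens, ctg)$coverage$covered_bp, 0)
  expect_equal(selectAlignmentChain(m41, lens, ctg)$coverage$covered_bp, 41)
})

test_that("exact tiling of three 100-bp exons covers the whole transcript", {
  lens <- c(t1 = 300); ctg <- c(c1 = 10000)
  mm <- rbind(makeMatch("t1", "c1", 1, 100, 1000, 1099, bitscore = 180),
              makeMatch("t1", "c1", 101, 200, 2000, 2099, bitscore = 170),
              makeMatch("t1", "c1", 201, 300, 3000, 3099, bitscore = 160))
  res <- selectAlignmentChain(mm, lens, ctg)
  expect_equal(res$coverage$coverage_fraction, 1)
  expect_equal(res$coverage$n_accepted, 3L)
})

test_that("overlapping matches are rejected and accepted intervals stay disjoint", {
  lens <- c(t1 = 400); ctg <- c(c1 = 10000)
  mm <- rbind(makeMatch("t1", "c1", 1, 200, 1000, 1199, bitscore = 300),
              makeMatch("t1", "c1", 150, 350, 3000, 3200, bitscore = 250),
              makeMatch("t1", "c1", 201, 300, 5000, 5099, bitscore = 200))
  res <- selectAlignmentChain(mm, lens, ctg)
  acc <- res$accepted
  expect_equal(nrow(acc), 2L)
  expect_equal(sort(acc$qstart), c(1, 201))
  # pairwise disjoint intervals
  iv <- acc[order(acc$qstart), c("qstart", "qend")]
  if (nrow(iv) > 1) expect_true(all(iv$qstart[-1] > iv$qend[-nrow(iv)]))
  expect_equal(res$coverage$covered_bp, 300)
})

test_that("the cross-contig rule requires both matches near contig ends", {
  lens <- c(t1 = 400)
  # contig ends: c1 length 2000, match at 1500..1599 -> 401 bp from the end;
  # c2 match at 50..149 -> 49 bp from the start
  ctg <- c(c1 = 2000, c2 = 5000, c3 = 50000)
  nearEndPair <- rbind(
    makeMatch("t1", "c1", 1, 150, 1850, 1999, bitscore = 300),   # 1 bp from end
    makeMatch("t1", "c2", 151, 300, 50, 199, bitscore = 250))    # 49 bp from start
  res <- selectAlignmentChain(nearEndPair, lens, ctg)
  expect_equal(res$coverage$n_accepted, 2L)
  expect_setequal(strsplit(res$coverage$contigs, ",")[[1]], c("c1", "c2"))

  farPair <- rbind(
    makeMatch("t1", "c3", 1, 150, 20000, 20149, bitscore = 300), # mid-contig
    makeMatch("t1", "c2", 151, 300, 50, 199, bitscore = 250))
  res2 <- selectAlignmentChain(farPair, lens, ctg)
  expect_equal(res2$coverage$n_accepted, 1L)
  expect_equal(res2$coverage$contigs, "c3")

  # unknown contig length when the end rule is consulted -> data error
  expect_error(selectAlignmentChain(nearEndPair, lens, ctg["c1"]),
               "contig length")
})

test_that("the greedy chain is invariant to input row order", {
  set.seed(101)
  lens <- c(t1 = 500); ctg <- c(c1 = 8000, c2 = 8000)
  mm <- do.call(rbind, lapply(1:8, function(i) {
    qs <- sample(1:450, 1)
    makeMatch("t1", sample(c("c1", "c2"), 1), qs, min(500, qs + sample(41:120, 1)),
              1000 * i, 1000 * i + 100, evalue = 10^-sample(4:30, 1),
              bitscore = sample(50:300, 1))
  }))
  ref <- selectAlignmentChain(mm, lens, ctg)
  for (rep in 1:5) {
    perm <- mm[sample(nrow(mm)), ]
    res <- selectAlignmentChain(perm, lens, ctg)
    expect_equal(res$coverage, ref$coverage)
  }
})

test_that("chain selection equals the independent rule oracle on random instances", {
  set.seed(111)
  for (rep in 1:40) {
    L <- sample(200:800, 1)
    lens <- c(tx = L)
    ctg <- c(cA = sample(c(1500, 30000), 1), cB = sample(c(1500, 30000), 1))
    nM <- sample(1:10, 1)
    mm <- do.call(rbind, lapply(seq_len(nM), function(i) {
      qs <- sample(seq_len(max(1, L - 60)), 1)
      qe <- min(L, qs + sample(20:200, 1))
      ctgId <- sample(names(ctg), 1)
      ss <- sample(seq_len(ctg[[ctgId]] - 300), 1)
      makeMatch("tx", ctgId, qs, qe, ss, ss + (qe - qs),
                evalue = 10^-sample(1:30, 1), bitscore = sample(40:300, 1))
    }))
    res <- selectAlignmentChain(mm, lens, ctg)
    orc <- oracleChain(mm, L, ctg)
    expect_equal(res$coverage$covered_bp, orc$covered_bp)
    expect_equal(res$coverage$coverage_fraction, orc$coverage)
    expect_equal(res$coverage$n_accepted, length(orc$accepted))
    # removing any accepted match never increases covered bp
    expect_true(res$coverage$coverage_fraction >= 0 &&
                  res$coverage$coverage_fraction <= 1)
  }
})

test_that("genomic-coordinate overlap mode is available behind a flag", {
  lens <- c(t1 = 400); ctg <- c(c1 = 10000)
  # same genomic interval hit by two disjoint transcript intervals
  mm <- rbind(makeMatch("t1", "c1", 1, 100, 1000, 1099, bitscore = 300),
              makeMatch("t1", "c1", 201, 300, 1050, 1149, bitscore = 250))
  byTx <- selectAlignmentChain(mm, lens, ctg, overlapOn = "transcript")
  byG <- selectAlignmentChain(mm, lens, ctg, overlapOn = "genomic")
  expect_equal(byTx$coverage$n_accepted, 2L)
  expect_equal(byG$coverage$n_accepted, 1L)
})

test_that("coverage histogram stratifies and uses a strict cut", {
  cov <- data.frame(transcript_id = c("a", "b", "c", "d"),
                    n_accepted = c(1L, 1L, 1L, 0L),
                    covered_bp = c(100, 50, 51, 0),
                    coverage_fraction = c(1, 0.5, 0.51, 0),
                    contigs = c("c1", "c1", "c2", ""),
                    stringsAsFactors = FALSE)
  cats <- c(a = "foreign", b = "foreign", c = "metazoan", d = "foreign")
  hh <- coverageHistogram(cov, categories = cats)
  # exactly 0.5 is excluded by the strict > 0.5 cut
  expect_equal(unname(hh$above_cut["foreign"]), 1 / 3)
  expect_equal(unname(hh$above_cut["metazoan"]), 1)
  expect_equal(sum(hh$histogram$count), 4L)
  # all unplaced -> nothing above any positive cut
  cov0 <- cov; cov0$coverage_fraction <- 0; cov0$contigs <- ""
  expect_equal(unname(coverageHistogram(cov0)$above_cut["overall"]), 0)
})

test_that("co-localisation counts metazoan and different-taxon foreign co-residents", {
  cov <- data.frame(
    transcript_id = c("f1", "f2", "f3", "m1", "f4"),
    n_accepted = 1L, covered_bp = 100,
    coverage_fraction = 1,
    contigs = c("c1", "c1", "c2", "c2", "c3"),
    stringsAsFactors = FALSE)
  rec <- data.frame(
    transcript_id = c("f1", "f2", "f3", "m1", "f4"),
    length = 100, h = c(90, 90, 90, -50, 90), alien_index = 0,
    category = c("foreign", "foreign", "foreign", "metazoan", "foreign"),
    source_taxon = c("Eubacteria", "Fungi", "Eubacteria", NA, "Eubacteria"),
    has_significant_metazoan = TRUE, stringsAsFactors = FALSE)
  r <- colocalizationReport(cov, rec)
  # f1+f2 share c1 with different taxa; f3 shares c2 with a metazoan;
  # f4 is alone on c3
  expect_equal(r$fraction_colocalized, 3 / 4)
  pc <- r$per_contig[order(r$per_contig$contig_id), ]
  expect_equal(pc$contig_id, c("c1", "c2", "c3"))
  expect_equal(pc$n_metazoan, c(0L, 1L, 0L))
  expect_equal(pc$n_foreign_other_taxon, c(2L, 0L, 0L))

  # a foreign transcript alone on its contig is never co-located
  solo <- cov[cov$transcript_id == "f4", ]
  expect_equal(colocalizationReport(solo, rec)$fraction_colocalized, 0)
})

test_that("synthetic genome recovers the generator's co-localisation rate within binomial error", {
  p <- simParams(nTranscripts = 1500, seed = 19, colocalizationRate = 0.8)
  sim <- simulateHitTable(p)
  g <- simulateGenome(sim$truth, p)
  lens <- setNames(sim$truth$length, sim$truth$transcript_id)
  ctg <- setNames(g$contigs$length, g$contigs$contig_id)
  ch <- selectAlignmentChain(g$alignments, lens, ctg)
  rec <- hgtRecords(buildProfiles(sim$hits))
  r <- colocalizationReport(ch$coverage, rec)
  nF <- sum(records(rec)$category == "foreign")
  expect_lt(abs(r$fraction_colocalized - 0.8),
            3 * sqrt(0.8 * 0.2 / nF) + 0.05)
  # contamination 0.1 -> about 90% of foreign transcripts well covered
  cats <- setNames(records(rec)$category, records(rec)$transcript_id)
  hh <- coverageHistogram(ch$coverage, categories = cats)
  nFcov <- sum(!is.na(cats) & cats == "foreign")
  expect_lt(abs(unname(hh$above_cut["foreign"]) - 0.9),
            3 * sqrt(0.9 * 0.1 / nFcov) + 0.03)
})
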