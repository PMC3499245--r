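test_that("alignment trimming drops exactly the single-residue columns", {
  aln <- c(a = "MK-A-", b = "M--AC", c = "-KQA-")
  # col1: 2 residues keep; col2: 2 keep; col3: 1 drop; col4: 3 keep; col5: 1 drop
  out <- trimAlignment(aln)
  expect_equal(unname(out), c("MKA", "M-A", "-KA"))
  expect_equal(names(out), c("a", "b", "c"))
  # column with >= 2 residues is kept even with gaps
  expect_equal(unname(trimAlignment(c(x = "A-", y = "A-"))), c("A", "A"))
  expect_error(trimAlignment(c(x = "A-", y = "-C")), "degenerate")
  expect_error(trimAlignment("AAAA"), "two sequences")
})

test_that("trimming agrees with a per-column brute-force filter on random gapped alignments", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(2:8, 1); L <- sample(5:40, 1)
    m <- matrix(sample(c("A", "C", "D", "-"), n * L, replace = TRUE,
                       prob = c(0.25, 0.25, 0.2, 0.3)), nrow = n)
    keep <- colSums(m != "-") > 1
    if (!any(keep)) next
    aln <- setNames(apply(m, 1, paste, collapse = ""), paste0("s", 1:n))
    expected <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
    expect_equal(unname(trimAlignment(aln)), expected)
  }
})

test_that("the NJ stand-in recovers clean topologies and bootstrapN = 0 means no supports", {
  # two clean clades separated by many substitutions
  aln <- c(m1 = "AAAAAAAAAACCCCCCCCCC", m2 = "AAAAAAAAAACCCCCCCCCG",
           b1 = "TTTTTTTTTTGGGGGGGGGG", b2 = "TTTTTTTTTTGGGGGGGGGA")
  tr <- buildSupportTree(aln, bootstrapN = 50, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.binary(tr))
  # the (m1,m2) | (b1,b2) split must be present with full support
  a <- extractMonophylySupports(tr, focal = "m1",
                                taxa = c(m1 = NA, m2 = "Metazoa",
                                         b1 = "Eubacteria", b2 = "Eubacteria"))
  expect_equal(unname(a$taxon_support["Eubacteria"]), 1)
  tr0 <- buildSupportTree(aln, bootstrapN = 0)
  expect_null(tr0$node.label)
  expect_error(buildSupportTree(aln[1:3]), "too few")
})

test_that("monophyly supports match the worked example with distinct root-edge labels", {
  tr <- ape::read.tree(text = "((m1:1,m2:1)0.9:1,(b1:1,focal:1)0.86:1);")
  a <- extractMonophylySupports(tr, focal = "focal",
                                taxa = c(m1 = "Metazoa", m2 = "Metazoa",
                                         b1 = "Eubacteria", focal = NA))
  expect_equal(unname(a$taxon_support["Metazoa"]), 0.9)
  expect_equal(unname(a$focal_support["Eubacteria"]), 0.86)
  expect_equal(a$separation_from_metazoa, 0.86)
  expect_equal(a$n_nonfocal_leaves, 3L)
  expect_equal(a$n_taxa_present, 2L)
})

test_that("a star tree yields all-absent supports and absent never passes the threshold", {
  tr <- ape::read.tree(text = "(m1:1,m2:1,b1:1,focal:1);")
  a <- extractMonophylySupports(tr, focal = "focal",
                                taxa = c(m1 = "Metazoa", m2 = "Metazoa",
                                         b1 = "Eubacteria", focal = NA))
  expect_true(all(is.na(a$taxon_support)))
  expect_true(all(is.na(a$focal_support)))
  expect_true(is.na(a$separation_from_metazoa))
  # nothing strongly supported with metazoans present -> group 2
  expect_equal(assignGroup(a), 2L)
})

test_that("bipartition extraction agrees with exhaustive enumeration on random trees up to 12 leaves", {
  set.seed(71)
  for (rep in 1:40) {
    nt <- sample(4:12, 1)
    tr <- ape::rtree(nt)
    tr$tip.label <- c("focal",
                      sprintf("%s_x_%d",
                              sample(hgtTaxa(), nt - 1, replace = TRUE),
                              2:nt))
    tr$node.label <- round(runif(tr$Nnode), 2)
    taxa <- leafTaxa(tr$tip.label, focal = "focal")
    a <- extractMonophylySupports(tr, "focal", taxa)
    o <- oracleMonophyly(tr, "focal", taxa)
    expect_equal(a$taxon_support, o$taxon, tolerance = 1e-12)
    expect_equal(a$focal_support, o$focal, tolerance = 1e-12)
  }
})

test_that("group assignment follows the definitions and the 1,3,5,4,2 precedence", {
  base <- list(transcript_id = "t", taxon_support = c(Metazoa = NA),
               focal_support = c(Metazoa = NA),
               separation_from_metazoa = NA_real_,
               n_nonfocal_leaves = 5L, n_taxa_present = 2L,
               taxa_present = c("Eubacteria", "Metazoa"),
               only_metazoan = FALSE)
  # only metazoan hits -> group 1 regardless of supports
  g1 <- modifyList(base, list(only_metazoan = TRUE, taxa_present = "Metazoa",
                              n_taxa_present = 1L))
  expect_equal(assignGroup(g1), 1L)
  # strong focal-with-Metazoa -> group 1
  g1b <- modifyList(base, list(focal_support = c(Metazoa = 0.9)))
  expect_equal(assignGroup(g1b), 1L)
  # too few sequences -> group 3, even with strong non-metazoan support
  g3 <- modifyList(base, list(n_nonfocal_leaves = 2L,
                              focal_support = c(Eubacteria = 0.99)))
  expect_equal(assignGroup(g3), 3L)
  # monophyletic with exactly one non-metazoan taxon -> group 5
  g5 <- modifyList(base, list(focal_support = c(Eubacteria = 0.86),
                              separation_from_metazoa = 0.86))
  expect_equal(assignGroup(g5), 5L)
  # metazoan monophyly strongly rejected without a single-taxon grouping -> 4
  g4 <- modifyList(base, list(separation_from_metazoa = 0.9))
  expect_equal(assignGroup(g4), 4L)
  # nothing strong -> group 2
  g2 <- modifyList(base, list(focal_support = c(Eubacteria = 0.5),
                              separation_from_metazoa = 0.5))
  expect_equal(assignGroup(g2), 2L)
  # precedence: group-1 evidence beats group-5 evidence
  g15 <- modifyList(base, list(focal_support = c(Metazoa = 0.9,
                                                 Eubacteria = 0.95)))
  expect_equal(assignGroup(g15), 1L)
})

test_that("raising sMin never moves a transcript from group 2 into 1, 4 or 5", {
  set.seed(81)
  for (rep in 1:60) {
    a <- list(transcript_id = "t",
              taxon_support = c(Metazoa = runif(1)),
              focal_support = c(Metazoa = runif(1), Eubacteria = runif(1),
                                Fungi = runif(1)),
              separation_from_metazoa = runif(1),
              n_nonfocal_leaves = sample(2:8, 1),
              n_taxa_present = 3L,
              taxa_present = c("Eubacteria", "Fungi", "Metazoa"),
              only_metazoan = FALSE)
    gLow <- assignGroup(a, sMin = 0.6)
    gHigh <- assignGroup(a, sMin = 0.9)
    if (gLow == 2L) expect_true(gHigh %in% c(2L, 3L))
  }
})

test_that("noiseless synthetic trees classify to the true group with perfect accuracy", {
  p <- simParams(nTranscripts = 300, seed = 15, misleadingRate = 0,
                 supportAlpha = 1e6, supportBeta = 1e-3)
  sim <- simulateHitTable(p)
  ts <- simulateTrees(sim$truth, p)
  cls <- classifyTrees(ts$trees)
  expect_true(all(cls$group == 5L))
  # and the supported taxon is the true source
  best <- vapply(seq_len(nrow(cls)), function(i) {
    fs <- unlist(cls[i, grep("focal_support_", names(cls))])
    hgtTaxa()[which.max(replace(fs, is.na(fs), -1))]
  }, character(1))
  truth <- ts$truth$true_taxon[match(cls$transcript_id, ts$truth$transcript_id)]
  expect_equal(unname(best), truth)
})

test_that("group summaries tally verification as groups 4+5 plus no-metazoan-hit transcripts", {
  s <- summarizeGroups(c(1, 4, 4, 5, 2), nNoMetazoan = 5L)
  expect_equal(s$table$count, c(1L, 1L, 0L, 2L, 1L))
  expect_equal(s$verified, 8L)
  expect_equal(s$total, 10L)
  expect_equal(s$verification_rate, 0.8)
  s0 <- summarizeGroups(integer(0))
  expect_equal(sum(s0$table$count), 0L)
  expect_true(is.na(s0$verification_rate))
})

test_that("support-threshold calibration recovers the threshold that generated the labels", {
  set.seed(91)
  mkAssess <- function() {
    list(transcript_id = "t",
         taxon_support = c(Metazoa = runif(1)),
         focal_support = c(Metazoa = runif(1, 0, 0.5),
                           Eubacteria = runif(1)),
         separation_from_metazoa = runif(1),
         n_nonfocal_leaves = 6L, n_taxa_present = 2L,
         taxa_present = c("Eubacteria", "Metazoa"), only_metazoan = FALSE)
  }
  assess <- replicate(200, mkAssess(), simplify = FALSE)
  recorded <- vapply(assess, assignGroup, integer(1), sMin = 0.8)
  cal <- calibrateSupportThreshold(assess, recorded)
  g <- vapply(assess, assignGroup, integer(1), sMin = cal$sMin)
  expect_equal(mean(g == recorded), 1)
  expect_lt(abs(cal$sMin - 0.8), 0.05)
})

test_that("extra leaves can be mapped to Metazoa for an inclusive re-analysis", {
  # focal clusters with nematodes; treating them as Metazoa turns a group-5
  # style call into group 1
  tr <- ape::read.tree(
    text = "(((nem1:1,focal:1)0.95:1,nem2:1)0.9:1,((m1:1,m2:1)0.8:1,(b1:1,b2:1)0.7:1)0.6:1);")
  baseTaxa <- c(nem1 = NA, nem2 = NA, focal = NA,
                m1 = "Metazoa", m2 = "Metazoa",
                b1 = "Eubacteria", b2 = "Eubacteria")
  excl <- function(labels, focal) {
    tx <- baseTaxa[labels]
    names(tx) <- labels
    tx[grepl("^nem", labels)] <- "OtherEukaryotes"  # stand-in: not metazoan
    tx
  }
  incl <- function(labels, focal) {
    tx <- baseTaxa[labels]
    names(tx) <- labels
    tx[grepl("^nem", labels)] <- "Metazoa"
    tx
  }
  gExcl <- assignGroup(extractMonophylySupports(tr, "focal",
                                                excl(tr$tip.label, "focal")))
  gIncl <- assignGroup(extractMonophylySupports(tr, "focal",
                                                incl(tr$tip.label, "focal")))
  expect_equal(gExcl, 5L)   # groups strongly with the non-metazoan leaves
  expect_false(gIncl %in% c(4L, 5L))  # no longer rejectable once nematodes count
})
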