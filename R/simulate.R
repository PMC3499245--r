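#' Construct simulator parameters
#'
#' Defaults mirror the study conditions of a desiccation-tolerant rotifer
#' transcriptome: median transcript length about 341 bp with mean about 445 bp
#' (log-normal), a 10\% foreign fraction, and a foreign source mix dominated by
#' eubacteria (59\%) with fungi (23\%), other eukaryotes (11\%), plants/algae
#' (6\%) and archaea (1\%). Bitscores follow S = bitsPerBp * length + N(0, sd)
#' with own-lineage hits scoring 0.6 bits/bp and cross-lineage hits 0.2
#' bits/bp; E-values are derived as E = searchSpace * 2^(-S) so E and S stay
#' consistent in the Karlin-Altschul sense. Cross-lineage hits are absent with
#' probability \code{dropout} (default 0.67, matching the observed sparsity of
#' metazoan matches among foreign transcripts).
#'
#' @param nTranscripts number of transcripts.
#' @param foreignFraction probability a transcript is foreign.
#' @param taxonMix named probability vector over \code{nonMetazoanTaxa()}.
#' @param lengthMeanlog,lengthSdlog log-normal length parameters (bp).
#' @param bitsPerBpOwn,bitsPerBpCross,bitscoreSd bitscore model.
#' @param searchSpace effective m*n for E = (m*n) * 2^(-S).
#' @param dropout probability a cross-lineage taxon has no hit.
#' @param supportAlpha,supportBeta Beta law of true-clade branch supports.
#' @param misleadingRate fraction of trees with the focal leaf regrafted into
#'   a wrong clade.
#' @param contaminationRate probability a foreign transcript is a contaminant
#'   (no genomic placement).
#' @param colocalizationRate probability a placed foreign transcript shares a
#'   contig with a metazoan transcript.
#' @param seed integer seed.
#' @return a validated \code{\link{SimParams-class}} object.
#' @examples
#' p <- simParams(nTranscripts = 200, seed = 1)
#' sim <- simulateHitTable(p)
#' head(sim$hits)
#' @export
simParams <- function(nTranscripts = 5000,
                      foreignFraction = 0.10,
                      taxonMix = c(Eubacteria = 0.59, Archaea = 0.01,
                                   Fungi = 0.23, Plantae = 0.06,
                                   OtherEukaryotes = 0.11),
                      lengthMeanlog = log(341),
                      lengthSdlog = sqrt(2 * (log(445) - log(341))),
                      bitsPerBpOwn = 0.6,
                      bitsPerBpCross = 0.2,
                      bitscoreSd = 4,
                      searchSpace = 1e9,
                      dropout = 0.67,
                      supportAlpha = 8,
                      supportBeta = 2,
                      misleadingRate = 0,
                      contaminationRate = 0.1,
                      colocalizationRate = 0.8,
                      seed = 1L) {
  new("SimParams",
      nTranscripts = as.integer(nTranscripts),
      foreignFraction = as.numeric(foreignFraction),
      taxonMix = taxonMix[nonMetazoanTaxa()],
      lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
      bitsPerBpOwn = bitsPerBpOwn, bitsPerBpCross = bitsPerBpCross,
      bitscoreSd = bitscoreSd, searchSpace = searchSpace,
      dropout = dropout,
      supportAlpha = supportAlpha, supportBeta = supportBeta,
      misleadingRate = misleadingRate,
      contaminationRate = contaminationRate,
      colocalizationRate = colocalizationRate,
      seed = as.integer(seed))
}

# E-value from bitscore, Karlin-Altschul style. Underflows to 0 for large S,
# which mimics the "0" E-values printed by search tools.
.evalueFromBits <- function(S, mn) mn * 2^(-S)

#' Simulate a taxon-partitioned homology hit table with ground truth
#'
#' Emulates the tabular output of a translated search of every transcript
#' against six taxon partitions (Metazoa, Eubacteria, Archaea, Fungi, Plantae,
#' OtherEukaryotes): up to five hits per transcript and taxon, bitscores from
#' the length-proportional score model (a transcript's own lineage scores at
#' \code{bitsPerBpOwn}, all others at \code{bitsPerBpCross}, subject to
#' dropout) and E-values derived from the bitscores. Deterministic under a
#' fixed seed.
#'
#' @param params a \code{\link{SimParams-class}} object.
#' @return list with elements \code{hits} (13-column data.frame: the standard
#'   12 tabular columns plus \code{taxon}) and \code{truth} (data.frame with
#'   \code{transcript_id}, \code{length}, \code{true_origin},
#'   \code{true_genomic} in \{"placed","contaminant"\}).
#' @export
simulateHitTable <- function(params) {
  validObject(params)
  .withSeed(params@seed + 101L, {
    n <- params@nTranscripts
    id <- sprintf("tr%05d", seq_len(n))
    len <- pmax(100L, as.integer(round(stats::rlnorm(n, params@lengthMeanlog,
                                                     params@lengthSdlog))))
    isForeign <- stats::runif(n) < params@foreignFraction
    origin <- rep("Metazoa", n)
    if (any(isForeign)) {
      origin[isForeign] <- sample(nonMetazoanTaxa(), sum(isForeign),
                                  replace = TRUE, prob = params@taxonMix)
    }
    genomic <- ifelse(isForeign & stats::runif(n) < params@contaminationRate,
                      "contaminant", "placed")

    # transcript x taxon grid
    grid <- expand.grid(i = seq_len(n), taxon = hgtTaxa(),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    own <- origin[grid$i] == grid$taxon
    present <- own | stats::runif(nrow(grid)) >= params@dropout
    grid <- grid[present, , drop = FALSE]
    own <- own[present]

    L <- len[grid$i]
    rate <- ifelse(own, params@bitsPerBpOwn, params@bitsPerBpCross)
    bestS <- pmax(25, rate * L + stats::rnorm(nrow(grid), 0, params@bitscoreSd))
    nhits <- sample.int(5L, nrow(grid), replace = TRUE)

    rows <- rep(seq_len(nrow(grid)), nhits)
    rank <- sequence(nhits)
    # lower-ranked hits trail the best by cumulative exponential decrements
    decr <- ifelse(rank == 1L, 0, stats::rexp(length(rows), rate = 1 / 8))
    S <- pmax(20, bestS[rows] - (rank - 1L) * 2 - decr)
    E <- .evalueFromBits(S, params@searchSpace)

    qlen <- len[grid$i][rows]
    alnLen <- pmax(30L, as.integer(round(qlen / 3 * stats::runif(length(rows), 0.5, 1))))
    qstart <- pmax(1L, as.integer(round(stats::runif(length(rows), 1, qlen / 4))))
    hits <- data.frame(
      qseqid = id[grid$i][rows],
      sseqid = sprintf("%s_subj%04d_%d",
                       substr(grid$taxon[rows], 1, 3),
                       grid$i[rows] %% 9973L, rank),
      pident = round(stats::runif(length(rows), 35, 95), 1),
      length = alnLen,
      mismatch = as.integer(round(alnLen * stats::runif(length(rows), 0.05, 0.4))),
      gapopen = sample(0:3, length(rows), replace = TRUE),
      qstart = qstart,
      qend = pmin(qlen, qstart + alnLen * 3L - 1L),
      sstart = 1L,
      send = alnLen,
      evalue = E,
      bitscore = round(S, 1),
      taxon = grid$taxon[rows],
      stringsAsFactors = FALSE
    )
    hits <- hits[order(hits$qseqid, hits$taxon, -hits$bitscore), ]
    rownames(hits) <- NULL

    truth <- data.frame(transcript_id = id, length = len,
                        true_origin = origin, true_genomic = genomic,
                        stringsAsFactors = FALSE)
    list(hits = hits, truth = truth)
  })
}

# build one simulated gene tree for a focal transcript.
# taxa present: metazoa + the true source + extra random taxa; each taxon a
# clean clade; focal grafted inside its (true or misleading) clade.
# Subtree strings carry no trailing branch length; ":1" is appended when a
# subtree becomes a child, so internal-node support labels end up in the
# standard position (after the closing parenthesis).
.simulateOneTree <- function(focalID, trueTaxon, params, nPerTaxon = 3L,
                             taxaPresent = NULL) {
  if (is.null(taxaPresent)) {
    taxaPresent <- unique(c("Metazoa", trueTaxon))
    extra <- setdiff(hgtTaxa(), taxaPresent)
    taxaPresent <- c(taxaPresent, sample(extra, sample(0:2, 1)))
  }
  mislead <- stats::runif(1) < params@misleadingRate
  hostTaxon <- trueTaxon
  if (mislead) {
    alternatives <- setdiff(taxaPresent, trueTaxon)
    if (length(alternatives)) hostTaxon <- sample(alternatives, 1)
  }
  sup <- function() round(stats::rbeta(1, params@supportAlpha, params@supportBeta), 3)
  join <- function(a, b) paste0("(", a, ":1,", b, ":1)", sup())
  fold <- function(parts) {
    while (length(parts) > 1L) parts <- c(join(parts[1], parts[2]), parts[-(1:2)])
    parts
  }
  cladeNwk <- vapply(taxaPresent, function(tx) {
    lv <- sprintf("%s_%s_%d", tx, substr(focalID, 3, 20), seq_len(nPerTaxon))
    if (tx == hostTaxon) lv <- c(join(focalID, lv[1]), lv[-1])
    fold(lv)
  }, character(1))
  nwk <- paste0(fold(cladeNwk), ";")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "misleading") <- mislead
  attr(tree, "hostTaxon") <- hostTaxon
  tree
}

#' Simulate support-annotated gene trees for foreign transcripts
#'
#' For each foreign transcript in the truth table, builds a gene tree in which
#' each sampled taxon forms a clean clade and the focal transcript leaf nests
#' inside its true source clade (or, with probability
#' \code{misleadingRate}, inside a wrong clade). Branch supports are drawn
#' from Beta(\code{supportAlpha}, \code{supportBeta}); leaf labels encode the
#' taxon as \code{<Taxon>_<id>_<k>} so \code{\link{leafTaxa}} can recover it.
#'
#' @param truth truth table from \code{\link{simulateHitTable}}.
#' @param params a \code{\link{SimParams-class}} object.
#' @param nPerTaxon leaves per non-focal taxon clade (default 3; use 1-2 to
#'   construct too-few-sequences cases).
#' @return list with \code{trees} (named list of \code{ape::phylo} with node
#'   labels holding supports) and \code{truth} (data.frame:
#'   \code{transcript_id}, \code{true_taxon}, \code{host_taxon},
#'   \code{misleading}).
#' @export
simulateTrees <- function(truth, params, nPerTaxon = 3L) {
  validObject(params)
  foreign <- truth[truth$true_origin != "Metazoa", , drop = FALSE]
  .withSeed(params@seed + 202L, {
    trees <- vector("list", nrow(foreign))
    names(trees) <- foreign$transcript_id
    misleading <- logical(nrow(foreign))
    host <- character(nrow(foreign))
    for (k in seq_len(nrow(foreign))) {
      tr <- .simulateOneTree(foreign$transcript_id[k], foreign$true_origin[k],
                             params, nPerTaxon = nPerTaxon)
      trees[[k]] <- tr
      misleading[k] <- attr(tr, "misleading")
      host[k] <- attr(tr, "hostTaxon")
    }
    list(trees = trees,
         truth = data.frame(transcript_id = foreign$transcript_id,
                            true_taxon = foreign$true_origin,
                            host_taxon = host, misleading = misleading,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a draft genome and transcript-to-genome alignment table
#'
#' Placed transcripts are split into 1-5 exon-like segments (each at least 40
#' bp) separated by intron gaps and laid onto genomic contigs; contaminant
#' transcripts receive no alignment rows. With probability
#' \code{colocalizationRate} a placed foreign transcript is put on the same
#' contig as a metazoan transcript (co-localisation evidence); otherwise it
#' gets a contig of its own.
#'
#' @param truth truth table from \code{\link{simulateHitTable}}.
#' @param params a \code{\link{SimParams-class}} object.
#' @return list with \code{contigs} (data.frame \code{contig_id},
#'   \code{length}), \code{alignments} (12-column data.frame, transcript vs
#'   contig), and \code{truth} (per transcript: \code{placed},
#'   \code{true_coverage}, \code{contig_id}, \code{colocalized}).
#' @export
simulateGenome <- function(truth, params) {
  validObject(params)
  .withSeed(params@seed + 303L, {
    n <- nrow(truth)
    placed <- truth$true_genomic == "placed"
    isForeign <- truth$true_origin != "Metazoa"

    # contig assignment: metazoan transcripts get "met" contigs (several share
    # one); placed foreign transcripts join a metazoan contig with probability
    # colocalizationRate, else get a private contig.
    contig <- rep(NA_character_, n)
    metIdx <- which(placed & !isForeign)
    nMetContig <- max(1L, ceiling(length(metIdx) / 3))
    if (length(metIdx)) {
      contig[metIdx] <- sprintf("ctg%05d", sample.int(nMetContig, length(metIdx),
                                                      replace = TRUE))
    }
    forIdx <- which(placed & isForeign)
    if (length(forIdx)) {
      joins <- (length(metIdx) > 0) &
        (stats::runif(length(forIdx)) < params@colocalizationRate)
      contig[forIdx] <- ifelse(joins,
                               sprintf("ctg%05d", sample.int(nMetContig,
                                                             length(forIdx), replace = TRUE)),
                               sprintf("ctgF%04d", seq_along(forIdx)))
    }

    alnRows <- vector("list", n)
    trueCov <- rep(NA_real_, n)
    offsets <- stats::setNames(rep(1L, length(unique(stats::na.omit(contig)))),
                               unique(stats::na.omit(contig)))
    for (i in which(placed)) {
      L <- truth$length[i]
      maxSeg <- max(1L, min(5L, L %/% 60L))
      nSeg <- sample.int(maxSeg, 1L)
      cuts <- sort(sample.int(L - 1L, nSeg - 1L))
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, L)
      keep <- (ends - starts + 1L) >= 41L
      if (!any(keep)) { starts <- 1L; ends <- L; keep <- TRUE }
      starts <- starts[keep]; ends <- ends[keep]
      segLen <- ends - starts + 1L
      cid <- contig[i]
      gpos <- offsets[cid]
      rows <- data.frame(
        qseqid = truth$transcript_id[i], sseqid = cid,
        pident = round(stats::runif(length(starts), 95, 100), 1),
        length = segLen, mismatch = 0L, gapopen = 0L,
        qstart = starts, qend = ends,
        sstart = gpos + cumsum(c(0L, utils::head(segLen, -1L) +
                                   sample(50:500, max(0, length(starts) - 1L),
                                          replace = TRUE))),
        send = 0L,
        evalue = .evalueFromBits(pmax(40, segLen * 1.8), params@searchSpace),
        bitscore = round(segLen * 1.8, 1),
        stringsAsFactors = FALSE
      )
      rows$send <- rows$sstart + segLen - 1L
      offsets[cid] <- max(rows$send) + sample(200:2000, 1L)
      alnRows[[i]] <- rows
      trueCov[i] <- sum(segLen) / L
    }
    alignments <- do.call(rbind, alnRows[!vapply(alnRows, is.null, logical(1))])
    if (is.null(alignments)) {
      alignments <- data.frame(qseqid = character(), sseqid = character(),
                               pident = numeric(), length = integer(),
                               mismatch = integer(), gapopen = integer(),
                               qstart = integer(), qend = integer(),
                               sstart = integer(), send = integer(),
                               evalue = numeric(), bitscore = numeric())
    }
    rownames(alignments) <- NULL
    usedContigs <- unique(stats::na.omit(contig))
    contigLen <- vapply(usedContigs, function(cc) {
      mx <- if (nrow(alignments)) max(c(0L, alignments$send[alignments$sseqid == cc])) else 0L
      as.integer(mx + sample(500:5000, 1L))
    }, integer(1))
    list(
      contigs = data.frame(contig_id = usedContigs, length = contigLen,
                           stringsAsFactors = FALSE),
      alignments = alignments,
      truth = data.frame(transcript_id = truth$transcript_id, placed = placed,
                         true_coverage = trueCov, contig_id = contig,
                         colocalized = !is.na(contig) & contig %in%
                           contig[metIdx] & isForeign,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Build a synthetic pathway map
#'
#' A simple pathway-to-EC map for simulation and tests: \code{nPathways}
#' pathways of \code{ecPerPathway} ECs each (ECs unique to their pathway).
#'
#' @param nPathways,ecPerPathway map dimensions.
#' @return data.frame with columns \code{pathway_id}, \code{pathway_name},
#'   \code{ec}.
#' @export
syntheticPathwayMap <- function(nPathways = 20, ecPerPathway = 10) {
  idx <- seq_len(nPathways * ecPerPathway)
  data.frame(
    pathway_id = rep(sprintf("ec%05d", 10 * seq_len(nPathways)), each = ecPerPathway),
    pathway_name = rep(sprintf("Synthetic pathway %d", seq_len(nPathways)),
                       each = ecPerPathway),
    ec = sprintf("%d.%d.%d.%d", (idx - 1) %% 6 + 1, (idx - 1) %% 9 + 1,
                 (idx - 1) %% 20 + 1, idx),
    stringsAsFactors = FALSE
  )
}

#' Simulate EC annotations with optional spiked-in enriched pathways
#'
#' Assigns EC numbers to transcripts such that in spiked pathways the ECs are
#' drawn preferentially from foreign transcripts (share \code{spikeShare}),
#' while non-spiked pathways follow the global category mix (the null).
#'
#' @param truth truth table from \code{\link{simulateHitTable}} (its
#'   \code{true_origin} defines the category: Metazoa -> metazoan, otherwise
#'   foreign; a fraction \code{indeterminateRate} is relabelled indeterminate).
#' @param pathwayMap data.frame as from \code{\link{syntheticPathwayMap}}.
#' @param spike character vector of pathway_ids to enrich for foreign ECs.
#' @param params a \code{\link{SimParams-class}} object (seed and foreign mix).
#' @param spikeShare share of a spiked pathway's ECs assigned to foreign-only
#'   transcripts (default 0.8).
#' @param indeterminateRate fraction of metazoan transcripts relabelled
#'   indeterminate (default 0.1).
#' @return list with \code{calls} (data.frame \code{transcript_id}, \code{ec},
#'   \code{category}) and \code{truth} (per pathway: \code{spiked} flag).
#' @export
simulateECAnnotations <- function(truth, pathwayMap, spike = character(),
                                  params, spikeShare = 0.8,
                                  indeterminateRate = 0.1) {
  validObject(params)
  .check(all(spike %in% pathwayMap$pathway_id),
         "spiked pathway(s) absent from the pathway map: ",
         paste(setdiff(spike, pathwayMap$pathway_id), collapse = ", "))
  .withSeed(params@seed + 404L, {
    category <- ifelse(truth$true_origin == "Metazoa", "metazoan", "foreign")
    met <- which(category == "metazoan")
    flip <- met[stats::runif(length(met)) < indeterminateRate]
    category[flip] <- "indeterminate"
    byCat <- split(truth$transcript_id, category)

    globalShare <- c(foreign = mean(category == "foreign"),
                     metazoan = mean(category == "metazoan"),
                     indeterminate = mean(category == "indeterminate"))
    out <- vector("list", nrow(pathwayMap))
    for (r in seq_len(nrow(pathwayMap))) {
      spiked <- pathwayMap$pathway_id[r] %in% spike
      pForeign <- if (spiked) spikeShare else globalShare["foreign"]
      pOther <- (1 - pForeign) * globalShare[c("metazoan", "indeterminate")] /
        max(1e-12, sum(globalShare[c("metazoan", "indeterminate")]))
      cat_r <- sample(c("foreign", "metazoan", "indeterminate"), 1,
                      prob = c(pForeign, pOther))
      pool <- byCat[[cat_r]]
      if (is.null(pool) || !length(pool)) next
      out[[r]] <- data.frame(transcript_id = sample(pool, 1), ec = pathwayMap$ec[r],
                             category = cat_r, stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(calls) <- NULL
    pw <- unique(pathwayMap[c("pathway_id", "pathway_name")])
    list(calls = calls,
         truth = data.frame(pathway_id = pw$pathway_id,
                            spiked = pw$pathway_id %in% spike,
                            stringsAsFactors = FALSE))
  })
}

#' Write dummy transcript sequences matching a truth table
#'
#' Sequence content is arbitrary (random nucleotides of the recorded lengths);
#' only the identifiers and lengths matter to the pipeline.
#'
#' @param truth truth table from \code{\link{simulateHitTable}}.
#' @param path output FASTA path.
#' @param seed RNG seed for the letters.
#' @return \code{path}, invisibly.
#' @export
writeDummyTranscripts <- function(truth, path, seed = 1L) {
  .withSeed(seed, {
    seqs <- vapply(truth$length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- truth$transcript_id
    Biostrings::writeXStringSet(x, filepath = path)
  })
  invisible(path)
}
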