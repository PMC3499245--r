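#' Build per-transcript, per-taxon best-hit profiles
#'
#' Distils a hit table into one profile per transcript: per taxon the top
#' \code{topK} hits by bitscore are retained (ties broken by lower E-value),
#' the best bitscore \code{S_<taxon>} and minimum E-value \code{E_<taxon>} are
#' recorded, and transcripts whose best E-value across all taxa exceeds
#' \code{epsilon} are excluded from the matched set (and tallied).
#'
#' @param hits data.frame as from \code{\link{readHits}} (must carry a
#'   \code{taxon} column with canonical labels).
#' @param lengths optional named vector of transcript lengths (bp), e.g. from
#'   \code{\link{readTranscriptLengths}}; when absent, lengths are estimated
#'   as the maximum query coordinate seen per transcript.
#' @param topK hits retained per transcript and taxon (default 5).
#' @param epsilon matched-set E-value ceiling (default 1e-5).
#' @return a \code{\link{HitProfiles-class}} object.
#' @examples
#' sim <- simulateHitTable(simParams(nTranscripts = 50, seed = 1))
#' prof <- buildProfiles(sim$hits)
#' prof
#' @export
buildProfiles <- function(hits, lengths = NULL, topK = 5L, epsilon = 1e-5) {
  .check(is.data.frame(hits), "hits must be a data.frame")
  .check(topK >= 1L, "topK must be >= 1")
  .check(epsilon > 0, "epsilon must be > 0")
  if (nrow(hits)) {
    .check(all(c("qseqid", "taxon", "evalue", "bitscore") %in% names(hits)),
           "hits must have qseqid, taxon, evalue, bitscore columns")
    hits$taxon <- normalizeTaxon(hits$taxon)
  }

  if (!nrow(hits)) {
    empty <- data.frame(transcript_id = character(), length = numeric(),
                        stringsAsFactors = FALSE)
    for (tx in hgtTaxa()) empty[[paste0("S_", tx)]] <- numeric()
    for (tx in hgtTaxa()) empty[[paste0("E_", tx)]] <- numeric()
    return(new("HitProfiles", profiles = empty, hits = hits,
               excluded = 0L, epsilon = epsilon, topK = as.integer(topK)))
  }

  # top-k per (transcript, taxon) by bitscore desc, then evalue asc
  ord <- order(hits$qseqid, hits$taxon, -hits$bitscore, hits$evalue)
  h <- hits[ord, , drop = FALSE]
  grp <- paste(h$qseqid, h$taxon, sep = "\r")
  rank <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  h <- h[rank <= topK, , drop = FALSE]

  ids <- sort(unique(h$qseqid))
  prof <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  if (!is.null(lengths)) {
    prof$length <- as.numeric(lengths[ids])
  } else if ("qend" %in% names(h)) {
    mx <- tapply(h$qend, h$qseqid, max)
    prof$length <- as.numeric(mx[ids])
  } else {
    prof$length <- NA_real_
  }

  idIdx <- match(h$qseqid, ids)
  for (tx in hgtTaxa()) {
    sel <- h$taxon == tx
    Svec <- rep(NA_real_, length(ids))
    Evec <- rep(NA_real_, length(ids))
    if (any(sel)) {
      # h is sorted best-first within group, so the first row per transcript
      # is the max-bitscore hit (ties already broken by lower E)
      firstRow <- !duplicated(idIdx[sel])
      Svec[idIdx[sel][firstRow]] <- h$bitscore[sel][firstRow]
      mn <- tapply(h$evalue[sel], idIdx[sel], min)
      Evec[as.integer(names(mn))] <- as.numeric(mn)
    }
    prof[[paste0("S_", tx)]] <- Svec
    prof[[paste0("E_", tx)]] <- Evec
  }

  minE <- do.call(pmin, c(prof[paste0("E_", hgtTaxa())], na.rm = TRUE))
  keep <- !is.na(minE) & minE <= epsilon
  excluded <- sum(!keep)
  prof <- prof[keep, , drop = FALSE]
  rownames(prof) <- NULL
  keptHits <- h[h$qseqid %in% prof$transcript_id, , drop = FALSE]
  rownames(keptHits) <- NULL
  new("HitProfiles", profiles = prof, hits = keptHits,
      excluded = as.integer(excluded), epsilon = epsilon,
      topK = as.integer(topK))
}

# per-taxon best-score matrix helpers -------------------------------------

.scoreMatrix <- function(prof) as.matrix(prof[paste0("S_", hgtTaxa())])
.evalueMatrix <- function(prof) as.matrix(prof[paste0("E_", hgtTaxa())])

#' Compute the HGT index h
#'
#' h is the difference in bits between the best non-metazoan bitscore and the
#' best metazoan bitscore. A side with no hit contributes 0 bits (the
#' "absent-side" convention), so a transcript with only non-metazoan hits gets
#' h equal to its best non-metazoan bitscore.
#'
#' @param x a \code{\link{HitProfiles-class}} object or its profiles
#'   data.frame.
#' @return numeric vector of h values (bits), named by transcript.
#' @export
computeH <- function(x) {
  prof <- if (is(x, "HitProfiles")) profiles(x) else x
  S <- as.matrix(prof[paste0("S_", hgtTaxa())])
  .check(nrow(S) == 0 || any(!is.na(S)),
         "profiles contain no hits at all")
  nonmet <- S[, paste0("S_", nonMetazoanTaxa()), drop = FALSE]
  bestNon <- suppressWarnings(apply(nonmet, 1L, max, na.rm = TRUE))
  bestNon[!is.finite(bestNon)] <- 0
  met <- S[, "S_Metazoa"]
  met[is.na(met)] <- 0
  stats::setNames(bestNon - met, prof$transcript_id)
}

#' Compute the alien index
#'
#' AI = ln(E_Metazoa + c) - ln(E_best-non-metazoan + c), with absent E-values
#' treated as 1 (no evidence) and a small clamp constant c preventing infinite
#' values on E-value underflow. AI > 0 indicates a foreign signal. Provided
#' for comparison with the bitscore-based index h, which needs no clamp.
#'
#' @param x a \code{\link{HitProfiles-class}} object or its profiles data.frame.
#' @param clamp the constant c (default 1e-200).
#' @return numeric vector of alien-index values, named by transcript.
#' @export
computeAlienIndex <- function(x, clamp = 1e-200) {
  prof <- if (is(x, "HitProfiles")) profiles(x) else x
  E <- as.matrix(prof[paste0("E_", hgtTaxa())])
  .check(all(E >= 0, na.rm = TRUE), "negative E-values in profiles")
  nonmet <- E[, paste0("E_", nonMetazoanTaxa()), drop = FALSE]
  bestNon <- suppressWarnings(apply(nonmet, 1L, min, na.rm = TRUE))
  bestNon[!is.finite(bestNon)] <- 1
  met <- E[, "E_Metazoa"]
  met[is.na(met)] <- 1
  stats::setNames(log(met + clamp) - log(bestNon + clamp), prof$transcript_id)
}

#' Classify h values into metazoan / indeterminate / foreign
#'
#' Boundary semantics: h >= theta is foreign; h <= 0 is metazoan; strictly
#' between is indeterminate.
#'
#' @param h numeric vector of HGT index values (bits).
#' @param theta foreignness threshold (default 30 bits).
#' @return character vector of categories.
#' @export
classifyH <- function(h, theta = 30) {
  .check(all(is.finite(h)), "h must be finite")
  .check(is.numeric(theta) && theta > 0, "theta must be a positive number")
  ifelse(h >= theta, "foreign", ifelse(h <= 0, "metazoan", "indeterminate"))
}

#' Attribute the source taxon of foreign transcripts
#'
#' The non-metazoan taxon achieving the maximal bitscore; ties broken by the
#' lower E-value, then by the fixed taxon order of \code{nonMetazoanTaxa()}.
#'
#' @param x a \code{\link{HitProfiles-class}} object or its profiles data.frame.
#' @return character vector of taxon labels (NA where no non-metazoan hit),
#'   named by transcript.
#' @export
attributeSourceTaxon <- function(x) {
  prof <- if (is(x, "HitProfiles")) profiles(x) else x
  taxa <- nonMetazoanTaxa()
  S <- as.matrix(prof[paste0("S_", taxa)])
  E <- as.matrix(prof[paste0("E_", taxa)])
  out <- rep(NA_character_, nrow(prof))
  for (i in seq_len(nrow(prof))) {
    s <- S[i, ]
    if (all(is.na(s))) next
    best <- which(s == max(s, na.rm = TRUE))
    if (length(best) > 1L) {
      e <- E[i, best]
      e[is.na(e)] <- Inf
      best <- best[e == min(e)]
    }
    out[i] <- taxa[best[1L]]  # fixed taxon order as final tie-break
  }
  stats::setNames(out, prof$transcript_id)
}

#' Compute per-transcript HGT records
#'
#' Bundles \code{\link{computeH}}, \code{\link{computeAlienIndex}},
#' \code{\link{classifyH}} and \code{\link{attributeSourceTaxon}} into an
#' \code{\link{HGTRecords-class}} object, recording for each transcript whether
#' it has a significant metazoan hit (E_Metazoa <= epsilon).
#'
#' @param profilesObj a \code{\link{HitProfiles-class}} object.
#' @param theta foreignness threshold on h (default 30 bits).
#' @param epsilon E-value defining "significant" (defaults to the matched-set
#'   ceiling stored in the profiles).
#' @param clamp alien-index clamp constant.
#' @param databaseTag label of the database partitioning ("U", "S", ...).
#' @return an \code{\link{HGTRecords-class}} object.
#' @examples
#' sim <- simulateHitTable(simParams(nTranscripts = 100, seed = 1))
#' rec <- hgtRecords(buildProfiles(sim$hits))
#' rec
#' @export
hgtRecords <- function(profilesObj, theta = 30, epsilon = NULL,
                       clamp = 1e-200, databaseTag = "U") {
  .check(is(profilesObj, "HitProfiles"), "profilesObj must be a HitProfiles")
  if (is.null(epsilon)) epsilon <- profilesObj@epsilon
  prof <- profiles(profilesObj)
  h <- computeH(prof)
  ai <- computeAlienIndex(prof, clamp = clamp)
  cat_ <- classifyH(h, theta = theta)
  src <- attributeSourceTaxon(prof)
  src[cat_ != "foreign"] <- NA_character_
  rec <- data.frame(
    transcript_id = prof$transcript_id,
    length = prof$length,
    h = unname(h),
    alien_index = unname(ai),
    category = cat_,
    source_taxon = unname(src),
    has_significant_metazoan = !is.na(prof$E_Metazoa) & prof$E_Metazoa <= epsilon,
    stringsAsFactors = FALSE
  )
  new("HGTRecords", records = rec, theta = theta, epsilon = epsilon,
      databaseTag = databaseTag)
}

# recompute per-taxon bests using only hits passing a stricter epsilon, then
# rebuild records; returns NULL when nothing survives.
.reanalyseAtEpsilon <- function(profilesObj, eps, theta, databaseTag) {
  hits <- retainedHits(profilesObj)
  if (!nrow(hits)) return(NULL)
  strict <- hits[hits$evalue <= eps, , drop = FALSE]
  if (!nrow(strict)) return(NULL)
  lengths <- stats::setNames(profiles(profilesObj)$length,
                             profiles(profilesObj)$transcript_id)
  prof <- buildProfiles(strict, lengths = lengths,
                        topK = profilesObj@topK, epsilon = eps)
  hgtRecords(prof, theta = theta, epsilon = eps, databaseTag = databaseTag)
}

#' Summarise an HGT-index analysis
#'
#' Emits the headline numbers of a dataset: matched-set size, foreign count
#' and fraction, the fraction of foreign transcripts lacking a significant
#' metazoan hit, the source-taxon composition of foreign transcripts, and the
#' same summary recomputed at stricter E-value ceilings (per-taxon bests are
#' recomputed using only hits passing each stricter ceiling, not merely
#' re-filtered).
#'
#' @param recordsObj an \code{\link{HGTRecords-class}} object.
#' @param profilesObj the \code{\link{HitProfiles-class}} the records came
#'   from (needed for the stricter-epsilon reanalysis; optional).
#' @param epsilons stricter ceilings to reanalyse at (default 1e-10, 1e-15).
#' @return list with elements \code{matched}, \code{foreign},
#'   \code{foreign_fraction}, \code{no_metazoan_among_foreign} (count and
#'   fraction), \code{source_composition}, and \code{reanalysis} (data.frame
#'   with one row per stricter epsilon).
#' @export
summarizeHGT <- function(recordsObj, profilesObj = NULL,
                         epsilons = c(1e-10, 1e-15)) {
  rec <- records(recordsObj)
  foreign <- rec[rec$category == "foreign", , drop = FALSE]
  comp <- table(factor(foreign$source_taxon, levels = nonMetazoanTaxa()))
  noMet <- sum(!foreign$has_significant_metazoan)
  re <- NULL
  if (!is.null(profilesObj) && length(epsilons)) {
    re <- do.call(rbind, lapply(epsilons, function(eps) {
      r2 <- .reanalyseAtEpsilon(profilesObj, eps, theta(recordsObj),
                                recordsObj@databaseTag)
      if (is.null(r2)) {
        return(data.frame(epsilon = eps, matched = 0L, foreign = 0L,
                          foreign_fraction = NA_real_))
      }
      rr <- records(r2)
      data.frame(epsilon = eps, matched = nrow(rr),
                 foreign = sum(rr$category == "foreign"),
                 foreign_fraction = mean(rr$category == "foreign"))
    }))
  }
  list(
    matched = nrow(rec),
    foreign = nrow(foreign),
    foreign_fraction = if (nrow(rec)) nrow(foreign) / nrow(rec) else NA_real_,
    no_metazoan_among_foreign = c(
      count = noMet,
      fraction = if (nrow(foreign)) noMet / nrow(foreign) else NA_real_),
    source_composition = if (nrow(foreign)) comp / nrow(foreign) else comp,
    reanalysis = re
  )
}

#' Cross-reference transcripts against an arbitrary reference gene set
#'
#' Given hits of the transcripts against a reference gene set (e.g. known
#' nuclear mitochondrial genes), reports per category the fraction of
#' transcripts with any reference match at E <= epsilon, for each requested
#' epsilon. Used to check that a class of genes is not inflating the foreign
#' set.
#'
#' @param recordsObj an \code{\link{HGTRecords-class}} object.
#' @param referenceHits data.frame with at least \code{qseqid} and
#'   \code{evalue} columns (e.g. from \code{\link{readHits}}).
#' @param epsilons E-value ceilings (default 1e-5, 1e-10, 1e-15).
#' @return data.frame with columns \code{epsilon}, \code{category},
#'   \code{fraction_matched}.
#' @export
crossrefGeneSet <- function(recordsObj, referenceHits,
                            epsilons = c(1e-5, 1e-10, 1e-15)) {
  rec <- records(recordsObj)
  out <- expand.grid(epsilon = epsilons,
                     category = c("metazoan", "indeterminate", "foreign"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$fraction_matched <- vapply(seq_len(nrow(out)), function(i) {
    ids <- rec$transcript_id[rec$category == out$category[i]]
    if (!length(ids)) return(0)
    if (!nrow(referenceHits)) return(0)
    matched <- unique(referenceHits$qseqid[referenceHits$evalue <= out$epsilon[i]])
    mean(ids %in% matched)
  }, numeric(1))
  out
}

#' Convert a parsed summary table to HitProfiles
#'
#' Lets a per-taxon summary table (see \code{\link{readSummaryTable}}) be fed
#' straight into \code{\link{hgtRecords}}/\code{\link{summarizeHGT}}: the
#' recorded per-taxon minimum E-values and maximum bitscores become the
#' profile, and the matched-set filter is re-applied at \code{epsilon}.
#'
#' @param summary data.frame from \code{\link{readSummaryTable}}.
#' @param epsilon matched-set ceiling (default 1e-5).
#' @return a \code{\link{HitProfiles-class}} object (with an empty audit hit
#'   list, since the summary table holds only the per-taxon bests).
#' @export
summaryToProfiles <- function(summary, epsilon = 1e-5) {
  prof <- data.frame(transcript_id = summary$transcript_id,
                     length = summary$length, stringsAsFactors = FALSE)
  for (tx in hgtTaxa()) {
    sc <- paste0("S_", tx); ec <- paste0("E_", tx)
    prof[[sc]] <- if (sc %in% names(summary)) summary[[sc]] else NA_real_
    prof[[ec]] <- if (ec %in% names(summary)) summary[[ec]] else NA_real_
  }
  minE <- do.call(pmin, c(prof[paste0("E_", hgtTaxa())], na.rm = TRUE))
  keep <- !is.na(minE) & minE <= epsilon
  excluded <- sum(!keep)
  prof <- prof[keep, , drop = FALSE]
  rownames(prof) <- NULL
  emptyHits <- data.frame(qseqid = character(), sseqid = character(),
                          pident = numeric(), length = numeric(),
                          mismatch = numeric(), gapopen = numeric(),
                          qstart = numeric(), qend = numeric(),
                          sstart = numeric(), send = numeric(),
                          evalue = numeric(), bitscore = numeric(),
                          taxon = character(), stringsAsFactors = FALSE)
  new("HitProfiles", profiles = prof, hits = emptyHits,
      excluded = as.integer(excluded), epsilon = epsilon, topK = 5L)
}
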