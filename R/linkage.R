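#' Select the accepted alignment chain of one or many transcripts
#'
#' Implements the four acceptance rules for transcript-to-genome matches.
#' Matches are processed in descending bitscore (ties: ascending E-value, then
#' ascending transcript start, for determinism); a match is accepted iff
#' \enumerate{
#'   \item its E-value is <= \code{epsilon} (default 1e-3);
#'   \item its transcript interval overlaps no previously accepted match;
#'   \item its alignment is longer than \code{minLen} bp (strict; minimum
#'     exon length constraint);
#'   \item it is the first accepted match, OR lies on the same genomic contig
#'     as a previously accepted match, OR both it and some previously
#'     accepted match lie within \code{endDist} bp of their contigs' ends
#'     (maximum intron length constraint for genes split across contigs).
#' }
#' Overlap is tested on transcript coordinates: coverage is defined against
#' transcript length and exon chains naturally partition the transcript.
#' The covered fraction is the summed length of accepted transcript intervals
#' divided by the transcript length.
#'
#' @param matches data.frame of genome matches (12 tabular columns as from
#'   \code{\link{readHits}}; \code{qseqid} = transcript, \code{sseqid} =
#'   contig).
#' @param transcriptLengths named vector of transcript lengths (bp). Must
#'   cover every transcript in \code{matches}; transcripts present here but
#'   with no match get coverage 0.
#' @param contigLengths named vector of contig lengths (bp); required only
#'   when the end-distance rule is consulted.
#' @param epsilon,minLen,endDist rule parameters (defaults 1e-3, 40, 1000).
#' @param overlapOn \code{"transcript"} (default) or \code{"genomic"}:
#'   coordinate system for the non-overlap rule.
#' @return list with \code{coverage} (data.frame: \code{transcript_id},
#'   \code{n_accepted}, \code{covered_bp}, \code{coverage_fraction},
#'   \code{contigs} comma-separated) and \code{accepted} (the accepted match
#'   rows, with an \code{accept_order} column).
#' @export
selectAlignmentChain <- function(matches, transcriptLengths,
                                 contigLengths = NULL,
                                 epsilon = 1e-3, minLen = 40, endDist = 1000,
                                 overlapOn = c("transcript", "genomic")) {
  overlapOn <- match.arg(overlapOn)
  .check(!is.null(names(transcriptLengths)),
         "transcriptLengths must be a named vector")
  ids <- names(transcriptLengths)
  if (nrow(matches)) {
    .check(all(matches$qseqid %in% ids),
           "matches reference transcripts missing from transcriptLengths")
  }

  nearEnd <- function(row) {
    L <- if (!is.null(contigLengths) && row$sseqid %in% names(contigLengths))
      contigLengths[[row$sseqid]] else NULL
    if (is.null(L) || is.na(L)) {
      stop("contig length unknown for '", row$sseqid,
           "' but the end-distance rule is needed")
    }
    lo <- min(row$sstart, row$send); hi <- max(row$sstart, row$send)
    min(lo - 1, L - hi) <= endDist
  }

  accepted <- vector("list", length(ids))
  covRows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    mm <- matches[matches$qseqid == id, , drop = FALSE]
    if (nrow(mm)) {
      mm <- mm[order(-mm$bitscore, mm$evalue, pmin(mm$qstart, mm$qend)), ,
               drop = FALSE]
    }
    accQ <- matrix(numeric(0), ncol = 2)   # accepted transcript intervals
    accG <- matrix(numeric(0), ncol = 2)   # accepted genomic intervals
    accContig <- character(0)
    accNearEnd <- logical(0)
    accIdx <- integer(0)
    for (r in seq_len(nrow(mm))) {
      row <- mm[r, ]
      if (row$evalue > epsilon) next
      q <- sort(c(row$qstart, row$qend))
      alen <- row$length
      if (!(alen > minLen)) next
      if (overlapOn == "transcript") {
        if (nrow(accQ) && any(q[1] <= accQ[, 2] & q[2] >= accQ[, 1])) next
      } else {
        g <- sort(c(row$sstart, row$send))
        sameCtg <- accContig == row$sseqid
        if (any(sameCtg & g[1] <= accG[, 2] & g[2] >= accG[, 1])) next
      }
      if (length(accIdx)) {
        linked <- row$sseqid %in% accContig
        if (!linked) {
          linked <- any(accNearEnd) && nearEnd(row)
        }
        if (!linked) next
      }
      accQ <- rbind(accQ, q)
      accG <- rbind(accG, sort(c(row$sstart, row$send)))
      accContig <- c(accContig, row$sseqid)
      ne <- if (!is.null(contigLengths) && row$sseqid %in% names(contigLengths))
        nearEnd(row) else FALSE
      accNearEnd <- c(accNearEnd, ne)
      accIdx <- c(accIdx, r)
    }
    covered <- if (nrow(accQ)) sum(accQ[, 2] - accQ[, 1] + 1) else 0
    covRows[[k]] <- data.frame(
      transcript_id = id,
      n_accepted = length(accIdx),
      covered_bp = covered,
      coverage_fraction = covered / transcriptLengths[[id]],
      contigs = paste(unique(accContig), collapse = ","),
      stringsAsFactors = FALSE
    )
    if (length(accIdx)) {
      acc <- mm[accIdx, , drop = FALSE]
      acc$accept_order <- seq_along(accIdx)
      accepted[[k]] <- acc
    }
  }
  coverage <- do.call(rbind, covRows)
  if (is.null(coverage)) {
    coverage <- data.frame(transcript_id = character(), n_accepted = integer(),
                           covered_bp = numeric(), coverage_fraction = numeric(),
                           contigs = character(), stringsAsFactors = FALSE)
  }
  rownames(coverage) <- NULL
  acceptedDf <- do.call(rbind, accepted[!vapply(accepted, is.null, logical(1))])
  list(coverage = coverage, accepted = acceptedDf)
}

#' Coverage histogram and above-cut fraction
#'
#' Bins the per-transcript genomic coverage fractions and reports the
#' fraction of transcripts covered over more than \code{cut} of their length
#' (strict inequality), optionally stratified by category.
#'
#' @param coverage data.frame from \code{\link{selectAlignmentChain}}.
#' @param categories optional named vector transcript_id -> category
#'   ("metazoan"/"indeterminate"/"foreign") for stratification.
#' @param breaks histogram breaks on [0, 1] (default 10 bins).
#' @param cut coverage cut (default 0.5, i.e. ">50\%").
#' @return list with \code{histogram} (data.frame: bin_low, bin_high,
#'   count, pct, and per-category counts when stratified) and
#'   \code{above_cut} (named numeric: overall and per-category fraction).
#' @export
coverageHistogram <- function(coverage, categories = NULL,
                              breaks = seq(0, 1, by = 0.1), cut = 0.5) {
  cf <- coverage$coverage_fraction
  .check(all(cf >= 0 & cf <= 1.000001), "coverage fractions must lie in [0,1]")
  binIdx <- cut(pmin(cf, 1), breaks = breaks, include.lowest = TRUE,
                right = TRUE)
  hist <- data.frame(bin_low = utils::head(breaks, -1),
                     bin_high = breaks[-1],
                     count = as.integer(table(binIdx)))
  hist$pct <- if (length(cf)) 100 * hist$count / length(cf) else 0
  above <- c(overall = mean(cf > cut))
  if (!is.null(categories)) {
    catv <- unname(categories[coverage$transcript_id])
    for (cc in c("metazoan", "indeterminate", "foreign")) {
      sel <- !is.na(catv) & catv == cc
      hist[[paste0("count_", cc)]] <-
        as.integer(table(binIdx[sel]))
      above[cc] <- if (any(sel)) mean(cf[sel] > cut) else NA_real_
    }
  }
  list(histogram = hist, above_cut = above)
}

#' Foreign/metazoan co-localisation report
#'
#' A transcript is "on" a contig if it has an accepted match there. For each
#' contig carrying at least one foreign transcript, counts the metazoan
#' transcripts and the foreign transcripts of a different source taxon on the
#' same contig; reports the global fraction of foreign transcripts with at
#' least one such co-resident, the evidence that rules out contamination.
#'
#' @param coverage data.frame from \code{\link{selectAlignmentChain}} (its
#'   \code{contigs} column defines "on").
#' @param recordsObj an \code{\link{HGTRecords-class}} object (categories and
#'   source taxa), or its records data.frame.
#' @return list with \code{per_contig} (data.frame: contig_id, n_foreign,
#'   n_metazoan, n_foreign_other_taxon) and \code{fraction_colocalized}
#'   (fraction of on-genome foreign transcripts with a metazoan or
#'   different-taxon foreign co-resident).
#' @export
colocalizationReport <- function(coverage, recordsObj) {
  rec <- if (is(recordsObj, "HGTRecords")) records(recordsObj) else recordsObj
  on <- coverage[coverage$contigs != "", , drop = FALSE]
  longRows <- lapply(seq_len(nrow(on)), function(i) {
    data.frame(transcript_id = on$transcript_id[i],
               contig_id = strsplit(on$contigs[i], ",", fixed = TRUE)[[1]],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, longRows)
  if (is.null(long) || !nrow(long)) {
    return(list(per_contig = data.frame(contig_id = character(),
                                        n_foreign = integer(),
                                        n_metazoan = integer(),
                                        n_foreign_other_taxon = integer()),
                fraction_colocalized = NA_real_))
  }
  idx <- match(long$transcript_id, rec$transcript_id)
  long$category <- rec$category[idx]
  long$source_taxon <- rec$source_taxon[idx]

  foreignContigs <- unique(long$contig_id[long$category %in% "foreign"])
  perContig <- do.call(rbind, lapply(foreignContigs, function(cc) {
    sub <- long[long$contig_id == cc, , drop = FALSE]
    f <- sub[sub$category %in% "foreign", , drop = FALSE]
    nOther <- sum(vapply(seq_len(nrow(f)), function(i) {
      any(f$source_taxon[-i] != f$source_taxon[i], na.rm = TRUE)
    }, logical(1)) > 0)
    data.frame(contig_id = cc,
               n_foreign = nrow(f),
               n_metazoan = sum(sub$category %in% "metazoan"),
               n_foreign_other_taxon = as.integer(nOther),
               stringsAsFactors = FALSE)
  }))

  foreignIds <- unique(long$transcript_id[long$category %in% "foreign"])
  coloc <- vapply(foreignIds, function(id) {
    ctgs <- long$contig_id[long$transcript_id == id]
    mySrc <- rec$source_taxon[match(id, rec$transcript_id)]
    others <- long[long$contig_id %in% ctgs & long$transcript_id != id, ,
                   drop = FALSE]
    any(others$category %in% "metazoan") ||
      any(others$category %in% "foreign" &
            !is.na(others$source_taxon) & others$source_taxon != mySrc)
  }, logical(1))
  list(per_contig = perContig,
       fraction_colocalized = if (length(coloc)) mean(coloc) else NA_real_)
}
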