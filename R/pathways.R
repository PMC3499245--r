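#' Assign EC numbers to transcripts from their best annotated match
#'
#' Filters the hit table to matches against EC-annotated subjects at
#' E <= \code{epsilon} and collates, per transcript, the EC number(s) of its
#' first match. Under the default \code{"first-annotated"} policy the first
#' match is the highest-bitscore annotated match (the literal first row of
#' the annotation-filtered hit list); under \code{"best-overall"} a
#' transcript is dropped when its overall best match carries no EC.
#' Multi-EC subjects contribute all their ECs.
#'
#' @param hits data.frame of hits against the annotated database
#'   (\code{qseqid}, \code{sseqid}, \code{evalue}, \code{bitscore}).
#' @param subjectEC data.frame mapping \code{subject_id} to \code{ec}
#'   (one row per pair).
#' @param recordsObj \code{\link{HGTRecords-class}} (or its records
#'   data.frame) giving each transcript's category.
#' @param epsilon significance ceiling for matches (default 1e-5).
#' @param policy \code{"first-annotated"} (default) or \code{"best-overall"}.
#' @return list with \code{calls} (data.frame: \code{transcript_id},
#'   \code{ec}, \code{category}), \code{n_excluded} (transcripts with no
#'   annotated match), and \code{fraction_foreign_with_ec}.
#' @export
assignEC <- function(hits, subjectEC, recordsObj, epsilon = 1e-5,
                     policy = c("first-annotated", "best-overall")) {
  policy <- match.arg(policy)
  .check(is.data.frame(subjectEC) &&
           all(c("subject_id", "ec") %in% names(subjectEC)),
         "subjectEC must map subject_id to ec")
  bad <- !isValidEC(subjectEC$ec)
  .check(!any(bad), "malformed EC in subject map: ",
         paste(utils::head(unique(subjectEC$ec[bad]), 5), collapse = ", "))
  rec <- if (is(recordsObj, "HGTRecords")) records(recordsObj) else recordsObj

  h <- hits[hits$evalue <= epsilon & hits$qseqid %in% rec$transcript_id, ,
            drop = FALSE]
  h <- h[order(h$qseqid, -h$bitscore, h$evalue), , drop = FALSE]
  annotated <- h$sseqid %in% subjectEC$subject_id
  nTested <- length(unique(h$qseqid))

  if (policy == "first-annotated") {
    ha <- h[annotated, , drop = FALSE]
    first <- ha[!duplicated(ha$qseqid), , drop = FALSE]
  } else {
    best <- h[!duplicated(h$qseqid), , drop = FALSE]
    first <- best[best$sseqid %in% subjectEC$subject_id, , drop = FALSE]
  }
  nExcluded <- nTested - nrow(first)

  calls <- merge(first[c("qseqid", "sseqid")], subjectEC,
                 by.x = "sseqid", by.y = "subject_id")
  calls <- data.frame(transcript_id = calls$qseqid, ec = calls$ec,
                      stringsAsFactors = FALSE)
  calls$category <- rec$category[match(calls$transcript_id, rec$transcript_id)]
  calls <- unique(calls[order(calls$transcript_id, calls$ec), ])
  rownames(calls) <- NULL

  foreignIds <- rec$transcript_id[rec$category == "foreign"]
  frac <- if (length(foreignIds)) {
    mean(foreignIds %in% calls$transcript_id)
  } else NA_real_
  list(calls = calls, n_excluded = as.integer(nExcluded),
       fraction_foreign_with_ec = frac)
}

.colourOf <- function(cats) {
  has <- c(met = "metazoan" %in% cats, forn = "foreign" %in% cats,
           ind = "indeterminate" %in% cats)
  if (!any(has)) stop("empty category set for an EC")
  if (has["met"] && has["forn"]) return("orange")      # possibly grey too
  if (has["forn"] && has["ind"]) return("pink")
  if (has["met"] && has["ind"]) return("light-green")
  if (has["forn"]) return("red")
  if (has["met"]) return("green")
  "grey"
}

#' Colour-code EC numbers by the origin of their transcripts
#'
#' The six-colour scheme over the categories observed for each EC:
#' green = metazoan only; red = foreign only; grey = indeterminate only;
#' orange = metazoan + foreign (possibly + indeterminate); pink = foreign +
#' indeterminate; light-green = metazoan + indeterminate. The colour is a
#' pure function of the category set.
#'
#' @param calls data.frame of EC calls (\code{ec}, \code{category}), e.g.
#'   from \code{\link{assignEC}}.
#' @return data.frame with \code{ec}, \code{colour}, and logical
#'   \code{foreign_contrib} (red, pink or orange).
#' @export
colorEC <- function(calls) {
  .check(nrow(calls) > 0, "no EC calls")
  .check(all(calls$category %in% c("metazoan", "indeterminate", "foreign")),
         "unknown category in EC calls")
  sets <- split(calls$category, calls$ec)
  colour <- vapply(sets, .colourOf, character(1))
  out <- data.frame(ec = names(sets), colour = unname(colour),
                    stringsAsFactors = FALSE)
  out$foreign_contrib <- out$colour %in% c("red", "pink", "orange")
  rownames(out) <- NULL
  out
}

#' Hypergeometric pathway enrichment for foreign enzymes
#'
#' Universe N = unique EC numbers observed in the dataset; K = those with a
#' foreign contribution (red, pink or orange). For each pathway with n of its
#' ECs in the universe and k of them in the foreign-contributing set, the
#' upper-tail hypergeometric probability P(X >= k) is computed and
#' Benjamini-Hochberg adjusted across all tested pathways. Pathways with
#' n = 0 are excluded from testing and reported separately.
#'
#' @param colours data.frame from \code{\link{colorEC}}.
#' @param pathwayMap data.frame (\code{pathway_id}, \code{pathway_name},
#'   \code{ec}) as from \code{\link{readPathwayMap}}.
#' @return list with \code{results} (data.frame: pathway_id, pathway_name,
#'   n_ec (n), n_foreign_ec (k), p, q, ordered by p), \code{universe} (named:
#'   N, K), and \code{untested} (pathway ids with no EC in the universe).
#' @export
enrichPathways <- function(colours, pathwayMap) {
  uni <- unique(colours$ec)
  forn <- unique(colours$ec[colours$foreign_contrib])
  N <- length(uni); K <- length(forn)
  pw <- split(pathwayMap$ec, pathwayMap$pathway_id)
  nameOf <- pathwayMap$pathway_name[!duplicated(pathwayMap$pathway_id)]
  names(nameOf) <- pathwayMap$pathway_id[!duplicated(pathwayMap$pathway_id)]
  n <- vapply(pw, function(ecs) length(intersect(ecs, uni)), integer(1))
  k <- vapply(pw, function(ecs) length(intersect(ecs, forn)), integer(1))
  tested <- n > 0
  p <- stats::phyper(k[tested] - 1, K, N - K, n[tested], lower.tail = FALSE)
  res <- data.frame(pathway_id = names(pw)[tested],
                    pathway_name = unname(nameOf[names(pw)[tested]]),
                    n_ec = n[tested], n_foreign_ec = k[tested],
                    p = p, q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$pathway_id), ]
  rownames(res) <- NULL
  list(results = res, universe = c(N = N, K = K),
       untested = names(pw)[!tested])
}

#' Headline enzyme fractions
#'
#' The summary numbers of the enzyme analysis: the fraction of foreign
#' transcripts annotated with an EC number, and of the EC universe the share
#' with no metazoan contribution (red + pink), the share with both foreign
#' and metazoan contributions (orange), and their sum (all ECs with a foreign
#' contribution).
#'
#' @param calls data.frame of EC calls (\code{transcript_id}, \code{ec},
#'   \code{category}).
#' @param recordsObj \code{\link{HGTRecords-class}} or its records data.frame.
#' @return named numeric vector: \code{n_ec_universe},
#'   \code{foreign_only_count}, \code{foreign_and_metazoan_count},
#'   \code{fraction_foreign_with_ec}, \code{pct_foreign_only},
#'   \code{pct_foreign_and_metazoan}, \code{pct_foreign_contribution}.
#' @export
summarizeEnzymes <- function(calls, recordsObj) {
  rec <- if (is(recordsObj, "HGTRecords")) records(recordsObj) else recordsObj
  colours <- colorEC(calls)
  nU <- nrow(colours)
  nOnly <- sum(colours$colour %in% c("red", "pink"))
  nBoth <- sum(colours$colour == "orange")
  foreignIds <- rec$transcript_id[rec$category == "foreign"]
  fracForeign <- if (length(foreignIds)) {
    mean(foreignIds %in% calls$transcript_id)
  } else NA_real_
  c(n_ec_universe = nU,
    foreign_only_count = nOnly,
    foreign_and_metazoan_count = nBoth,
    fraction_foreign_with_ec = fracForeign,
    pct_foreign_only = 100 * nOnly / nU,
    pct_foreign_and_metazoan = 100 * nBoth / nU,
    pct_foreign_contribution = 100 * (nOnly + nBoth) / nU)
}
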