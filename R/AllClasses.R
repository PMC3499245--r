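#' @import methods
NULL

# ---------------------------------------------------------------------------
# SimParams
# ---------------------------------------------------------------------------

#' Parameters of the synthetic transcriptome-HGT simulator
#'
#' Container for everything the generators need: the number of transcripts,
#' the foreign fraction, the taxon mix of foreign transcripts, the transcript
#' length distribution, the bitscore/E-value model, hit dropout, the
#' branch-support model, contamination, and the seed. Construct with
#' \code{\link{simParams}}.
#'
#' @slot nTranscripts integer, number of transcripts to simulate.
#' @slot foreignFraction probability a transcript is of foreign origin.
#' @slot taxonMix named probability vector over the five non-metazoan taxa;
#'   source-taxon distribution of foreign transcripts.
#' @slot lengthMeanlog,lengthSdlog log-normal parameters of transcript length (bp).
#' @slot bitsPerBpOwn,bitsPerBpCross expected bits per transcript bp for hits
#'   against a transcript's own lineage and against other lineages.
#' @slot bitscoreSd Gaussian noise sd (bits) added to every best-hit bitscore.
#' @slot searchSpace effective search-space size m*n used to derive E-values
#'   from bitscores via E = (m*n) * 2^(-S).
#' @slot dropout probability that a cross-lineage taxon has no hit at all.
#' @slot supportAlpha,supportBeta Beta parameters for true-clade branch supports.
#' @slot misleadingRate fraction of simulated trees in which the focal leaf is
#'   regrafted into a wrong clade.
#' @slot contaminationRate probability a foreign transcript has no genomic
#'   placement (i.e. simulates a contaminant).
#' @slot colocalizationRate probability a placed foreign transcript shares its
#'   contig with a metazoan transcript.
#' @slot seed integer seed driving all generators via fixed offsets.
#' @seealso \code{\link{simParams}}, \code{\link{simulateHitTable}}
#' @export
setClass("SimParams", representation(
  nTranscripts = "integer",
  foreignFraction = "numeric",
  taxonMix = "numeric",
  lengthMeanlog = "numeric",
  lengthSdlog = "numeric",
  bitsPerBpOwn = "numeric",
  bitsPerBpCross = "numeric",
  bitscoreSd = "numeric",
  searchSpace = "numeric",
  dropout = "numeric",
  supportAlpha = "numeric",
  supportBeta = "numeric",
  misleadingRate = "numeric",
  contaminationRate = "numeric",
  colocalizationRate = "numeric",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nTranscripts < 1L) msg <- c(msg, "nTranscripts must be >= 1")
  if (!.isProb(object@foreignFraction)) msg <- c(msg, "foreignFraction must be in [0,1]")
  tm <- object@taxonMix
  if (!identical(sort(names(tm)), sort(nonMetazoanTaxa()))) {
    msg <- c(msg, "taxonMix must be named by the five non-metazoan taxa")
  } else if (any(tm < 0) || abs(sum(tm) - 1) > 1e-8) {
    msg <- c(msg, "taxonMix must be a probability vector summing to 1")
  }
  if (!(object@bitsPerBpOwn > object@bitsPerBpCross && object@bitsPerBpCross > 0)) {
    msg <- c(msg, "score model requires bitsPerBpOwn > bitsPerBpCross > 0")
  }
  if (object@bitscoreSd < 0) msg <- c(msg, "bitscoreSd must be >= 0")
  if (object@searchSpace <= 0) msg <- c(msg, "searchSpace must be > 0")
  for (fld in c("dropout", "misleadingRate", "contaminationRate", "colocalizationRate")) {
    if (!.isProb(slot(object, fld))) msg <- c(msg, paste(fld, "must be in [0,1]"))
  }
  if (object@supportAlpha <= 0 || object@supportBeta <= 0) {
    msg <- c(msg, "support Beta parameters must be positive")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# HitProfiles
# ---------------------------------------------------------------------------

#' Per-transcript, per-taxon best-hit profiles
#'
#' The substrate of the HGT index: for each transcript passing the matched-set
#' filter, the best bitscore and minimum E-value per taxon partition, distilled
#' from the top-k retained hits (kept in the \code{hits} slot for audit).
#' Absent taxa are represented as \code{NA} ("no hit"), never as bitscore 0,
#' so downstream rules can distinguish "no metazoan hit" from "weak metazoan
#' hit". Construct with \code{\link{buildProfiles}}.
#'
#' @slot profiles data.frame, one row per retained transcript with columns
#'   \code{transcript_id}, \code{length}, \code{S_<taxon>} (best bitscore) and
#'   \code{E_<taxon>} (min E-value) for the six taxa.
#' @slot hits data.frame of the retained top-k hits per transcript and taxon.
#' @slot excluded integer, transcripts dropped by the matched-set filter.
#' @slot epsilon numeric, the matched-set E-value ceiling used.
#' @slot topK integer, hits retained per transcript and taxon.
#' @export
setClass("HitProfiles", representation(
  profiles = "data.frame",
  hits = "data.frame",
  excluded = "integer",
  epsilon = "numeric",
  topK = "integer"
))

setValidity("HitProfiles", function(object) {
  need <- c("transcript_id", "length",
            paste0("S_", hgtTaxa()), paste0("E_", hgtTaxa()))
  miss <- setdiff(need, names(object@profiles))
  if (length(miss)) return(paste("profiles missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@profiles$transcript_id)) {
    return("duplicate transcript_id in profiles")
  }
  ev <- as.matrix(object@profiles[paste0("E_", hgtTaxa())])
  if (any(ev < 0, na.rm = TRUE)) return("negative E-values")
  TRUE
})

# ---------------------------------------------------------------------------
# HGTRecords
# ---------------------------------------------------------------------------

#' Per-transcript HGT index records
#'
#' One row per profiled transcript: the HGT index h (bits), the alien index,
#' the three-way category at threshold theta, the attributed source taxon for
#' foreign transcripts, and whether the transcript has a significant metazoan
#' hit. Construct with \code{\link{hgtRecords}}.
#'
#' @slot records data.frame with columns \code{transcript_id}, \code{length},
#'   \code{h}, \code{alien_index}, \code{category}, \code{source_taxon},
#'   \code{has_significant_metazoan}.
#' @slot theta numeric, foreignness threshold on h (bits).
#' @slot epsilon numeric, E-value defining a "significant" hit.
#' @slot databaseTag character, label of the database partitioning the hits
#'   came from (e.g. "U" or "S").
#' @export
setClass("HGTRecords", representation(
  records = "data.frame",
  theta = "numeric",
  epsilon = "numeric",
  databaseTag = "character"
))

setValidity("HGTRecords", function(object) {
  r <- object@records
  need <- c("transcript_id", "length", "h", "alien_index", "category",
            "source_taxon", "has_significant_metazoan")
  miss <- setdiff(need, names(r))
  if (length(miss)) return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (!all(r$category %in% c("metazoan", "indeterminate", "foreign"))) {
    return("category must be metazoan/indeterminate/foreign")
  }
  th <- object@theta
  ok <- (r$category == "foreign") == (r$h >= th) &
        (r$category == "metazoan") == (r$h <= 0)
  if (!all(ok)) return("category inconsistent with h and theta")
  TRUE
})

# ---------------------------------------------------------------------------
# Accessors and show methods
# ---------------------------------------------------------------------------

#' @rdname HitProfiles-class
#' @param object,x a \code{HitProfiles} or \code{HGTRecords} object.
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname HitProfiles-class
#' @export
setMethod("profiles", "HitProfiles", function(x) x@profiles)

#' @rdname HitProfiles-class
#' @export
setGeneric("retainedHits", function(x) standardGeneric("retainedHits"))

#' @rdname HitProfiles-class
#' @export
setMethod("retainedHits", "HitProfiles", function(x) x@hits)

#' @rdname HitProfiles-class
#' @export
setGeneric("excludedCount", function(x) standardGeneric("excludedCount"))

#' @rdname HitProfiles-class
#' @export
setMethod("excludedCount", "HitProfiles", function(x) x@excluded)

#' @rdname HGTRecords-class
#' @param x an \code{HGTRecords} object.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname HGTRecords-class
#' @export
setMethod("records", "HGTRecords", function(x) x@records)

#' @rdname HGTRecords-class
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname HGTRecords-class
#' @export
setMethod("theta", "HGTRecords", function(x) x@theta)

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nTranscripts, "transcripts, foreign fraction",
      object@foreignFraction, "\n")
  cat("  taxon mix:", paste(sprintf("%s=%.2f", names(object@taxonMix),
                                    object@taxonMix), collapse = " "), "\n")
  cat(sprintf("  length ~ lognormal(%.3f, %.3f); score %g/%g bits/bp (sd %g); mn=%g\n",
              object@lengthMeanlog, object@lengthSdlog, object@bitsPerBpOwn,
              object@bitsPerBpCross, object@bitscoreSd, object@searchSpace))
  cat(sprintf("  dropout=%g support Beta(%g,%g) misleading=%g contamination=%g seed=%d\n",
              object@dropout, object@supportAlpha, object@supportBeta,
              object@misleadingRate, object@contaminationRate, object@seed))
})

setMethod("show", "HitProfiles", function(object) {
  cat("HitProfiles:", nrow(object@profiles), "transcripts retained,",
      object@excluded, "excluded (E >", format(object@epsilon), "in all taxa),",
      "top", object@topK, "hits/taxon\n")
})

setMethod("show", "HGTRecords", function(object) {
  tab <- table(factor(object@records$category,
                      levels = c("metazoan", "indeterminate", "foreign")))
  cat(sprintf("HGTRecords (h_%s, theta = %g): %d transcripts\n",
              object@databaseTag, object@theta, nrow(object@records)))
  cat(sprintf("  metazoan %d | indeterminate %d | foreign %d (%.1f%%)\n",
              tab[1], tab[2], tab[3], 100 * tab[3] / max(1, nrow(object@records))))
})
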