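#' Canonical taxon labels
#'
#' The six database partitions a taxon-partitioned homology search is split
#' into. \code{hgtTaxa()} returns all six; \code{nonMetazoanTaxa()} the five
#' non-metazoan ones. All per-taxon columns and parameters in the package use
#' this vocabulary and ordering (the ordering is also the documented final
#' tie-break for source-taxon attribution).
#'
#' @return Character vector of taxon labels.
#' @export
hgtTaxa <- function() {
  c("Metazoa", "Eubacteria", "Archaea", "Fungi", "Plantae", "OtherEukaryotes")
}

#' @rdname hgtTaxa
#' @export
nonMetazoanTaxa <- function() setdiff(hgtTaxa(), "Metazoa")

# Accepted spellings on input -> canonical form. "Archea" appears in the wild.
.taxonSynonyms <- c(
  "metazoa" = "Metazoa",
  "eubacteria" = "Eubacteria", "bacteria" = "Eubacteria",
  "archaea" = "Archaea", "archea" = "Archaea",
  "fungi" = "Fungi",
  "plantae" = "Plantae", "plants" = "Plantae", "viridiplantae" = "Plantae",
  "othereukaryotes" = "OtherEukaryotes", "other eukaryotes" = "OtherEukaryotes",
  "other_eukaryotes" = "OtherEukaryotes", "other-eukaryotes" = "OtherEukaryotes"
)

#' Normalise taxon labels to the canonical six-label vocabulary
#'
#' @param x character vector of taxon labels (case-insensitive; common
#'   variants such as \code{"Archea"} or \code{"Other Eukaryotes"} accepted).
#' @return character vector of canonical labels.
#' @export
normalizeTaxon <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- .taxonSynonyms[key]
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unknown taxon label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected one of: ", paste(hgtTaxa(), collapse = ", "), ")")
  }
  unname(out)
}

# stopifnot with nicer messages
.check <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

.isProb <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Open a (possibly gzip-compressed) text file for reading. gzfile() reads
# plain text transparently, so it is used unconditionally.
.openText <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  gzfile(path, open = "rt")
}

#' Validate Enzyme Commission number syntax
#'
#' An EC number has four dot-separated fields; each field is an integer or a
#' trailing dash (incomplete classification). Partial codes with dashes are
#' legal but kept distinct from complete codes.
#'
#' @param ec character vector.
#' @return logical vector.
#' @export
isValidEC <- function(ec) {
  grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", ec)
}
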