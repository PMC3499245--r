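.hitColumns <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column tabular homology hit file
#'
#' Reads the de-facto tabular output of local-alignment search tools
#' (\code{qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore}), optionally with a 13th taxon column. Query coordinates
#' are normalised ascending; subject coordinates are kept as given (minus
#' strand encoded by sstart > send). Gzip-compressed files are accepted.
#'
#' @param path file path (plain or .gz).
#' @param taxon single taxon label applied to every row (for per-taxon files);
#'   ignored when a 13th column is present.
#' @return data.frame of hits with canonical \code{taxon} labels.
#' @export
readHits <- function(path, taxon = NULL) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty hit file: ", path)
    out <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = numeric(),
                      mismatch = numeric(), gapopen = numeric(),
                      qstart = numeric(), qend = numeric(),
                      sstart = numeric(), send = numeric(),
                      evalue = numeric(), bitscore = numeric(),
                      taxon = character(), stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- if (any(nf == 13L)) 13L else 12L
  bad <- which(nf != expected)
  if (length(bad)) {
    stop("malformed hit file ", path, ": expected ", expected,
         " tab-separated columns but found ", nf[bad[1]],
         " at line ", bad[1])
  }
  m <- do.call(rbind, fields)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  numCols <- c(pident = 3, length = 4, mismatch = 5, gapopen = 6, qstart = 7,
               qend = 8, sstart = 9, send = 10, evalue = 11, bitscore = 12)
  for (nm in names(numCols)) {
    v <- suppressWarnings(as.numeric(m[, numCols[[nm]]]))
    if (anyNA(v)) {
      stop("unparseable numeric in column '", nm, "' of ", path,
           " at line ", which(is.na(v))[1])
    }
    out[[nm]] <- v
  }
  out$taxon <- if (expected == 13L) normalizeTaxon(m[, 13]) else {
    if (is.null(taxon)) stop("no taxon column in ", path,
                             " and no 'taxon' argument supplied")
    normalizeTaxon(taxon)
  }
  if (any(out$evalue < 0)) stop("negative E-value in ", path)
  if (any(out$bitscore <= 0)) stop("non-positive bitscore in ", path)
  flip <- out$qstart > out$qend
  if (any(flip)) {
    tmp <- out$qstart[flip]
    out$qstart[flip] <- out$qend[flip]
    out$qend[flip] <- tmp
  }
  out
}

#' Write a hit table in 12(+1)-column tabular format
#'
#' @param hits data.frame as produced by \code{\link{readHits}} or
#'   \code{\link{simulateHitTable}}.
#' @param path output path (".gz" suffix triggers compression).
#' @param taxonColumn write the 13th taxon column (default TRUE when present).
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(hits, path, taxonColumn = "taxon" %in% names(hits)) {
  cols <- .hitColumns
  if (taxonColumn) cols <- c(cols, "taxon")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(format(hits[cols], scientific = TRUE, trim = TRUE,
                            digits = 6),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript lengths from a FASTA file
#'
#' @param path FASTA path (plain or gzip).
#' @return named integer vector of sequence lengths (bp).
#' @export
readTranscriptLengths <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  Biostrings::fasta.seqlengths(path)
}

# default column-name mapping for supplementary-style summary tables; the
# dialect is a named list overriding any of these patterns.
.summaryDialect <- function(dialect = list()) {
  d <- list(
    id = c("transcript", "transcript_id", "contig", "name", "transcript name"),
    length = c("sequence_length", "length", "sequence length"),
    evaluePrefix = "min_evalue_",   # per-taxon: min_evalue_<Taxon>
    bitscorePrefix = "max_bitscore_",
    supportPrefix = "support_",       # monophyly support of each taxon
    focalSupportPrefix = "focal_support_", # support of transcript with taxon
    h = c("h", "hgt_index", "h_u", "h_s"),
    alien = c("alien_index", "ai"),
    classification = c("classification", "phylogenetic_classification", "group")
  )
  d[names(dialect)] <- dialect
  d
}

#' Read a supplementary-style per-transcript summary table
#'
#' Parses TSV/CSV exports of per-transcript summary tables carrying, per taxon,
#' a minimum E-value and a maximum bitscore column, and optionally per-taxon
#' monophyly supports, a recorded index, alien index and classification.
#' Absent cells (empty, "NA", "-") become "no hit" (\code{NA}); E-value
#' underflow strings ("0") are preserved as 0.
#'
#' @param path TSV (default) or CSV file, optionally gzipped.
#' @param dialect named list overriding the default column-name mapping; see
#'   source of \code{HGTscan:::.summaryDialect} for the recognised keys.
#' @param sep field separator (default tab).
#' @return data.frame with columns \code{transcript_id}, \code{length},
#'   \code{E_<taxon>}, \code{S_<taxon>}, and when present
#'   \code{support_<taxon>}, \code{focal_support_<taxon>}, \code{h},
#'   \code{alien_index}, \code{classification}.
#' @export
readSummaryTable <- function(path, dialect = list(), sep = "\t") {
  d <- .summaryDialect(dialect)
  con <- .openText(path)
  on.exit(close(con))
  raw <- utils::read.table(con, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "-", "na"))
  nm <- tolower(names(raw))
  pick <- function(cands) {
    i <- match(tolower(cands), nm)
    i <- i[!is.na(i)]
    if (length(i)) i[1] else NA_integer_
  }
  idCol <- pick(d$id); lenCol <- pick(d$length)
  if (is.na(idCol) || is.na(lenCol)) {
    stop("summary table ", path, " lacks mandatory columns; expected an id ",
         "column (one of: ", paste(d$id, collapse = ", "), ") and a length ",
         "column (one of: ", paste(d$length, collapse = ", "), ")")
  }
  out <- data.frame(transcript_id = as.character(raw[[idCol]]),
                    length = as.numeric(raw[[lenCol]]),
                    stringsAsFactors = FALSE)
  grab <- function(prefix, target) {
    for (tx in hgtTaxa()) {
      j <- pick(paste0(prefix, c(tx, tolower(tx),
                                 if (tx == "Archaea") "Archea",
                                 if (tx == "OtherEukaryotes") "Other Eukaryotes")))
      if (!is.na(j)) out[[paste0(target, tx)]] <<- as.numeric(raw[[j]])
    }
  }
  grab(d$evaluePrefix, "E_")
  grab(d$bitscorePrefix, "S_")
  grab(d$supportPrefix, "support_")
  grab(d$focalSupportPrefix, "focal_support_")
  eCols <- grep("^E_", names(out)); sCols <- grep("^S_", names(out))
  if (!length(eCols) || !length(sCols)) {
    stop("summary table ", path, " has no per-taxon E-value/bitscore columns ",
         "(expected headers like '", d$evaluePrefix, "Metazoa' and '",
         d$bitscorePrefix, "Metazoa'; pass a dialect to remap)")
  }
  j <- pick(d$h); if (!is.na(j)) out$h <- as.numeric(raw[[j]])
  j <- pick(d$alien); if (!is.na(j)) out$alien_index <- as.numeric(raw[[j]])
  j <- pick(d$classification)
  if (!is.na(j)) out$classification <- as.character(raw[[j]])
  supCols <- grep("^(focal_)?support_", names(out), value = TRUE)
  for (sc in supCols) {
    v <- out[[sc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("supports outside [0,1] in column ", sc, " of ", path)
    }
  }
  # retain only rows with at least one taxon pair present
  keep <- rowSums(!is.na(out[eCols])) + rowSums(!is.na(out[sCols])) > 0
  out[keep, , drop = FALSE]
}

#' Read a Newick tree with branch supports
#'
#' Supports are taken from internal-node labels (the convention of
#' likelihood-based tree builders that attach approximate likelihood-ratio or
#' bootstrap supports). Unlabelled internal nodes get \code{NA} ("absent"),
#' distinct from support 0.
#'
#' @param path Newick file (plain or gzip); may contain several trees.
#' @return an \code{ape::phylo} (or \code{multiPhylo} when the file holds
#'   several trees) whose \code{node.label} is numeric-coercible; supports are
#'   also attached as the numeric attribute \code{"supports"}.
#' @export
readNewickSupports <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  txt <- paste(readLines(con), collapse = "\n")
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  annotate <- function(tr) {
    sup <- if (is.null(tr$node.label)) rep(NA_real_, tr$Nnode) else
      suppressWarnings(as.numeric(tr$node.label))
    attr(tr, "supports") <- sup
    tr
  }
  if (inherits(tree, "multiPhylo")) {
    tree[] <- lapply(tree, annotate)
    tree
  } else annotate(tree)
}

#' Write a support-annotated tree to Newick
#'
#' @param tree \code{ape::phylo}; node labels are written as supports.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewickSupports <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a pathway-to-EC map
#'
#' @param path TSV with three columns: pathway id, pathway display name, EC
#'   number (header optional, detected from the first line).
#' @return data.frame with \code{pathway_id}, \code{pathway_name}, \code{ec};
#'   duplicate (pathway, ec) rows collapsed; EC syntax validated.
#' @export
readPathwayMap <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  hasHeader <- grepl("pathway", tolower(first))
  close(con); on.exit()
  con <- .openText(path)
  on.exit(close(con))
  raw <- utils::read.table(con, header = hasHeader, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  names(raw)[1:min(3L, ncol(raw))] <-
    c("pathway_id", "pathway_name", "ec")[seq_len(min(3L, ncol(raw)))]
  .check(ncol(raw) >= 3L, "pathway map must have 3 columns (id, name, ec): ", path)
  bad <- !isValidEC(raw$ec)
  if (any(bad)) {
    stop("malformed EC number(s) in ", path, ": ",
         paste(utils::head(unique(raw$ec[bad]), 5), collapse = ", "))
  }
  out <- unique(raw[c("pathway_id", "pathway_name", "ec")])
  rownames(out) <- NULL
  out
}

#' Write a pathway map, TSV
#' @param map data.frame as from \code{\link{readPathwayMap}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePathwayMap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
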