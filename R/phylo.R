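#' Trim an alignment to columns supported by more than one sequence
#'
#' Removes columns where at most one sequence has a residue (regions present
#' in only one sequence carry no phylogenetic signal); relative column order
#' is preserved. Gap characters are '-' and '.'.
#'
#' @param aln character vector of equal-length aligned sequences (named), or a
#'   \code{Biostrings::AAStringSet}/\code{DNAStringSet}.
#' @return object of the same kind with the offending columns removed.
#' @export
trimAlignment <- function(aln) {
  isXSS <- inherits(aln, "XStringSet")
  seqs <- if (isXSS) as.character(aln) else aln
  .check(length(seqs) >= 2L, "alignment needs at least two sequences")
  .check(length(unique(nchar(seqs))) == 1L, "sequences must be aligned (equal length)")
  m <- do.call(rbind, strsplit(seqs, ""))
  nonGap <- colSums(m != "-" & m != ".")
  keep <- nonGap > 1L
  if (!any(keep)) stop("degenerate alignment: no column has more than one residue")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(seqs)
  if (isXSS) {
    cls <- if (inherits(aln, "AAStringSet")) Biostrings::AAStringSet
           else Biostrings::DNAStringSet
    out <- cls(out)
    names(out) <- names(aln)
  }
  out
}

# fraction of mismatching positions among columns where both sequences have a
# residue; 1 (max distance) when there is no comparable column.
.pairwiseDistance <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-" | m == "."
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      D[i, j] <- D[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 1
    }
  }
  D
}

#' Build a support-annotated tree from an alignment (test stand-in)
#'
#' A lightweight distance tree for exercising the downstream monophyly
#' classification on synthetic data: neighbour joining on pairwise mismatch
#' distances, with bootstrap proportions (column resampling) as internal-edge
#' supports in [0, 1]. This is a deliberately simple builder for simulation
#' tests, not a maximum-likelihood method, and carries no model of sequence
#' evolution.
#'
#' @param aln aligned sequences (character vector or \code{XStringSet}),
#'   at least 4.
#' @param bootstrapN bootstrap replicates (default 100; 0 means no supports).
#' @param seed RNG seed for the resampling.
#' @return \code{ape::phylo} with \code{node.label} holding supports (empty
#'   root label; \code{NULL} when \code{bootstrapN} = 0).
#' @export
buildSupportTree <- function(aln, bootstrapN = 100L, seed = 1L) {
  seqs <- if (inherits(aln, "XStringSet")) as.character(aln) else aln
  if (length(seqs) < 4L) {
    stop("too few sequences to build a meaningful tree (need >= 4, got ",
         length(seqs), ")")
  }
  .check(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
         "sequences must have unique names")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  njFromMatrix <- function(mm) ape::nj(.pairwiseDistance(mm))
  tree <- njFromMatrix(m)
  if (bootstrapN > 0L) {
    bp <- .withSeed(seed,
      ape::boot.phylo(tree, m, njFromMatrix, B = as.integer(bootstrapN),
                      quiet = TRUE))
    tree$node.label <- round(bp / bootstrapN, 3)
  }
  tree
}

#' Taxon of each leaf from a label pattern
#'
#' Default labelling convention: the leaf label starts with the taxon name
#' followed by an underscore (as produced by \code{\link{simulateTrees}}).
#'
#' @param labels character vector of leaf labels.
#' @param focal label of the focal transcript (assigned \code{NA} taxon).
#' @param pattern regular expression with one capture group extracting the
#'   taxon from a label.
#' @return named character vector label -> canonical taxon (\code{NA} for the
#'   focal leaf and labels that do not match).
#' @export
leafTaxa <- function(labels, focal = NULL, pattern = "^([A-Za-z]+)_") {
  tax <- rep(NA_character_, length(labels))
  mm <- regmatches(labels, regexec(pattern, labels))
  raw <- vapply(mm, function(x) if (length(x) >= 2L) x[2] else NA_character_,
                character(1))
  known <- !is.na(raw) & tolower(raw) %in% names(.taxonSynonyms)
  tax[known] <- normalizeTaxon(raw[known])
  if (!is.null(focal)) tax[labels == focal] <- NA_character_
  stats::setNames(tax, labels)
}

# Enumerate the (side, support) pairs defined by the internal edges of a tree
# read in rooted form. For each supported internal node, the clade side (its
# descendant tips) carries the node's support; the complement side carries
# the same support, except for the children of a binary root: there the two
# root edges are the same unrooted edge but carry separate annotations, and
# each annotation applies to its own clade side only (so conflicting labels
# on the two root children stay distinct).
.edgeSides <- function(tree) {
  nt <- length(tree$tip.label)
  sup <- if (is.null(tree$node.label)) rep(NA_real_, tree$Nnode) else
    suppressWarnings(as.numeric(tree$node.label))
  root <- nt + 1L
  tipsUnder <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) tipsUnder[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    par <- eo[k, 1]; ch <- eo[k, 2]
    tipsUnder[[par]] <- c(tipsUnder[[par]], tipsUnder[[ch]])
  }
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rootDegree <- sum(tree$edge[, 1] == root)
  out <- list()
  if (tree$Nnode < 2L && rootDegree <= 2L) return(out)  # star/cherry: no internal edges
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    if (node == root) next  # the root itself is not an edge
    side <- tipsUnder[[node]]
    if (length(side) < 1L || length(side) >= nt) next
    s <- sup[node - nt]
    out[[length(out) + 1L]] <- list(side = side, support = s)
    if (!(parent[node] == root && rootDegree == 2L)) {
      out[[length(out) + 1L]] <- list(side = setdiff(tree$tip.label, side),
                                      support = s)
    }
  }
  out
}

#' Extract per-taxon monophyly supports for a focal transcript
#'
#' Works on the bipartitions of the unrooted tree. For each taxon present,
#' reports (a) the support of the best edge whose one side contains exactly
#' that taxon's leaves (taxon monophyly) and (b) the support of the best edge
#' whose one side contains exactly the focal leaf plus that taxon's leaves
#' (focal-with-taxon monophyly); \code{NA} ("absent") when no such edge
#' exists or the edge carries no support. Also reports the best-supported
#' edge separating the focal leaf from all metazoan leaves, and the leaf and
#' taxon counts the group assignment needs.
#'
#' @param tree \code{ape::phylo} with supports as node labels (see
#'   \code{\link{readNewickSupports}}).
#' @param focal label of the focal leaf.
#' @param taxa named character vector leaf -> taxon (see
#'   \code{\link{leafTaxa}}); leaves other than the focal must have a taxon.
#' @return list of class \code{"phylo_assessment"}: \code{transcript_id},
#'   \code{taxon_support} (named numeric), \code{focal_support} (named
#'   numeric), \code{separation_from_metazoa} (numeric), \code{n_nonfocal_leaves},
#'   \code{n_taxa_present}, \code{taxa_present}, \code{only_metazoan}.
#' @export
extractMonophylySupports <- function(tree, focal, taxa = NULL) {
  .check(focal %in% tree$tip.label, "focal leaf '", focal, "' not in tree")
  if (is.null(taxa)) taxa <- leafTaxa(tree$tip.label, focal = focal)
  nonfocal <- setdiff(tree$tip.label, focal)
  .check(all(!is.na(taxa[nonfocal])),
         "every non-focal leaf must have a taxon")
  taxaPresent <- sort(unique(unname(taxa[nonfocal])))
  leavesOf <- split(nonfocal, taxa[nonfocal])

  edges <- .edgeSides(tree)
  sameSet <- function(a, b) length(a) == length(b) && setequal(a, b)
  better <- function(new, old) {
    if (is.na(old)) return(TRUE)
    !is.na(new) && new > old
  }

  taxSup <- focSup <- stats::setNames(rep(NA_real_, length(taxaPresent)),
                                      taxaPresent)
  sepMet <- NA_real_
  metLeaves <- leavesOf[["Metazoa"]]
  for (e in edges) {
    side <- e$side
    for (tx in taxaPresent) {
      if (sameSet(side, leavesOf[[tx]]) && better(e$support, taxSup[tx]))
        taxSup[tx] <- e$support
      if (sameSet(side, c(focal, leavesOf[[tx]])) && better(e$support, focSup[tx]))
        focSup[tx] <- e$support
    }
    if (!is.null(metLeaves) && length(metLeaves) &&
        focal %in% side && !any(metLeaves %in% side) &&
        better(e$support, sepMet)) {
      sepMet <- e$support
    }
  }
  out <- list(transcript_id = focal,
              taxon_support = taxSup,
              focal_support = focSup,
              separation_from_metazoa = sepMet,
              n_nonfocal_leaves = length(nonfocal),
              n_taxa_present = length(taxaPresent),
              taxa_present = taxaPresent,
              only_metazoan = identical(taxaPresent, "Metazoa"))
  class(out) <- "phylo_assessment"
  out
}

#' Assign a transcript to one of the five phylogenetic groups
#'
#' Mutually exclusive verdicts on a foreign call, evaluated in precedence
#' order 1, 3, 5, 4, 2:
#' \describe{
#'   \item{1}{monophyletic with Metazoa: only metazoan hits, or
#'     focal-with-Metazoa support >= \code{sMin};}
#'   \item{3}{too few sequences: fewer than \code{minNonfocal} non-focal
#'     leaves, or fewer than two taxa present;}
#'   \item{5}{monophyletic with a single non-metazoan taxon at support >=
#'     \code{sMin};}
#'   \item{4}{monophyly with Metazoa strongly rejected: an edge with support
#'     >= \code{sMin} separates the focal leaf from all metazoan leaves;}
#'   \item{2}{otherwise (monophyly with Metazoa cannot be strongly rejected).}
#' }
#' Absent supports (\code{NA}) never satisfy a \code{>= sMin} test.
#'
#' @param assessment a \code{phylo_assessment} from
#'   \code{\link{extractMonophylySupports}}, or a list with the same fields.
#' @param sMin support threshold for "strong" statements (default 0.75).
#' @param minNonfocal minimum non-focal leaves for a meaningful clade
#'   (default 3).
#' @return integer group in 1..5.
#' @export
assignGroup <- function(assessment, sMin = 0.75, minNonfocal = 3L) {
  a <- assessment
  geq <- function(x) !is.na(x) && x >= sMin
  sup <- function(v, nm) if (nm %in% names(v)) v[[nm]] else NA_real_
  if (isTRUE(a$only_metazoan)) return(1L)
  if (geq(sup(a$focal_support, "Metazoa"))) return(1L)
  if (a$n_nonfocal_leaves < minNonfocal || a$n_taxa_present < 2L) return(3L)
  nonmetPresent <- setdiff(a$taxa_present, "Metazoa")
  withTaxon <- nonmetPresent[vapply(nonmetPresent, function(tx)
    geq(sup(a$focal_support, tx)), logical(1))]
  if (length(withTaxon) == 1L) return(5L)
  if ("Metazoa" %in% a$taxa_present && geq(a$separation_from_metazoa)) return(4L)
  2L
}

#' Classify a set of trees
#'
#' Runs \code{\link{extractMonophylySupports}} and \code{\link{assignGroup}}
#' over a list of trees, one focal transcript per tree.
#'
#' @param trees named list of \code{ape::phylo} (names = focal leaf labels),
#'   e.g. from \code{\link{simulateTrees}} or \code{\link{readNewickSupports}}.
#' @param sMin,minNonfocal see \code{\link{assignGroup}}.
#' @param taxaFun function(labels, focal) -> named taxon vector (default
#'   \code{\link{leafTaxa}}); to run a nematode-inclusive style re-analysis,
#'   supply a function mapping the extra leaves to Metazoa.
#' @return data.frame with \code{transcript_id}, \code{group},
#'   \code{best_taxon_support} columns plus per-taxon focal supports.
#' @export
classifyTrees <- function(trees, sMin = 0.75, minNonfocal = 3L,
                          taxaFun = leafTaxa) {
  .check(length(trees) == 0 || !is.null(names(trees)),
         "trees must be a named list (names = focal leaves)")
  rows <- lapply(names(trees), function(id) {
    tr <- trees[[id]]
    a <- extractMonophylySupports(tr, focal = id,
                                  taxa = taxaFun(tr$tip.label, id))
    g <- assignGroup(a, sMin = sMin, minNonfocal = minNonfocal)
    fs <- a$focal_support
    best <- if (all(is.na(fs))) NA_real_ else max(fs, na.rm = TRUE)
    row <- data.frame(transcript_id = id, group = g,
                      best_taxon_support = best, stringsAsFactors = FALSE)
    for (tx in hgtTaxa()) {
      row[[paste0("focal_support_", tx)]] <-
        if (tx %in% names(fs)) fs[[tx]] else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), group = integer(),
                      best_taxon_support = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarise group assignments
#'
#' Counts and percentages per group, plus the "verified foreign" tally:
#' groups 4 and 5 among the trees, together with the transcripts that never
#' entered phylogenetics because they had no significant metazoan hit.
#'
#' @param assessments data.frame from \code{\link{classifyTrees}} (or any
#'   data.frame with a \code{group} column), or an integer vector of groups.
#' @param nNoMetazoan number of foreign transcripts with no significant
#'   metazoan hit (counted as verified without a tree).
#' @return list with \code{table} (data.frame: group, count, pct),
#'   \code{verified} (count), \code{total} (foreign total), and
#'   \code{verification_rate}.
#' @export
summarizeGroups <- function(assessments, nNoMetazoan = 0L) {
  groups <- if (is.data.frame(assessments)) assessments$group else assessments
  tab <- table(factor(groups, levels = 1:5))
  n <- length(groups)
  df <- data.frame(group = 1:5, count = as.integer(tab),
                   pct = if (n) round(100 * as.integer(tab) / n, 1) else 0)
  verified <- sum(tab[c("4", "5")]) + nNoMetazoan
  total <- n + nNoMetazoan
  list(table = df, verified = as.integer(verified), total = as.integer(total),
       verification_rate = if (total) verified / total else NA_real_,
       tree_rate_45 = if (n) sum(tab[c("4", "5")]) / n else NA_real_)
}

#' Calibrate the support threshold against recorded classifications
#'
#' Fits \code{sMin} by maximising agreement between \code{\link{assignGroup}}
#' verdicts and a supplied classification column (as recorded in a summary
#' table), over a grid of candidate thresholds.
#'
#' @param assessments list of \code{phylo_assessment} objects.
#' @param recorded integer vector of recorded groups (same order).
#' @param grid candidate thresholds (default seq(0.5, 0.99, 0.01)).
#' @param minNonfocal passed to \code{\link{assignGroup}}.
#' @return list with \code{sMin} (best threshold; smallest in case of ties)
#'   and \code{agreement} (data.frame grid vs agreement rate).
#' @export
calibrateSupportThreshold <- function(assessments, recorded,
                                      grid = seq(0.5, 0.99, by = 0.01),
                                      minNonfocal = 3L) {
  .check(length(assessments) == length(recorded),
         "assessments and recorded must have equal length")
  agree <- vapply(grid, function(s) {
    g <- vapply(assessments, assignGroup, integer(1), sMin = s,
                minNonfocal = minNonfocal)
    mean(g == recorded)
  }, numeric(1))
  list(sMin = grid[which.max(agree)],
       agreement = data.frame(sMin = grid, agreement = agree))
}
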