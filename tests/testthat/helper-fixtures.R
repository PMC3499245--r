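# Shared fixture builders. Everything is constructed in code; no data files.

# one-row (or multi-row) profiles data.frame from named per-taxon score and
# E-value lists; absent taxa are NA.
makeProfile <- function(S = list(), E = list(), id = "t1", length = 300) {
  prof <- data.frame(transcript_id = id, length = length,
                     stringsAsFactors = FALSE)
  for (tx in hgtTaxa()) {
    prof[[paste0("S_", tx)]] <- if (tx %in% names(S)) S[[tx]] else NA_real_
    prof[[paste0("E_", tx)]] <- if (tx %in% names(E)) E[[tx]] else {
      # default: an E-value consistent with the bitscore when a score exists
      if (tx %in% names(S)) 2^(-S[[tx]]) * 1e9 else NA_real_
    }
  }
  prof
}

# minimal hit table row
makeHit <- function(qseqid, taxon, bitscore, evalue = 1e9 * 2^(-bitscore),
                    sseqid = "subj1", qstart = 1, qend = 100,
                    sstart = 1, send = 100, len = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = 80, length = len,
             mismatch = 5, gapopen = 0, qstart = qstart, qend = qend,
             sstart = sstart, send = send, evalue = evalue,
             bitscore = bitscore, taxon = taxon, stringsAsFactors = FALSE)
}

# genome match row in the 12-column shape selectAlignmentChain expects
makeMatch <- function(qseqid, sseqid, qstart, qend, sstart, send,
                      evalue = 1e-6, bitscore = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = 99,
             length = abs(qend - qstart) + 1, mismatch = 0, gapopen = 0,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

# independent brute-force re-implementation of the four chaining rules,
# written as a plain sequential filter (the oracle for selectAlignmentChain)
oracleChain <- function(matches, transcriptLength, contigLengths,
                        epsilon = 1e-3, minLen = 40, endDist = 1000) {
  ord <- order(-matches$bitscore, matches$evalue,
               pmin(matches$qstart, matches$qend))
  matches <- matches[ord, , drop = FALSE]
  accepted <- list()
  nearEnd <- function(m) {
    L <- contigLengths[[m$sseqid]]
    lo <- min(m$sstart, m$send); hi <- max(m$sstart, m$send)
    min(lo - 1, L - hi) <= endDist
  }
  for (r in seq_len(nrow(matches))) {
    m <- matches[r, ]
    if (m$evalue > epsilon) next
    if (!(m$length > minLen)) next
    q1 <- min(m$qstart, m$qend); q2 <- max(m$qstart, m$qend)
    overlaps <- FALSE
    for (a in accepted) {
      a1 <- min(a$qstart, a$qend); a2 <- max(a$qstart, a$qend)
      if (q1 <= a2 && q2 >= a1) { overlaps <- TRUE; break }
    }
    if (overlaps) next
    if (length(accepted)) {
      sameCtg <- any(vapply(accepted, function(a) a$sseqid == m$sseqid,
                            logical(1)))
      endOK <- nearEnd(m) && any(vapply(accepted, nearEnd, logical(1)))
      if (!sameCtg && !endOK) next
    }
    accepted[[length(accepted) + 1L]] <- m
  }
  covered <- sum(vapply(accepted, function(a)
    abs(a$qend - a$qstart) + 1, numeric(1)))
  list(accepted = accepted, covered_bp = covered,
       coverage = covered / transcriptLength)
}

# independent exhaustive bipartition scan for small trees: walks the edge
# list directly (no reliance on the package's postorder accumulation) and
# applies the same annotation convention: each supported internal node's
# clade side gets its label; the complement too, except for children of a
# binary root.
oracleMonophyly <- function(tree, focal, taxa) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  below <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  sup <- suppressWarnings(as.numeric(tree$node.label))
  rootDeg <- sum(tree$edge[, 1] == root)
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  sides <- list()
  for (node in setdiff((nt + 1L):(nt + tree$Nnode), root)) {
    cl <- below(node)
    if (length(cl) >= nt) next
    s <- sup[node - nt]
    sides[[length(sides) + 1L]] <- list(side = cl, support = s)
    if (!(parent[node] == root && rootDeg == 2L)) {
      sides[[length(sides) + 1L]] <- list(side = setdiff(tree$tip.label, cl),
                                          support = s)
    }
  }
  nonfocal <- setdiff(tree$tip.label, focal)
  taxaPresent <- sort(unique(unname(taxa[nonfocal])))
  best <- function(target) {
    out <- NA_real_
    for (e in sides) {
      if (setequal(e$side, target)) {
        if (is.na(out) || (!is.na(e$support) && e$support > out)) out <- e$support
      }
    }
    out
  }
  list(
    taxon = vapply(taxaPresent, function(tx)
      best(nonfocal[taxa[nonfocal] == tx]), numeric(1)),
    focal = vapply(taxaPresent, function(tx)
      best(c(focal, nonfocal[taxa[nonfocal] == tx])), numeric(1))
  )
}

# exact hypergeometric upper tail by direct enumeration of the tail sum
oracleHyper <- function(k, N, K, n) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# classical step-up BH adjustment
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
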