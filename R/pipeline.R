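.defaultConfig <- function() {
  list(
    theta = 30,          # foreignness threshold on h (bits)
    epsilon1 = 1e-5,     # matched-set / significance E-value ceiling
    epsilon2 = 1e-3,     # genome-alignment E-value ceiling
    sMin = 0.75,         # strong-support threshold for monophyly statements
    lMin = 40,           # minimum exon length (bp, strict)
    dEnd = 1000,         # contig-end distance for split genes (bp)
    topK = 5,            # hits retained per transcript and taxon
    seed = 1L,
    outDir = NULL,       # when set, stage outputs are written as TSV
    stages = c("index", "curves", "classify", "linkage", "pathways")
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Injects defaults, rejects unknown keys (with a nearest-match suggestion)
#' and checks every threshold's domain.
#'
#' @param config named list of overrides, or a path to a YAML file with the
#'   same keys.
#' @return the normalised configuration list.
#' @examples
#' cfg <- validateConfig(list(theta = 25))
#' cfg$theta
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  .check(is.list(config), "config must be a list or a YAML path")
  defaults <- .defaultConfig()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    hint <- vapply(unknown, function(u) {
      cand <- agrep(u, names(defaults), max.distance = 0.3, value = TRUE)
      if (length(cand)) paste0(" (did you mean '", cand[1], "'?)") else ""
    }, character(1))
    stop("unknown config key(s): ",
         paste0(unknown, hint, collapse = ", "))
  }
  cfg <- defaults
  cfg[names(config)] <- config
  num <- function(key) {
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    .check(length(v) == 1L && is.finite(v), "config key '", key,
           "' must be a single finite number")
    v
  }
  .check(num("theta") > 0, "theta must be > 0")
  for (k in c("epsilon1", "epsilon2")) {
    v <- num(k)
    .check(v > 0 && v <= 1, k, " must lie in (0, 1]")
    cfg[[k]] <- v
  }
  .check(num("sMin") > 0 && num("sMin") <= 1, "sMin must lie in (0, 1]")
  .check(num("lMin") > 0, "lMin must be > 0")
  .check(num("dEnd") >= 0, "dEnd must be >= 0")
  .check(num("topK") >= 1, "topK must be >= 1")
  cfg$theta <- num("theta"); cfg$sMin <- num("sMin")
  cfg$lMin <- num("lMin"); cfg$dEnd <- num("dEnd")
  cfg$topK <- as.integer(num("topK")); cfg$seed <- as.integer(num("seed"))
  .check(all(cfg$stages %in% .defaultConfig()$stages),
         "unknown stage name(s): ",
         paste(setdiff(cfg$stages, .defaultConfig()$stages), collapse = ", "))
  cfg
}

# write a stage output TSV with a traceability header block
.writeStage <- function(df, cfg, name) {
  if (is.null(cfg$outDir)) return(invisible(NULL))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$outDir, paste0(name, ".tsv"))
  if (file.exists(path)) {
    stop("refusing to overwrite existing stage output: ", path)
  }
  hash <- substr(.configHash(cfg), 1, 12)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# HGTscan ", as.character(utils::packageVersion("HGTscan"))),
    paste0("# stage: ", name),
    paste0("# config: ", hash, "  seed: ", cfg$seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.configHash <- function(cfg) {
  cfg$outDir <- NULL
  flat <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small deterministic polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (byte in utf8ToInt(flat)) h <- (h * 31 + byte) %% 2147483647
  sprintf("%08x", h)
}

#' Run the end-to-end analysis on synthetic data
#'
#' Orchestrates every stage on ground-truthed synthetic inputs: hit-table
#' generation, profile building and HGT records, the cumulative index curve,
#' tree classification of foreign transcripts, genome-linkage coverage and
#' co-localisation, and pathway enrichment with spiked pathways. Stage
#' toggles, thresholds and the seed come from the configuration; with
#' \code{outDir} set, every stage writes a TSV stamped with the package
#' version, a configuration hash and the seed. The returned report collates
#' the headline numbers, each traceable to a stage output.
#'
#' @param config see \code{\link{validateConfig}}.
#' @param params a \code{\link{SimParams-class}}; defaults to
#'   \code{simParams(seed = config$seed)}.
#' @param spike pathway ids to spike for the enrichment stage (default the
#'   first two synthetic pathways).
#' @return list with per-stage results (\code{truth}, \code{profiles},
#'   \code{records}, \code{summary}, \code{curve}, \code{groups},
#'   \code{coverage}, \code{colocalization}, \code{pathways}) and
#'   \code{report}, a named numeric vector of headline values.
#' @examples
#' \donttest{
#' res <- runPipeline(list(seed = 7), params = simParams(nTranscripts = 300,
#'                                                       seed = 7))
#' res$report
#' }
#' @export
runPipeline <- function(config = list(), params = NULL, spike = NULL) {
  cfg <- validateConfig(config)
  if (is.null(params)) params <- simParams(seed = cfg$seed)
  validObject(params)
  report <- c(seed = as.numeric(cfg$seed))

  sim <- simulateHitTable(params)
  out <- list(truth = sim$truth)

  prof <- buildProfiles(sim$hits, topK = cfg$topK, epsilon = cfg$epsilon1)
  rec <- hgtRecords(prof, theta = cfg$theta, databaseTag = "U")
  out$profiles <- prof
  out$records <- rec
  sm <- summarizeHGT(rec, prof)
  out$summary <- sm
  .writeStage(records(rec), cfg, "records")
  report["matched"] <- sm$matched
  report["foreign_fraction"] <- sm$foreign_fraction

  if ("curves" %in% cfg$stages) {
    cur <- survivalCurve(records(rec)$h, species = "synthetic")
    out$curve <- cur
    .writeStage(as.data.frame(cur), cfg, "curve")
    report["pct_at_theta"] <- curveAt(cur, cfg$theta)
  }

  if ("classify" %in% cfg$stages) {
    tsim <- simulateTrees(sim$truth, params)
    cls <- classifyTrees(tsim$trees, sMin = cfg$sMin)
    recs <- records(rec)
    foreignCalled <- recs$transcript_id[recs$category == "foreign"]
    treeIds <- intersect(cls$transcript_id, foreignCalled)
    noMet <- sum(recs$category == "foreign" & !recs$has_significant_metazoan)
    grp <- summarizeGroups(cls[cls$transcript_id %in% treeIds, ],
                           nNoMetazoan = noMet)
    out$trees <- tsim
    out$classifications <- cls
    out$groups <- grp
    .writeStage(cls, cfg, "classifications")
    report["verification_rate"] <- grp$verification_rate
  }

  if ("linkage" %in% cfg$stages) {
    gsim <- simulateGenome(sim$truth, params)
    lens <- stats::setNames(sim$truth$length, sim$truth$transcript_id)
    ctg <- stats::setNames(gsim$contigs$length, gsim$contigs$contig_id)
    chain <- selectAlignmentChain(gsim$alignments, lens, ctg,
                                  epsilon = cfg$epsilon2,
                                  minLen = cfg$lMin, endDist = cfg$dEnd)
    cats <- stats::setNames(records(rec)$category, records(rec)$transcript_id)
    hist <- coverageHistogram(chain$coverage, categories = cats)
    coloc <- colocalizationReport(chain$coverage, rec)
    out$genome <- gsim
    out$coverage <- chain$coverage
    out$coverage_histogram <- hist
    out$colocalization <- coloc
    .writeStage(chain$coverage, cfg, "coverage")
    report["coverage_above_50pct_foreign"] <- unname(hist$above_cut["foreign"])
    report["fraction_colocalized"] <- coloc$fraction_colocalized
  }

  if ("pathways" %in% cfg$stages) {
    pmap <- syntheticPathwayMap()
    if (is.null(spike)) spike <- unique(pmap$pathway_id)[1:2]
    esim <- simulateECAnnotations(sim$truth, pmap, spike = spike,
                                  params = params)
    colours <- colorEC(esim$calls)
    enr <- enrichPathways(colours, pmap)
    out$ec_calls <- esim$calls
    out$ec_colours <- colours
    out$pathways <- enr
    out$pathway_truth <- esim$truth
    .writeStage(enr$results, cfg, "pathways")
    report["n_enriched_q05"] <- sum(enr$results$q < 0.05)
  }

  out$report <- report
  .writeStage(data.frame(metric = names(report), value = unname(report)),
              cfg, "report")
  out
}
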