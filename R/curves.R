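#' Cumulative index curve of a dataset
#'
#' For each grid point g, the percentage of the matched set with HGT index
#' >= g (half-open "at least" convention, exact counting). Non-increasing in
#' g by construction.
#'
#' @param h numeric vector of HGT index values (one per matched transcript).
#' @param grid numeric grid of index values (default integers -200..200).
#' @param species optional label stored with the curve.
#' @return data.frame of class \code{"hgt_survival"} with columns \code{h},
#'   \code{pct} and attributes \code{species}, \code{n}.
#' @export
survivalCurve <- function(h, grid = -200:200, species = NA_character_) {
  .check(length(h) >= 1L, "survivalCurve needs at least one h value")
  .check(all(is.finite(h)), "h values must be finite")
  n <- length(h)
  # exact counting of h >= g for each grid point
  pct <- 100 * vapply(grid, function(g) sum(h >= g), numeric(1)) / n
  out <- data.frame(h = grid, pct = pct)
  attr(out, "species") <- species
  attr(out, "n") <- n
  class(out) <- c("hgt_survival", "data.frame")
  out
}

#' Ratio of two cumulative index curves
#'
#' R(h) = pct1(h) / pct2(h), the cross-species ratio statistic used to choose
#' the foreignness threshold: R is flat for h <= 0, rises as metazoan
#' transcripts drop out, and plateaus once only truly foreign transcripts
#' remain. Points where pct2(h) = 0 are undefined and reported as NA (never 0
#' or Inf). A plateau diagnostic (mean and sd of R over a window, default
#' h in [30, 100]) is attached.
#'
#' @param curve1,curve2 curves from \code{\link{survivalCurve}} on a shared
#'   grid.
#' @param window numeric length-2, the plateau window (default c(30, 100)).
#' @return data.frame of class \code{"hgt_rcurve"} with columns \code{h},
#'   \code{R}; attributes \code{plateau_mean}, \code{plateau_sd},
#'   \code{species}.
#' @export
rCurve <- function(curve1, curve2, window = c(30, 100)) {
  .check(identical(curve1$h, curve2$h), "curves must share the same grid")
  R <- ifelse(curve2$pct > 0, curve1$pct / curve2$pct, NA_real_)
  out <- data.frame(h = curve1$h, R = R)
  inWin <- out$h >= window[1] & out$h <= window[2] & !is.na(R)
  attr(out, "plateau_mean") <- if (any(inWin)) mean(R[inWin]) else NA_real_
  attr(out, "plateau_sd") <- if (sum(inWin) > 1) stats::sd(R[inWin]) else NA_real_
  attr(out, "species") <- paste(attr(curve1, "species"), "vs",
                                attr(curve2, "species"))
  class(out) <- c("hgt_rcurve", "data.frame")
  out
}

#' Evaluate a curve at given index values
#'
#' @param curve a \code{survivalCurve} or \code{rCurve} result.
#' @param at numeric values on the curve's grid.
#' @return numeric vector.
#' @export
curveAt <- function(curve, at) {
  i <- match(at, curve$h)
  .check(!anyNA(i), "requested points not on the curve grid")
  col <- if ("pct" %in% names(curve)) "pct" else "R"
  curve[[col]][i]
}

#' Logistic regression of foreignness on species and contig length
#'
#' Fits a binomial GLM of the per-transcript foreign indicator (h >= theta)
#' on species and contig length, to test whether the probability per gene of
#' being called foreign differs among taxa once length differences between
#' assemblies are controlled for. Reports Wald tests for the species
#' contrasts and each species' predicted probability over its observed length
#' range. Complete separation is detected and reported, never silently
#' ignored.
#'
#' @param data data.frame with columns \code{species}, \code{length}, and
#'   either \code{foreign} (logical) or \code{h} (converted at \code{theta}).
#' @param theta threshold used when converting \code{h} (default 30).
#' @return list with \code{model} (the glm fit), \code{coefficients} (Wald
#'   table), \code{predicted} (per-species probability range over observed
#'   lengths), \code{separation} (logical flag).
#' @export
hgtGlm <- function(data, theta = 30) {
  .check(all(c("species", "length") %in% names(data)),
         "data must have species and length columns")
  if (!"foreign" %in% names(data)) {
    .check("h" %in% names(data), "data must have a foreign or h column")
    data$foreign <- data$h >= theta
  }
  .check(length(unique(data$species)) >= 2L, "need at least two species")
  data$species <- factor(data$species)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(foreign ~ species + length, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # glm's own warning threshold misses quasi-separation with aliased
  # covariates; flag numerically degenerate fitted probabilities too
  separation <- separation ||
    any(stats::fitted(fit) < 1e-8 | stats::fitted(fit) > 1 - 1e-8)
  co <- summary(fit)$coefficients
  pred <- do.call(rbind, lapply(levels(data$species), function(sp) {
    rng <- range(data$length[data$species == sp])
    p <- stats::predict(fit, newdata = data.frame(species = sp, length = rng),
                        type = "response")
    data.frame(species = sp, length_min = rng[1], length_max = rng[2],
               p_at_min = p[1], p_at_max = p[2])
  }))
  list(model = fit, coefficients = co, predicted = pred,
       separation = separation)
}

#' Length-controlled analysis of covariance of the HGT index
#'
#' Models the signed square root of h (sign(h) * sqrt(|h|), a
#' variance-stabilising transform of the index magnitude that keeps the sign)
#' as a linear function of contig length (covariate) and species (factor).
#' Variance shares are sequential sums of squares with length entered first,
#' then species.
#'
#' @param data data.frame with columns \code{species}, \code{length}, \code{h}.
#' @return list with \code{model} (lm fit), \code{coefficients},
#'   \code{anova} (sequential ANOVA table), \code{variance_explained} (named
#'   vector: share of total variance for length, species, residual).
#' @export
hgtAncova <- function(data) {
  .check(all(c("species", "length", "h") %in% names(data)),
         "data must have species, length and h columns")
  data$species <- factor(data$species)
  resp <- sign(data$h) * sqrt(abs(data$h))
  .check(stats::var(resp) > 0, "zero-variance response")
  fit <- stats::lm(resp ~ length + species, data = data)
  av <- stats::anova(fit)
  ss <- av[["Sum Sq"]]
  share <- ss / sum(ss)
  names(share) <- rownames(av)
  list(model = fit, coefficients = summary(fit)$coefficients, anova = av,
       variance_explained = c(length = unname(share["length"]),
                              species = unname(share["species"]),
                              residual = unname(share["Residuals"])))
}

#' Write a curve to TSV
#' @param curve a curve data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCurve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
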