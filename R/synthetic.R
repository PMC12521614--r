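#' Specify a synthetic scan archetype
#'
#' Defines the ground truth for one simulated site-saturation scan: the
#' archetype (generating profile of true per-substitution means), the
#' replicate/batch design, the replicate noise level, the coupling between
#' expression and transport effects, and substitutions forced to
#' undetectable expression.
#'
#' Default transport profiles per archetype (percent of wild type):
#' \itemize{
#'   \item \code{neutral}: all true means exactly 100;
#'   \item \code{toggle}: \code{ceiling(2/3 * nSubs)} (13 of 19) at the
#'     dead floor, the rest spread over 20--120;
#'   \item \code{rheostat}: evenly spread over 0--120, populating the full
#'     accessible range including >WT outcomes;
#'   \item \code{moderate_rheostat}: non-neutral means confined to 30--49,
#'     less than half the accessible range.
#' }
#' The default expression profile is neutral (100 everywhere);
#' \code{coupling = "correlated"} ties it to the transport profile and
#' \code{coupling = "tradeoff"} inverts it (high transport, low
#' expression), both keeping expression detectable.
#'
#' @param label Archetype: \code{"neutral"}, \code{"toggle"},
#'   \code{"rheostat"} or \code{"moderate_rheostat"}.
#' @param nSubs Number of substitutions (<= 19).
#' @param position,wt Position index and wild-type residue of the simulated
#'   scan.
#' @param substrates Character vector of substrate labels for the uptake
#'   assay.
#' @param noiseCV Replicate coefficient of variation (multiplicative
#'   log-normal noise; 0 for exact values).
#' @param nReplicates Wells per construct per batch.
#' @param nBatches Independent batches (plates for uptake, blots for
#'   surface expression).
#' @param coupling Expression/transport coupling, see above.
#' @param dropout Substitutions forced to undetectable surface expression
#'   (and hence no transport).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param transportProfile,expressionProfile Optional explicit true-mean
#'   vectors (length \code{nSubs}) overriding the archetype defaults.
#' @return A list of class \code{"archetypeSpec"}.
#' @export
archetypeSpec <- function(label = c("neutral", "toggle", "rheostat",
                                    "moderate_rheostat"),
                          nSubs = 19, position = 1, wt = "G",
                          substrates = "TCA", noiseCV = 0.10,
                          nReplicates = 3, nBatches = 3,
                          coupling = c("independent", "correlated",
                                       "tradeoff"),
                          dropout = character(), seed = 1,
                          transportProfile = NULL,
                          expressionProfile = NULL) {
  label <- match.arg(label)
  coupling <- match.arg(coupling)
  stopifnot(nSubs >= 1, nSubs <= 19, noiseCV >= 0, nReplicates >= 1,
            nBatches >= 1, .isResidue(wt))
  subs <- setdiff(AA_CODES, wt)[seq_len(nSubs)]
  if (!all(dropout %in% subs))
    stop("dropout must be a subset of the generated substitutions",
         call. = FALSE)
  if (label == "neutral" && length(dropout) > floor(0.3 * nSubs))
    stop("contradictory spec: a neutral archetype cannot have that many ",
         "dropout substitutions", call. = FALSE)
  if (is.null(transportProfile)) {
    transportProfile <- switch(label,
      neutral = rep(100, nSubs),
      toggle = {
        nDead <- ceiling(2 / 3 * nSubs)
        c(rep(0, nDead), seq(20, 120, length.out = nSubs - nDead))
      },
      rheostat = seq(0, 120, length.out = nSubs),
      moderate_rheostat = seq(30, 49, length.out = nSubs))
  }
  stopifnot(length(transportProfile) == nSubs)
  if (is.null(expressionProfile)) {
    expressionProfile <- switch(coupling,
      independent = rep(100, nSubs),
      correlated = pmax(transportProfile, 2),
      tradeoff = pmax(170 - transportProfile, 10))
  }
  stopifnot(length(expressionProfile) == nSubs)
  transportProfile[subs %in% dropout] <- 0
  expressionProfile[subs %in% dropout] <- 0
  structure(list(label = label, nSubs = nSubs, subs = subs,
                 position = position, wt = wt, substrates = substrates,
                 noiseCV = noiseCV, nReplicates = nReplicates,
                 nBatches = nBatches, coupling = coupling,
                 dropout = dropout, seed = as.integer(seed),
                 transportProfile = transportProfile,
                 expressionProfile = expressionProfile),
            class = "archetypeSpec")
}

# log-normal replicate noise parameterized by CV; degenerates to the exact
# mean at cv = 0
.lnoise <- function(n, mu, cv) {
  if (cv == 0 || mu == 0) return(rep(mu, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
}

# raw-signal scale constants: wild-type net uptake signal and empty-vector
# background (arbitrary counts-per-protein units), wild-type band intensity
.S0 <- 1000
.BG <- 50
.E0 <- 100

#' Generate one synthetic position scan with ground truth
#'
#' Emits raw uptake wells (including the batch empty-vector and wild-type
#' wells the normalization path requires) and surface-biotinylation lanes
#' (two wild-type lanes per blot), runs them through the package's own
#' normalization ([normalizeUptakeWells()], [normalizeSurfaceLanes()]) and
#' assembles the resulting \linkS4class{PositionScan}.  Replicate noise is
#' multiplicative log-normal parameterized by \code{noiseCV}; empty-vector
#' background jitter makes below-background (negative net) wells possible
#' at the dead floor, exercising the background-subtraction path.
#' Generation is deterministic for a fixed spec (seeded).
#'
#' @param spec An [archetypeSpec()].
#' @return A list with elements \code{scan} (the normalized
#'   \linkS4class{PositionScan}), \code{uptakeWells},
#'   \code{surfaceLanes} (the raw tables), and \code{truth} (list with
#'   \code{means} data.frame of true per-variant means per assay and
#'   \code{intendedLabels}, the archetype labels implied by the noise-free
#'   truth for every channel).
#' @examples
#' gen <- generatePositionScan(archetypeSpec("rheostat", seed = 7))
#' scoreScan(gen$scan)
#' @export
generatePositionScan <- function(spec) {
  stopifnot(inherits(spec, "archetypeSpec"))
  set.seed(spec$seed)
  subs <- spec$subs
  tTrue <- spec$transportProfile
  eTrue <- spec$expressionProfile
  cv <- spec$noiseCV

  uptakeWells <- do.call(rbind, lapply(spec$substrates, function(subst) {
    do.call(rbind, lapply(seq_len(spec$nBatches), function(b) {
      rows <- list(
        data.frame(substrate = subst, batch = b, group = "empty_vector",
                   sub = NA_character_,
                   signal = .lnoise(spec$nReplicates, .BG, cv)),
        data.frame(substrate = subst, batch = b, group = "wildtype",
                   sub = NA_character_,
                   signal = .lnoise(spec$nReplicates, .BG + .S0, cv)))
      varRows <- lapply(seq_along(subs), function(i) {
        data.frame(substrate = subst, batch = b, group = "variant",
                   sub = subs[[i]],
                   signal = .lnoise(spec$nReplicates,
                                    .BG + tTrue[[i]] / 100 * .S0, cv))
      })
      do.call(rbind, c(rows, varRows))
    }))
  }))

  surfaceLanes <- do.call(rbind, lapply(seq_len(spec$nBatches), function(b) {
    wtRows <- data.frame(blot = b, group = "wildtype", sub = NA_character_,
                         intensity = .lnoise(2L, .E0, cv))
    varRows <- lapply(seq_along(subs), function(i) {
      data.frame(blot = b, group = "variant", sub = subs[[i]],
                 intensity = if (subs[[i]] %in% spec$dropout) 0
                             else .lnoise(1L, eTrue[[i]] / 100 * .E0, cv))
    })
    do.call(rbind, c(list(wtRows), varRows))
  }))

  meas <- list()
  for (subst in spec$substrates) {
    w <- uptakeWells[uptakeWells$substrate == subst,
                     c("batch", "group", "sub", "signal")]
    norm <- normalizeUptakeWells(w)
    meas[[length(meas) + 1L]] <- data.frame(
      sub = ifelse(norm$is_wt, spec$wt, norm$sub),
      kind = "cellular_uptake", substrate = subst,
      mean = norm$mean, sd = norm$sd, n = norm$n)
  }
  normS <- normalizeSurfaceLanes(surfaceLanes)
  meas[[length(meas) + 1L]] <- data.frame(
    sub = ifelse(normS$is_wt, spec$wt, normS$sub),
    kind = "surface_expression", substrate = NA_character_,
    mean = normS$mean, sd = normS$sd, n = normS$n)
  scan <- PositionScan(do.call(rbind, meas), position = spec$position,
                       wt = spec$wt)
  scan <- expressionFilter(scan)

  truthMeans <- rbind(
    do.call(rbind, lapply(spec$substrates, function(subst)
      data.frame(sub = subs, kind = "cellular_uptake", substrate = subst,
                 true_mean = tTrue))),
    data.frame(sub = subs, kind = "surface_expression",
               substrate = NA_character_, true_mean = eTrue))
  corrTrue <- ifelse(eTrue > 0, 100 * tTrue / eTrue, NA_real_)
  truthMeans <- rbind(truthMeans,
    do.call(rbind, lapply(spec$substrates, function(subst)
      data.frame(sub = subs, kind = "corrected_transport",
                 substrate = subst, true_mean = corrTrue))))

  dropoutMask <- subs %in% spec$dropout
  intended <- list()
  for (subst in spec$substrates) {
    intended[[assayKey("cellular_uptake", subst)]] <-
      classLabel(rheoScale(tTrue[!dropoutMask]))
    intended[[assayKey("corrected_transport", subst)]] <-
      classLabel(rheoScale(corrTrue[!dropoutMask]))
  }
  eScore <- eTrue
  eScore[dropoutMask] <- 0
  intended[["surface_expression"]] <- classLabel(rheoScale(eScore))

  list(scan = scan, uptakeWells = uptakeWells, surfaceLanes = surfaceLanes,
       truth = list(means = truthMeans, intendedLabels = intended,
                    label = spec$label))
}

#' Generate a multi-position synthetic study
#'
#' Builds a full study bundle -- one scan per archetype spec, a
#' conservation table, and optionally an AlphaMissense-style prediction
#' table with configurable concordance -- that runs through the entire
#' pipeline (normalize, filter, correct, score, correlate).
#'
#' @param specs List of [archetypeSpec()] with distinct positions (at
#'   least 3 for the correlation stages to be computable).
#' @param conservation Integer vector of ConSurf-style grades (1--9), one
#'   per spec.
#' @param prediction Generate a prediction table?
#' @param predictionConcordance Probability that a variant's predictor
#'   score band agrees with its simulated ground truth; the remainder get
#'   uniform random scores.
#' @param benignMax,pathogenicMin Predictor band cutoffs.
#' @param seed Seed for the predictor-score draws.
#' @return A list with \code{scans} (named list of
#'   \linkS4class{PositionScan}), \code{generated} (full per-position
#'   generator output including truth), \code{conservation} (data.frame)
#'   and \code{prediction} (data.frame or NULL).
#' @export
generateStudy <- function(specs, conservation, prediction = FALSE,
                          predictionConcordance = 0.9, benignMax = 0.34,
                          pathogenicMin = 0.564, seed = 1) {
  stopifnot(length(specs) == length(conservation),
            all(conservation >= 1), all(conservation <= 9))
  gens <- lapply(specs, generatePositionScan)
  scans <- lapply(gens, `[[`, "scan")
  names(scans) <- vapply(scans, function(s)
    paste0(wtResidue(s), scanPosition(s)), character(1))
  consTab <- data.frame(
    position = vapply(scans, scanPosition, integer(1)),
    score = as.integer(conservation), row.names = NULL)
  predTab <- NULL
  if (prediction) {
    set.seed(seed)
    rows <- do.call(rbind, lapply(seq_along(specs), function(i) {
      sp <- specs[[i]]
      data.frame(position = sp$position, sub = sp$subs,
                 true_uptake = sp$transportProfile)
    }))
    lowTrue <- rows$true_uptake < 80  # clearly below the WT range
    agree <- runif(nrow(rows)) < predictionConcordance
    score <- runif(nrow(rows))  # discordant/ambiguous draws
    score[agree & lowTrue] <- runif(sum(agree & lowTrue), pathogenicMin, 1)
    score[agree & !lowTrue] <- runif(sum(agree & !lowTrue), 0, benignMax)
    predTab <- data.frame(position = rows$position, sub = rows$sub,
                          score = score)
    attr(predTab, "benign_max") <- benignMax
    attr(predTab, "pathogenic_min") <- pathogenicMin
  }
  list(scans = scans, generated = gens, conservation = consTab,
       prediction = predTab)
}
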