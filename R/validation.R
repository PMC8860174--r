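#' Agreement between detected and reference thresholds
#'
#' Compares two threshold sets over a common electrode index space.
#' Electrodes without a threshold in either set are excluded from the
#' comparison and counted separately. Agreement within one grid step of
#' the 10% geometric amplitude grid corresponds to agreement within
#' +/-10% of amplitude; the comparison is done in grid-index arithmetic to
#' avoid floating-point boundary ambiguity of a literal ratio test. The
#' Pearson correlation is computed on the threshold amplitudes of the
#' jointly detected electrodes and reported as `NA` when fewer than two
#' electrodes are jointly detected or either set is constant.
#'
#' @param detected,reference [BundleThresholds-class] objects over the
#'   same electrodes.
#' @return an [AgreementReport-class].
#' @examples
#' g <- defaultAmplitudeGrid()
#' a <- BundleThresholds(1:3, c(5L, 6L, 9L), g)
#' b <- BundleThresholds(1:3, c(5L, 5L, 5L), g)
#' compareThresholds(a, b)  # 2/3 within one step, 1/3 exact
#' @export
compareThresholds <- function(detected, reference) {
  stopifnot(is(detected, "BundleThresholds"), is(reference, "BundleThresholds"))
  if (!identical(detected@electrode, reference@electrode))
    stop("detected and reference cover different electrode sets")
  di <- detected@index
  ri <- reference@index
  joint <- !is.na(di) & !is.na(ri)
  n <- sum(joint)
  if (n > 0L) {
    dd <- abs(di[joint] - ri[joint])
    fWithin <- mean(dd <= 1L)
    fExact <- mean(dd == 0L)
  } else {
    fWithin <- NA_real_
    fExact <- NA_real_
  }
  r <- NA_real_
  if (n >= 2L) {
    x <- detected@amplitude[joint]
    y <- reference@amplitude[joint]
    if (stats::sd(x) > 0 && stats::sd(y) > 0) r <- stats::cor(x, y)
  }
  new("AgreementReport",
      nCompared = as.integer(n),
      fractionWithinOneStep = fWithin,
      fractionExact = fExact,
      pearsonR = r,
      nDetectedOnly = as.integer(sum(!is.na(di) & is.na(ri))),
      nReferenceOnly = as.integer(sum(is.na(di) & !is.na(ri))),
      nNeither = as.integer(sum(is.na(di) & is.na(ri))))
}

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport over %d jointly detected electrodes\n", object@nCompared))
  cat(sprintf("  within one grid step (+/-10%%): %s\n",
              format(object@fractionWithinOneStep, digits = 4)))
  cat(sprintf("  exact match:                   %s\n",
              format(object@fractionExact, digits = 4)))
  cat(sprintf("  Pearson r (amplitudes):        %s\n",
              format(object@pearsonR, digits = 4)))
  if (object@nDetectedOnly || object@nReferenceOnly || object@nNeither)
    cat(sprintf("  excluded: %d detected-only, %d reference-only, %d neither\n",
                object@nDetectedOnly, object@nReferenceOnly, object@nNeither))
})

#' Chance-level agreement under permutation of the reference
#'
#' Estimates the agreement expected by chance by randomly permuting the
#' reference thresholds among the electrodes that carry one (within each
#' stratum, e.g. each scan or preparation, when `strata` is given; the
#' strata results are pooled through the joint fraction) and recomputing
#' the fraction within one grid step for each permutation.
#'
#' @param detected,reference [BundleThresholds-class] objects over the
#'   same electrodes.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param strata optional vector (length = electrodes) of stratum labels;
#'   permutation happens within strata.
#' @return list with `mean`, `sd` and the per-permutation `fractions`.
#' @export
permutationBaseline <- function(detected, reference, nPerm = 100L, seed = 1L,
                                strata = NULL) {
  stopifnot(nPerm >= 1L)
  if (!identical(detected@electrode, reference@electrode))
    stop("detected and reference cover different electrode sets")
  refIdx <- reference@index
  hasRef <- which(!is.na(refIdx))
  if (is.null(strata)) strata <- rep(1L, length(refIdx))
  groups <- split(hasRef, strata[hasRef])
  fractions <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPerm), function(k) {
      perm <- refIdx
      for (g in groups) perm[g] <- refIdx[sample(g)]
      compareThresholds(detected,
                        BundleThresholds(reference@electrode, perm,
                                         reference@grid))@fractionWithinOneStep
    }, numeric(1L))
  })
  list(mean = mean(fractions), sd = stats::sd(fractions), fractions = fractions)
}

# internal: spike-time tables for every stimulating electrode of a scan
.scanTimes <- function(scan, config) {
  d <- dim(scan@voltages)
  lapply(seq_len(d[1L]), function(i) {
    block <- array(scan@voltages[i, , , , ], d[-1L])
    .blockSpikeTimes(block, config, scan@samplingRate)
  })
}

.detectAllFromTimes <- function(times, scan, config, repeats = NULL,
                                pValue = NULL) {
  cfg <- config
  if (!is.null(pValue)) cfg@pValue <- as.numeric(pValue)
  win <- windowSamples(cfg, scan@samplingRate)
  idx <- vapply(times, function(t)
    .detectFromTimes(t, attr(t, "ampIndices"), scan@array, scan@grid,
                     cfg, length(win), repeats = repeats), integer(1L))
  BundleThresholds(scan@stimElectrodes, idx, scan@grid)
}

#' Detection accuracy as a function of the number of repeats
#'
#' Reruns detection on random subsets of the scan's repeats and compares
#' each rerun against the reference thresholds, tracing how agreement
#' grows with the number of stimulation repeats. Spike times are extracted
#' once; only the variance test onward depends on the repeat subset.
#'
#' @param scan a [ScanRecording-class].
#' @param config a [DetectionConfig-class].
#' @param repeatCounts integer vector of subset sizes (each in
#'   2..nRepeats).
#' @param nDraws random subsets per size.
#' @param seed RNG seed for the subset draws.
#' @param reference a [BundleThresholds-class] (e.g. the full-repeat
#'   detection, or ground truth).
#' @return data frame with one row per repeat count: `nRepeats`,
#'   `meanWithinOneStep`, `sdWithinOneStep`, `nDraws`; per-draw fractions
#'   in attribute `"draws"`.
#' @export
repeatsCurve <- function(scan, config, repeatCounts, nDraws = 10L, seed = 1L,
                         reference) {
  R <- nRepeats(scan)
  repeatCounts <- as.integer(repeatCounts)
  if (any(repeatCounts < 2L))
    stop("repeat counts below 2 are rejected (spike-time variance undefined)")
  if (any(repeatCounts > R))
    stop("repeat counts exceed the scan's ", R, " repeats")
  times <- .scanTimes(scan, config)
  draws <- withr::with_seed(as.integer(seed), {
    lapply(repeatCounts, function(k)
      lapply(seq_len(nDraws), function(j) sort(sample.int(R, k))))
  })
  perDraw <- do.call(rbind, lapply(seq_along(repeatCounts), function(ci) {
    f <- vapply(draws[[ci]], function(subset) {
      det <- .detectAllFromTimes(times, scan, config, repeats = subset)
      compareThresholds(det, reference)@fractionWithinOneStep
    }, numeric(1L))
    data.frame(nRepeats = repeatCounts[ci], draw = seq_len(nDraws),
               fractionWithinOneStep = f)
  }))
  out <- do.call(rbind, lapply(split(perDraw, perDraw$nRepeats), function(g)
    data.frame(nRepeats = g$nRepeats[1L],
               meanWithinOneStep = mean(g$fractionWithinOneStep),
               sdWithinOneStep = stats::sd(g$fractionWithinOneStep),
               nDraws = nrow(g))))
  out <- out[order(out$nRepeats), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "draws") <- perDraw
  out
}

#' Detection accuracy as a function of the test level
#'
#' Reruns detection at each candidate p-value of the spike-time variance
#' test and reports the agreement against the reference. Spike times are
#' extracted once; only the cutoff changes across the sweep.
#'
#' @param scan a [ScanRecording-class].
#' @param config a [DetectionConfig-class] (its `pValue` is overridden by
#'   each sweep value).
#' @param pValues numeric vector of test levels in (0, 1).
#' @param reference a [BundleThresholds-class].
#' @return data frame with columns `pValue`, `fractionWithinOneStep`,
#'   `fractionExact`, `nCompared`.
#' @export
pvalueSweep <- function(scan, config, pValues, reference) {
  if (any(pValues <= 0 | pValues >= 1)) stop("all p-values must lie in (0, 1)")
  times <- .scanTimes(scan, config)
  rows <- lapply(pValues, function(p) {
    rep_ <- compareThresholds(.detectAllFromTimes(times, scan, config, pValue = p),
                              reference)
    data.frame(pValue = p,
               fractionWithinOneStep = rep_@fractionWithinOneStep,
               fractionExact = rep_@fractionExact,
               nCompared = rep_@nCompared)
  })
  do.call(rbind, rows)
}
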