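# Poisson acquisition at duration-equivalent count budgets.

# evaluate expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# per-arm substream: fold (master seed, duration class, replicate) into one
# 31-bit seed, so replicates can be re-ordered without changing their draws
.deriveSeed <- function(master, durationClass, replicate) {
  as.integer((((master %% 2147483647) * 48271) %% 2147483647 +
                durationClass * 7919 + replicate * 104729) %% 2147483647)
}

#' Count budget for a phantom acquisition
#'
#' The 2-minute-per-bed-equivalent phantom frame carries `base2` expected
#' counts (default 2e6 per slice stack); the 3 m/b-equivalent frame scales by
#' 46/31, the ratio of the two list-mode frame durations it emulates.
#'
#' @param durationClass 2 or 3.
#' @param seed RNG seed for the Poisson draw.
#' @param base2 expected total counts of the 2 m/b-equivalent frame.
#' @return a [CountBudget-class].
#' @export
phantomBudget <- function(durationClass, seed = 1L, base2 = 2e6) {
  stopifnot(durationClass %in% c(2, 3))
  counts <- if (durationClass == 2) base2 else base2 * 46 / 31
  CountBudget(durationClass, counts, seed)
}

#' Count budget for a patient acquisition
#'
#' The 2 m/b budget carries `base2` expected counts per bed (default 3.2e6,
#' from the one-time liver-noise calibration);
#' the 3 m/b budget scales by exactly 3/2. `base2` is the calibration knob
#' tied to the liver-noise target (see [calibratePatientBudget()]).
#'
#' @param durationClass 2 or 3.
#' @param seed RNG seed.
#' @param base2 expected total counts of the 2 m/b acquisition.
#' @return a [CountBudget-class].
#' @export
patientBudget <- function(durationClass, seed = 1L, base2 = 3.2e6) {
  stopifnot(durationClass %in% c(2, 3))
  counts <- if (durationClass == 2) base2 else base2 * 3 / 2
  CountBudget(durationClass, counts, seed)
}

#' @rdname poissonAcquire
#' @export
setMethod("poissonAcquire", signature("Sinogram", "CountBudget"),
  function(expected, budget, ...) {
    if (expected@kind != "expected")
      stop("poissonAcquire needs an expected-kind sinogram")
    tot <- sum(expected@values)
    if (tot <= 0) {
      if (budget@expectedTotalCounts > 0)
        stop("cannot draw positive counts from an all-zero expected sinogram")
      return(Sinogram(expected@values * 0, expected@geometry, kind = "counts",
                      meta = list(durationClass = budget@durationClass,
                                  expectedTotalCounts = 0,
                                  seed = budget@seed)))
    }
    countScale <- budget@expectedTotalCounts / tot
    lam <- expected@values * countScale
    counts <- .withSeed(budget@seed,
                        array(rpois(length(lam), lam), dim(lam)))
    # countScale maps concentration-units line integrals to expected counts;
    # reconstruction divides it back out to restore kBq/mL (the scanner's
    # calibration factor, known exactly here)
    Sinogram(counts, expected@geometry, kind = "counts",
             meta = list(durationClass = budget@durationClass,
                         expectedTotalCounts = budget@expectedTotalCounts,
                         seed = budget@seed, countScale = countScale))
  })

#' Simulate projection data from a truth volume
#'
#' Convenience wrapper for the simulation chain: Gaussian resolution blur in
#' the image domain, forward projection, Poisson draw at the budget.
#'
#' @param truth an [ActivityVolume-class].
#' @param geometry a [ProjectionGeometry-class].
#' @param budget a [CountBudget-class], or `NULL` for the noiseless expected
#'   sinogram.
#' @param psfFwhm Gaussian resolution FWHM in mm (default 4).
#' @return a [Sinogram-class] of kind `"counts"` (or `"expected"` when
#'   `budget` is `NULL`).
#' @export
simulateData <- function(truth, geometry, budget = NULL, psfFwhm = 4) {
  expected <- project(applyPsf(truth, psfFwhm), geometry)
  if (is.null(budget)) return(expected)
  poissonAcquire(expected, budget)
}
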