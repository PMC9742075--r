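# Sweep orchestrator: the 16-group experiment (OSEM at 2/3 m/b plus the
# penalized algorithm over the beta grid at both durations), replicated over
# seeded noise realizations, with per-group aggregation and normality-gated
# paired comparisons against the reference arm.

#' Build a sweep configuration
#'
#' Bundles everything [runSweep()] needs: the mode (phantom or patient), the
#' truth specification, grid and geometry, the beta grid and duration
#' classes, the count budgets, the protocols and the reference group.
#'
#' @param mode `"phantom"` or `"patient"`.
#' @param masterSeed master RNG seed; per-(duration, replicate) substreams
#'   are derived from it, so replicates can be re-ordered without changing
#'   their draws.
#' @param replicates number of independent noise realizations.
#' @param betaGrid penalization factors (default the conventional seven).
#' @param durationClasses duration classes to include (default `c(2, 3)`).
#' @param budgetBase2 expected counts of the 2 m/b-equivalent acquisition
#'   (default 2e6 for phantom mode, 3.2e6 for patient mode); the 3 m/b
#'   budget scales by 46/31 (phantom) or 3/2 (patient).
#' @param spec the [PhantomSpec-class] or [PatientSpec-class] truth; default
#'   built per mode.
#' @param grid reconstruction grid; default `VoxelGrid()` (phantom) or
#'   `VoxelGrid(nz = 20L)` (patient).
#' @param geometry projection geometry; default derived from `grid`.
#' @param osem [OsemProtocol-class] for the OSEM arms.
#' @param pem template [PemProtocol-class]; its beta is overridden per arm.
#' @param psfFwhm simulation resolution FWHM, mm.
#' @param reference reference group label (default `"O3"`).
#' @param roiRingRadius background-ROI ring radius, mm (phantom mode).
#' @param roiClearance minimum sphere-to-background-ROI edge clearance, mm.
#' @return a named list (class `"petSweepConfig"`).
#' @export
sweepConfig <- function(mode = c("phantom", "patient"), masterSeed = 1L,
                        replicates = 1L,
                        betaGrid = c(0.03, 0.07, 0.1, 0.2, 0.3, 0.4, 0.5),
                        durationClasses = c(2, 3), budgetBase2 = NULL,
                        spec = NULL, grid = NULL, geometry = NULL,
                        osem = OsemProtocol(), pem = PemProtocol(beta = 0),
                        psfFwhm = 4, reference = "O3", roiRingRadius = 95,
                        roiClearance = 15) {
  mode <- match.arg(mode)
  if (is.null(grid))
    grid <- if (mode == "phantom") VoxelGrid() else VoxelGrid(nz = 20L)
  if (is.null(geometry)) geometry <- ProjectionGeometry(grid = grid)
  if (is.null(spec))
    spec <- if (mode == "phantom") NemaPhantomSpec() else PatientSpec()
  if (is.null(budgetBase2))
    budgetBase2 <- if (mode == "phantom") 2e6 else 3.2e6
  cfg <- list(mode = mode, masterSeed = as.integer(masterSeed),
              replicates = as.integer(replicates), betaGrid = betaGrid,
              durationClasses = durationClasses, budgetBase2 = budgetBase2,
              spec = spec, grid = grid, geometry = geometry, osem = osem,
              pem = pem, psfFwhm = psfFwhm, reference = reference,
              roiRingRadius = roiRingRadius, roiClearance = roiClearance)
  class(cfg) <- "petSweepConfig"
  arms <- .sweepArms(cfg)
  if (!reference %in% arms$label)
    stop(sprintf("reference arm '%s' is not in the configured arm list",
                 reference))
  cfg
}

.sweepArms <- function(cfg) {
  rows <- list()
  for (d in cfg$durationClasses) {
    rows[[length(rows) + 1L]] <-
      data.frame(label = .formatGroupLabel("OSEM", d), algorithm = "OSEM",
                 duration = d, beta = NA_real_)
    for (b in cfg$betaGrid)
      rows[[length(rows) + 1L]] <-
        data.frame(label = .formatGroupLabel("PEM", d, b), algorithm = "PEM",
                   duration = d, beta = b)
  }
  do.call(rbind, rows)
}

.budgetFor <- function(cfg, duration, seed) {
  if (cfg$mode == "phantom")
    phantomBudget(duration, seed, base2 = cfg$budgetBase2)
  else patientBudget(duration, seed, base2 = cfg$budgetBase2)
}

.reconstructArm <- function(cfg, arm, counts, suvScale) {
  lbl <- makeGroupLabel(arm$algorithm, arm$duration, arm$beta)
  if (arm$algorithm == "OSEM")
    osemReconstruct(counts, cfg$osem, cfg$grid, cfg$geometry, label = lbl,
                    suvScale = suvScale)
  else {
    prot <- cfg$pem
    prot@beta <- arm$beta
    pemReconstruct(counts, prot, cfg$grid, cfg$geometry, label = lbl,
                   suvScale = suvScale)
  }
}

#' Run the full sweep experiment
#'
#' For every replicate and duration class: simulate the truth volume, acquire
#' one Poisson sinogram from the derived substream, reconstruct every arm of
#' that duration from the same counts (as rebinning one list-mode acquisition
#' would), and measure the mode's metrics. Aggregates per-group summaries,
#' normalizes against the reference group, and runs normality-gated paired
#' comparisons of every arm against the reference with Benjamini-Hochberg
#' correction per metric family. Fully deterministic given the master seed.
#'
#' @param cfg a configuration from [sweepConfig()].
#' @param outDir optional output directory; when given, CSV reports, the
#'   effective-config echo (`config.yaml`) and a timestamped run log are
#'   written there.
#' @return list with `perReplicate` (raw long table), `groupMetrics`
#'   (one row per group), `comparisons` (one row per non-reference arm and
#'   metric), and for phantom mode `sphereMetrics` (group x sphere).
#' @export
runSweep <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "petSweepConfig"))
  arms <- .sweepArms(cfg)
  phantomMode <- cfg$mode == "phantom"
  if (phantomMode) {
    truth <- buildNemaPhantom(cfg$spec, cfg$grid)
    layout <- layoutRois(cfg$spec, cfg$grid, ringRadius = cfg$roiRingRadius,
                         clearanceMm = cfg$roiClearance)
    sc <- 1
  } else {
    truth <- buildPatient(cfg$spec, cfg$grid)
    sc <- suvScaleOf(cfg$spec)
  }
  expected <- project(applyPsf(truth, cfg$psfFwhm), cfg$geometry)

  rows <- list()
  for (rep in seq_len(cfg$replicates)) {
    for (d in cfg$durationClasses) {
      seed <- .deriveSeed(cfg$masterSeed, d, rep)
      counts <- poissonAcquire(expected, .budgetFor(cfg, d, seed))
      for (i in which(arms$duration == d)) {
        arm <- arms[i, ]
        rec <- .reconstructArm(cfg, arm, counts, sc)
        if (phantomMode) {
          sm <- measureSphereMetrics(rec, layout, cfg$spec)
          sm$group <- arm$label; sm$replicate <- rep
          rows[[length(rows) + 1L]] <- sm
        } else {
          lc <- liverCv(rec, patient = cfg$spec)
          les <- cfg$spec@lesions
          if (length(les)) {
            for (li in seq_along(les)) {
              seg <- segmentLesion(rec, les[[li]]@center)
              rows[[length(rows) + 1L]] <- data.frame(
                group = arm$label, replicate = rep, lesion = li,
                liverSuvMean = lc$suvMean, liverCv = lc$cv,
                suvMax = seg$suvMax, volumeMm3 = seg$volumeMm3,
                equivalentDiameter = seg$equivalentDiameter,
                sizeClass = stratify(seg$equivalentDiameter)$sizeClass)
            }
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              group = arm$label, replicate = rep, lesion = NA_integer_,
              liverSuvMean = lc$suvMean, liverCv = lc$cv,
              suvMax = NA_real_, volumeMm3 = NA_real_,
              equivalentDiameter = NA_real_, sizeClass = NA_character_)
          }
        }
      }
    }
  }
  per <- do.call(rbind, rows)
  res <- if (phantomMode) .aggregatePhantom(cfg, per, arms)
         else .aggregatePatient(cfg, per, arms)
  res$perReplicate <- per
  if (!is.null(outDir)) .writeSweepReports(cfg, res, outDir)
  res
}

.meanSd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)

.aggregatePhantom <- function(cfg, per, arms) {
  ref <- cfg$reference
  # per-group x sphere averages over replicates
  agg <- aggregate(per[, c("cH", "cB", "sd", "cr", "bv", "cnr", "rcr")],
                   by = list(group = per$group, sphere = per$sphere,
                             diameter = per$diameter), FUN = mean)
  agg <- agg[order(agg$group, agg$sphere), ]
  # normalized activity: per replicate, group mean of sphere ROI means over
  # the reference group's, then averaged (mean-of-ratios)
  gm <- aggregate(list(meanCH = per$cH),
                  by = list(group = per$group, replicate = per$replicate),
                  FUN = mean)
  ratios <- do.call(rbind, lapply(split(gm, gm$replicate), function(gr) {
    refv <- gr$meanCH[gr$group == ref]
    data.frame(group = gr$group, replicate = gr$replicate[1],
               ratio = ifelse(gr$group == ref, 1, gr$meanCH / refv))
  }))
  na <- aggregate(list(normalizedActivity = ratios$ratio),
                  by = list(group = ratios$group), FUN = mean)
  groupMetrics <- aggregate(per[, c("cr", "bv", "cnr", "rcr")],
                            by = list(group = per$group), FUN = mean)
  groupMetrics <- merge(groupMetrics, na, by = "group")
  groupMetrics <- groupMetrics[order(groupMetrics$group), ]

  comparisons <- .compareArms(cfg, per, arms,
                              metrics = c("cr", "bv", "cnr", "rcr"),
                              pairOn = c("replicate", "sphere"))
  list(sphereMetrics = agg, groupMetrics = groupMetrics,
       comparisons = comparisons)
}

.aggregatePatient <- function(cfg, per, arms) {
  ref <- cfg$reference
  liver <- unique(per[, c("group", "replicate", "liverSuvMean", "liverCv")])
  gl <- aggregate(liver[, c("liverSuvMean", "liverCv")],
                  by = list(group = liver$group), FUN = mean)
  # normalized CV per replicate, then averaged
  ncv <- do.call(rbind, lapply(split(liver, liver$replicate), function(lr) {
    refv <- lr$liverCv[lr$group == ref]
    data.frame(group = lr$group,
               ratio = ifelse(lr$group == ref, 1, lr$liverCv / refv))
  }))
  ncvAgg <- aggregate(list(normalizedCvMean = ncv$ratio),
                      by = list(group = ncv$group), FUN = mean)
  ncvSd <- aggregate(list(normalizedCvSd = ncv$ratio),
                     by = list(group = ncv$group),
                     FUN = function(x) if (length(x) > 1) sd(x) else 0)
  groupMetrics <- merge(merge(gl, ncvAgg, by = "group"), ncvSd, by = "group")

  if (!all(is.na(per$suvMax))) {
    # per-lesion normalized SUVmax (per replicate and lesion, vs reference)
    key <- interaction(per$replicate, per$lesion, drop = TRUE)
    nsv <- do.call(rbind, lapply(split(per, key), function(pr) {
      refv <- pr$suvMax[pr$group == ref]
      data.frame(group = pr$group,
                 ratio = ifelse(pr$group == ref, 1, pr$suvMax / refv))
    }))
    sm <- aggregate(list(suvMaxMean = per$suvMax),
                    by = list(group = per$group), FUN = mean)
    nsAgg <- aggregate(list(normalizedSuvMaxMean = nsv$ratio),
                       by = list(group = nsv$group), FUN = mean)
    nsSd <- aggregate(list(normalizedSuvMaxSd = nsv$ratio),
                      by = list(group = nsv$group),
                      FUN = function(x) if (length(x) > 1) sd(x) else 0)
    groupMetrics <- Reduce(function(a, b) merge(a, b, by = "group"),
                           list(groupMetrics, sm, nsAgg, nsSd))
  }
  groupMetrics <- groupMetrics[order(groupMetrics$group), ]
  comparisons <- .compareArms(cfg, per, arms,
                              metrics = c("liverCv", "suvMax"),
                              pairOn = c("replicate", "lesion"),
                              dedupFor = c(liverCv = TRUE, suvMax = FALSE))
  list(groupMetrics = groupMetrics, comparisons = comparisons)
}

# paired comparisons of every non-reference arm against the reference, one
# BH family per metric across arms
.compareArms <- function(cfg, per, arms, metrics, pairOn,
                         dedupFor = NULL) {
  ref <- cfg$reference
  out <- list()
  for (metric in metrics) {
    sub <- per[, c("group", pairOn, metric)]
    if (!is.null(dedupFor) && isTRUE(dedupFor[[metric]])) {
      sub <- unique(per[, c("group", pairOn[1], metric)])
      keyCols <- pairOn[1]
    } else keyCols <- pairOn
    sub <- sub[stats::complete.cases(sub), ]
    if (!nrow(sub)) next
    key <- do.call(paste, c(sub[keyCols], sep = ":"))
    refSub <- sub[sub$group == ref, ]
    refKey <- do.call(paste, c(refSub[keyCols], sep = ":"))
    for (g in setdiff(unique(sub$group), ref)) {
      gs <- sub[sub$group == g, ]
      gKey <- do.call(paste, c(gs[keyCols], sep = ":"))
      common <- intersect(gKey, refKey)
      x <- gs[[metric]][match(common, gKey)]
      y <- refSub[[metric]][match(common, refKey)]
      cmp <- pairedComparison(x, y)
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, group = g, reference = ref, n = cmp$n,
        test = cmp$test, gate = cmp$gate, statistic = cmp$statistic,
        p = cmp$p.value)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res$pAdjusted <- NA_real_
  for (metric in unique(res$metric)) {
    idx <- res$metric == metric
    res$pAdjusted[idx] <- bhAdjust(res$p[idx])
  }
  res
}

.writeSweepReports <- function(cfg, res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df))
      write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                file.path(outDir, name), row.names = FALSE, quote = FALSE)
  }
  wr(res$groupMetrics, "group_metrics.csv")
  wr(res$comparisons, "comparisons.csv")
  wr(res$sphereMetrics, "sphere_metrics.csv")
  wr(res$perReplicate, "per_replicate.csv")
  echo <- list(mode = cfg$mode, masterSeed = cfg$masterSeed,
               replicates = cfg$replicates, betaGrid = cfg$betaGrid,
               durationClasses = cfg$durationClasses,
               budgetBase2 = cfg$budgetBase2, psfFwhm = cfg$psfFwhm,
               reference = cfg$reference,
               grid = list(nx = cfg$grid@nx, ny = cfg$grid@ny,
                           nz = cfg$grid@nz, dx = cfg$grid@dx,
                           dy = cfg$grid@dy, dz = cfg$grid@dz),
               geometry = list(nAngles = cfg$geometry@nAngles,
                               nBins = cfg$geometry@nBins,
                               binWidth = cfg$geometry@binWidth))
  yaml::write_yaml(echo, file.path(outDir, "config.yaml"))
  writeLines(sprintf("[%s] sweep completed: mode=%s arms=%d replicates=%d",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S"), cfg$mode,
                     nrow(.sweepArms(cfg)), cfg$replicates),
             file.path(outDir, "run.log"))
  invisible(outDir)
}

#' Read a sweep configuration from a YAML file
#'
#' Reads the scalar sections of a YAML config (mode, masterSeed, replicates,
#' betaGrid, durationClasses, budgetBase2, psfFwhm, reference, grid,
#' geometry) and builds a [sweepConfig()] with package defaults for the rest.
#'
#' @param path YAML file path.
#' @return a sweep configuration.
#' @export
readSweepConfig <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- if (!is.null(y$grid))
    VoxelGrid(y$grid$nx, y$grid$ny, y$grid$nz, y$grid$dx, y$grid$dy,
              y$grid$dz) else NULL
  geometry <- if (!is.null(y$geometry))
    ProjectionGeometry(y$geometry$nAngles, y$geometry$nBins,
                       y$geometry$binWidth) else NULL
  args <- y[intersect(names(y), c("mode", "masterSeed", "replicates",
                                  "betaGrid", "durationClasses",
                                  "budgetBase2", "psfFwhm", "reference"))]
  args$betaGrid <- unlist(args$betaGrid)
  args$durationClasses <- unlist(args$durationClasses)
  do.call(sweepConfig, c(args, list(grid = grid, geometry = geometry)))
}
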