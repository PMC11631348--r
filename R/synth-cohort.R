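#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated study population:
#' three correlated latent intelligence components (general g, crystallized
#' gC, fluid gF), family clustering, and confounds correlated with the
#' general factor. Defaults emulate the population structure reported for
#' a large young-adult cohort: component inter-correlations 0.78 (g-gC),
#' 0.76 (g-gF), 0.49 (gC-gF), and confound-g correlations of -0.13 (age),
#' 0.18 (sex), 0.00 (handedness), -0.20 (mean framewise displacement),
#' -0.20 (spike proportion).
#'
#' @param nSubjects Number of subjects.
#' @param componentCor Named numeric: target correlations \code{g_gc},
#'   \code{g_gf}, \code{gc_gf}.
#' @param confoundCor Named numeric: target correlations of age, sex,
#'   handedness, mean FD, and spike proportion with the general factor.
#' @param familyEffect Proportion of latent-component variance shared
#'   within family (0 disables family clustering).
#' @param familyGeomProb Success probability of the truncated geometric
#'   family-size distribution (larger = smaller families; most families of
#'   size 1-3 at the default).
#' @param familyMaxSize Maximum family size.
#' @param ageMean,ageSD Age distribution (years).
#' @param fdMean,fdSD Mean framewise displacement distribution (mm).
#' @param spikeMean,spikeSD Spike-proportion distribution (fraction of
#'   volumes with FD above the spike threshold).
#' @param maxSpikeShape,maxSpikeScale Gamma parameters of the largest-spike
#'   magnitude (mm).
#' @param loadingSpec Measure loading specification, see
#'   [defaultLoadingSpec()].
#' @return A list of class \code{cohortConfig}.
#' @export
cohortConfig <- function(nSubjects = 806,
                         componentCor = c(g_gc = 0.78, g_gf = 0.76,
                                          gc_gf = 0.49),
                         confoundCor = c(age = -0.13, sex = 0.18,
                                         handedness = 0.00, mean_fd = -0.20,
                                         spike_prop = -0.20),
                         familyEffect = 0.3,
                         familyGeomProb = 0.45, familyMaxSize = 6,
                         ageMean = 28.6, ageSD = 3.6,
                         fdMean = 0.12, fdSD = 0.04,
                         spikeMean = 0.06, spikeSD = 0.05,
                         maxSpikeShape = 2, maxSpikeScale = 0.6,
                         loadingSpec = defaultLoadingSpec()) {
  cfg <- list(nSubjects = nSubjects, componentCor = componentCor,
              confoundCor = confoundCor, familyEffect = familyEffect,
              familyGeomProb = familyGeomProb, familyMaxSize = familyMaxSize,
              ageMean = ageMean, ageSD = ageSD, fdMean = fdMean, fdSD = fdSD,
              spikeMean = spikeMean, spikeSD = spikeSD,
              maxSpikeShape = maxSpikeShape, maxSpikeScale = maxSpikeScale,
              loadingSpec = loadingSpec)
  class(cfg) <- "cohortConfig"
  cfg
}

#' Default measure-to-factor loading specification
#'
#' Twelve cognitive measures in a bifactor-compatible structure: seven
#' fluid-defining tasks load on the fluid group factor, two (picture
#' vocabulary, oral reading recognition) on the crystallized component, and
#' three load on the general factor only. Loadings were chosen by
#' closed-form factor-model arithmetic so that scores estimated from the
#' measures recover the generating latents (see the methods vignette).
#'
#' @param generalFluid,generalPure,generalCryst General-factor loadings for
#'   the three measure groups.
#' @param groupFluid,groupCryst Group-factor loadings.
#' @return data.frame with columns measure, general, group, groupLoading,
#'   noiseSD.
#' @export
defaultLoadingSpec <- function(generalFluid = 0.68, generalPure = 0.72,
                               generalCryst = 0.75, groupFluid = 0.35,
                               groupCryst = 0.55) {
  fluid <- c("PicSeq", "CardSort", "Flanker", "PMAT24", "ProcSpeed",
             "VSPLOT", "ListSort")
  cryst <- c("PicVocab", "ReadEng")
  pure <- c("DDisc", "SCPT", "IWRD")
  spec <- data.frame(
    measure = c(fluid, cryst, pure),
    general = c(rep(generalFluid, 7), rep(generalCryst, 2),
                rep(generalPure, 3)),
    group = c(rep("fluid", 7), rep("crystallized", 2), rep("none", 3)),
    groupLoading = c(rep(groupFluid, 7), rep(groupCryst, 2), rep(0, 3)),
    stringsAsFactors = FALSE)
  spec$noiseSD <- sqrt(pmax(1 - spec$general^2 - spec$groupLoading^2, 0.02))
  spec
}

#' Measure-to-factor map matching [defaultLoadingSpec()]
#'
#' Names the seven fluid-defining measures and the two crystallized
#' measures used by [scoreIntelligence()].
#' @return List with elements \code{fluid}, \code{crystallized},
#'   \code{all}.
#' @export
defaultMeasureMap <- function() {
  spec <- defaultLoadingSpec()
  list(fluid = spec$measure[spec$group == "fluid"],
       crystallized = spec$measure[spec$group == "crystallized"],
       all = spec$measure)
}

componentCorMatrix <- function(componentCor) {
  R <- diag(3)
  dimnames(R) <- list(c("g", "gc", "gf"), c("g", "gc", "gf"))
  R["g", "gc"] <- R["gc", "g"] <- componentCor[["g_gc"]]
  R["g", "gf"] <- R["gf", "g"] <- componentCor[["g_gf"]]
  R["gc", "gf"] <- R["gf", "gc"] <- componentCor[["gc_gf"]]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("component correlation targets do not form a positive ",
         "semi-definite matrix (min eigenvalue ", signif(min(ev), 3), ")")
  R
}

# family sizes from a geometric distribution truncated at maxSize
drawFamilySizes <- function(n, prob, maxSize) {
  sizes <- integer(0)
  while (sum(sizes) < n) {
    draw <- pmin(stats::rgeom(max(16L, ceiling(n / 2)), prob) + 1L, maxSize)
    sizes <- c(sizes, draw)
  }
  keep <- cumsum(sizes) < n
  sizes <- sizes[c(which(keep), sum(keep) + 1L)]
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  sizes
}

mvnormChol <- function(n, R) {
  matrix(stats::rnorm(n * ncol(R)), n) %*% chol(R)
}

#' Generate a synthetic cohort with known latent intelligence components
#'
#' Draws a cohort of subjects with family clustering, three correlated
#' latent intelligence components, confounds correlated with the general
#' factor, and 12 cognitive measures generated from a bifactor-compatible
#' loading specification. Deterministic for a fixed seed.
#'
#' Latent components are a family-shared plus an individual multivariate
#' normal part; confounds are built from a standard-normal channel
#' correlated with g at the configured target (with a latent-threshold
#' adjustment for the binary sex variable and a Gaussian-copula transform
#' for the uniformly distributed handedness score) and then mapped to
#' natural units.
#'
#' @param config A [cohortConfig()].
#' @param seed Integer seed.
#' @return List with elements \code{cohort} (data.frame: id, family_id,
#'   confounds, 12 measures) and \code{truth} (list: true_g, true_gc,
#'   true_gf, the orthogonalized group latents, config, seed).
#' @examples
#' sim <- generateCohort(cohortConfig(nSubjects = 50), seed = 1)
#' head(sim$cohort[, 1:6])
#' @export
generateCohort <- function(config = cohortConfig(), seed) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$nSubjects
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'nSubjects' must be a positive integer")
  R <- componentCorMatrix(config$componentCor)
  .withSeed(seed, {

  sizes <- drawFamilySizes(n, config$familyGeomProb, config$familyMaxSize)
  famId <- rep(sprintf("F%04d", seq_along(sizes)), times = sizes)

  a <- config$familyEffect
  famPart <- mvnormChol(length(sizes), R)[rep(seq_along(sizes), sizes), ,
                                          drop = FALSE]
  indPart <- mvnormChol(n, R)
  latent <- sqrt(a) * famPart + sqrt(1 - a) * indPart
  colnames(latent) <- c("g", "gc", "gf")
  g <- latent[, "g"]

  # standard-normal channel with correlation r to g
  channel <- function(r) r * g + sqrt(1 - r^2) * stats::rnorm(n)

  cc <- config$confoundCor
  age <- config$ageMean + config$ageSD * channel(cc[["age"]])
  # point-biserial attenuation: median split of a latent with correlation
  # rho yields r_pb = rho * dnorm(0) / 0.5
  rhoSex <- cc[["sex"]] / (stats::dnorm(0) / 0.5)
  if (abs(rhoSex) >= 1) stop("sex-g correlation target infeasible")
  sex <- as.integer(channel(rhoSex) > 0)
  hand <- stats::qunif(stats::pnorm(channel(cc[["handedness"]])), -100, 100)
  meanFd <- pmax(config$fdMean + config$fdSD * channel(cc[["mean_fd"]]),
                 0.005)
  spike <- pmin(pmax(config$spikeMean +
                       config$spikeSD * channel(cc[["spike_prop"]]), 0), 1)
  maxSpike <- stats::rgamma(n, shape = config$maxSpikeShape,
                            scale = config$maxSpikeScale)

  truth <- list(true_g = g, true_gc = latent[, "gc"],
                true_gf = latent[, "gf"],
                config = config, seed = as.integer(seed))
  truth <- c(truth, orthogonalGroupLatents(truth))
  measures <- generateMeasures(truth, config$loadingSpec)

  cohort <- data.frame(id = sprintf("S%05d", seq_len(n)), family_id = famId,
                       age = age, sex = sex, handedness = hand,
                       mean_fd = meanFd, spike_prop = spike,
                       max_spike = maxSpike, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(measures))
  list(cohort = cohort, truth = truth)
  })
}

# group latents orthogonal to g: standardized residuals of gc and gf on g
orthogonalGroupLatents <- function(truth) {
  resid <- function(y) {
    b <- stats::cov(y, truth$true_g) / stats::var(truth$true_g)
    r <- y - b * truth$true_g
    r / stats::sd(r)
  }
  list(u_crystallized = resid(truth$true_gc),
       u_fluid = resid(truth$true_gf))
}

#' Generate cognitive measures from latent components
#'
#' Builds the 12 cognitive measures as loadings times latents plus
#' independent Gaussian noise: each measure loads on the general factor
#' and optionally on one group factor (the orthogonalized fluid or
#' crystallized latent), mirroring a bifactor measurement model.
#'
#' @param truth Ground-truth list from [generateCohort()] (fields
#'   \code{true_g}, \code{u_fluid}, \code{u_crystallized}).
#' @param loadingSpec data.frame as returned by [defaultLoadingSpec()].
#' @return Matrix of measures, subjects x measures.
#' @export
generateMeasures <- function(truth, loadingSpec = defaultLoadingSpec()) {
  stopifnot(all(c("measure", "general", "group", "groupLoading",
                  "noiseSD") %in% names(loadingSpec)))
  bad <- setdiff(unique(loadingSpec$group), c("fluid", "crystallized",
                                              "none"))
  if (length(bad))
    stop("unknown group factor(s): ", paste(bad, collapse = ", "))
  n <- length(truth$true_g)
  groups <- cbind(fluid = truth$u_fluid, crystallized = truth$u_crystallized,
                  none = rep(0, n))
  m <- vapply(seq_len(nrow(loadingSpec)), function(k) {
    s <- loadingSpec[k, ]
    s$general * truth$true_g + s$groupLoading * groups[, s$group] +
      s$noiseSD * stats::rnorm(n)
  }, numeric(n))
  colnames(m) <- loadingSpec$measure
  m
}

#' Exclude subjects by in-scanner head motion
#'
#' Retains subjects with mean framewise displacement (FD) below
#' \code{meanFdMax}, spike proportion (volumes with FD above the spike
#' threshold) below \code{spikePropMax}, and no spike above
#' \code{maxSpikeMax}; the defaults are mean FD < 0.2 mm, spike
#' proportion < 20\%, max spike 5 mm. Subject order is preserved.
#'
#' @param cohort Cohort data.frame with columns \code{mean_fd},
#'   \code{spike_prop}, \code{max_spike}.
#' @param meanFdMax,spikePropMax,maxSpikeMax Exclusion thresholds.
#' @return Filtered cohort data.frame.
#' @export
excludeByMotion <- function(cohort, meanFdMax = 0.2, spikePropMax = 0.2,
                            maxSpikeMax = 5) {
  stopifnot(meanFdMax > 0, spikePropMax > 0, maxSpikeMax > 0)
  keep <- cohort$mean_fd < meanFdMax & cohort$spike_prop < spikePropMax &
    cohort$max_spike <= maxSpikeMax
  cohort[keep, , drop = FALSE]
}
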