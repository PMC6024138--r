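#' Scenario: generating parameter values for a simulated species
#'
#' @param psi occupancy probability in (0, 1).
#' @param betaS1 length-2 coefficients \code{(intercept, slope)} for
#'   \eqn{logit(s_1)} on \code{log(K + 1)}.
#' @param betaS0 length-2 coefficients for \eqn{logit(s_0)}.
#' @param label optional three-letter code (occupancy / baseline detection
#'   / baseline misidentification, e.g. \code{"HMH"}).
#' @return classed list \code{"ocScenario"}.
#' @export
ocScenario <- function(psi, betaS1, betaS0, label = NULL) {
  stopifnot(is.numeric(psi), length(psi) == 1L, psi > 0, psi < 1,
            length(betaS1) == 2L, all(is.finite(betaS1)),
            length(betaS0) == 2L, all(is.finite(betaS0)))
  structure(list(psi = psi, betaS1 = as.numeric(betaS1),
                 betaS0 = as.numeric(betaS0), label = label),
            class = "ocScenario")
}

#' @export
print.ocScenario <- function(x, ...) {
  cat(sprintf("scenario %s: psi = %.2f, beta_s1 = (%.3g, %.3g), beta_s0 = (%.3g, %.3g)\n",
              if (is.null(x$label)) "<unnamed>" else x$label,
              x$psi, x$betaS1[1], x$betaS1[2], x$betaS0[1], x$betaS0[2]))
  invisible(x)
}

#' Default species scenarios
#'
#' Five species-characteristic combinations labelled by occupancy (L/H),
#' baseline detection (L/M/H) and baseline misidentification (L/H). The HMH
#' combination uses published values (\eqn{\psi = 0.8}, detection
#' \code{(0, 1.6)}, misidentification \code{(-2.2, 1.5)}). The remaining
#' levels are surrogate values chosen to match the qualitative labels and
#' are user-overridable: occupancy L = 0.2; detection intercepts L/M/H =
#' -1.1 / 0 / +1.1 with slope 1.6; misidentification L intercept
#' \code{logit(0.05)} (about -2.944) and H intercept -2.2, slope 1.5. On
#' the probability scale at \code{K = 0} the misidentification baselines
#' are 0.05 (L) and 0.10 (H).
#'
#' @return named list of \code{\link{ocScenario}} objects
#'   (HHL, HLL, LLL, LLH, HMH), with attribute \code{surrogate} marking
#'   which are built from surrogate levels.
#' @export
defaultScenarios <- function() {
  det <- list(L = c(-1.1, 1.6), M = c(0, 1.6), H = c(1.1, 1.6))
  mis <- list(L = c(stats::qlogis(0.05), 1.5), H = c(-2.2, 1.5))
  occ <- c(L = 0.2, H = 0.8)
  mk <- function(lab) {
    a <- substr(lab, 1, 1); b <- substr(lab, 2, 2); c3 <- substr(lab, 3, 3)
    ocScenario(occ[[a]], det[[b]], mis[[c3]], label = lab)
  }
  out <- lapply(c("HHL", "HLL", "LLL", "LLH", "HMH"), mk)
  names(out) <- vapply(out, `[[`, "", "label")
  attr(out, "surrogate") <- c(HHL = TRUE, HLL = TRUE, LLL = TRUE,
                              LLH = TRUE, HMH = FALSE)
  out
}

#' Confirmation design C(p, d)
#'
#' A proportion \code{p} of sites is selected for confirmation; within each
#' selected site exactly \code{d} visits are confirmed, ambiguous
#' detections first.
#'
#' @param p proportion of confirmed sites in (0, 1].
#' @param d number of confirmed visits per confirmed site.
#' @return classed list \code{"ocConfirmationDesign"}.
#' @export
confirmationDesign <- function(p, d) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p <= 1,
            is.numeric(d), length(d) == 1L, d >= 1, d == round(d))
  structure(list(p = p, d = as.integer(d)), class = "ocConfirmationDesign")
}

#' @export
print.ocConfirmationDesign <- function(x, ...) {
  cat(sprintf("confirmation design C(p = %g, d = %d)\n", x$p, x$d))
  invisible(x)
}

.designLabel <- function(cd) sprintf("C(%g,%d)", cd$p, cd$d)

#' Activity (K) generator configuration
#'
#' The number of auto-classified recordings per visit. Parametric mode
#' draws from a zero-inflated negative binomial (defaults: mean 25,
#' dispersion 0.7, extra zero mass 0.1), a stand-in for resampling
#' empirical activity values; bootstrap mode samples with replacement from
#' a user-supplied vector of observed K values.
#'
#' @param mode \code{"parametric"} or \code{"bootstrap"}.
#' @param mean,dispersion negative-binomial mean and size parameter.
#' @param zeroMass extra point mass at zero in [0, 1).
#' @param values integer vector of empirical K values (bootstrap mode).
#' @return classed list \code{"ocKConfig"}.
#' @export
kConfig <- function(mode = c("parametric", "bootstrap"), mean = 25,
                    dispersion = 0.7, zeroMass = 0.1, values = NULL) {
  mode <- match.arg(mode)
  if (mode == "parametric")
    stopifnot(mean > 0, dispersion > 0, zeroMass >= 0, zeroMass < 1)
  if (mode == "bootstrap") {
    if (is.null(values) || length(values) == 0L)
      stop("bootstrap mode requires a non-empty vector of K values")
    stopifnot(all(values >= 0), all(values == round(values)))
  }
  structure(list(mode = mode, mean = mean, dispersion = dispersion,
                 zeroMass = zeroMass, values = values),
            class = "ocKConfig")
}

#' Survey design: dimensions, confirmation and activity model
#'
#' @param nSites number of sites (default 84).
#' @param nVisits visits per site (default 4).
#' @param confirmation a \code{\link{confirmationDesign}} (default full
#'   confirmation \code{C(1, nVisits)}).
#' @param K a \code{\link{kConfig}}.
#' @return classed list \code{"ocDesignSpec"}.
#' @export
surveyDesign <- function(nSites = 84, nVisits = 4, confirmation = NULL,
                         K = kConfig()) {
  stopifnot(nSites >= 1, nVisits >= 1)
  if (is.null(confirmation)) confirmation <- confirmationDesign(1, nVisits)
  stopifnot(inherits(confirmation, "ocConfirmationDesign"),
            inherits(K, "ocKConfig"))
  if (confirmation$d > nVisits)
    stop("confirmation design d exceeds the number of visits")
  structure(list(nSites = as.integer(nSites), nVisits = as.integer(nVisits),
                 confirmation = confirmation, K = K),
            class = "ocDesignSpec")
}

# deterministic seed derivation; stays below 2^31 - 1
.deriveSeed <- function(seed, ...) {
  m <- 2147483563
  a <- as.numeric(seed) %% m
  for (k in c(...)) a <- (a * 48271 + as.numeric(k) + 1) %% m
  as.integer(a + 1)
}

#' Generate a matrix of activity values
#'
#' @param design an \code{\link{surveyDesign}} (or anything with
#'   \code{nSites}/\code{nVisits}/\code{K}).
#' @param seed RNG seed (integer).
#' @return \code{nSites x nVisits} integer matrix of K values.
#' @export
generateK <- function(design, seed = 1L) {
  cfg <- design$K
  n <- design$nSites * design$nVisits
  set.seed(.deriveSeed(seed, 2L))
  K <- if (cfg$mode == "parametric") {
    k <- stats::rnbinom(n, size = cfg$dispersion, mu = cfg$mean)
    if (cfg$zeroMass > 0) k[stats::runif(n) < cfg$zeroMass] <- 0L
    k
  } else {
    cfg$values[sample.int(length(cfg$values), n, replace = TRUE)]
  }
  matrix(as.integer(K), nrow = design$nSites, ncol = design$nVisits)
}

#' Simulate a fully confirmed survey under the OC data-generating process
#'
#' Draws latent occupancy states \eqn{Z_i \sim Bernoulli(\psi)}, activity
#' values \eqn{K_{ij}} from the design's generator, per-visit detection
#' probabilities from the logit-linear links, and confirmed outcomes
#' \eqn{\nu_{ij}} from the conditional multinomial
#' (\code{\link{nuOutcomeProbs}}). Every visit is confirmed (design
#' \eqn{C_{1,J}}); reduced confirmation designs are applied afterwards with
#' \code{\link{applyConfirmation}} so that all derived datasets share the
#' same master draw. Distinct substreams (Z, K, outcomes) are derived from
#' \code{seed}, so changing e.g. the confirmation step never perturbs the
#' master data.
#'
#' @param scenario an \code{\link{ocScenario}}.
#' @param design an \code{\link{surveyDesign}}.
#' @param seed integer seed.
#' @param K optional precomputed K matrix (overrides the generator).
#' @return an \linkS4class{ocSurvey} with \code{nu} at every visit and the
#'   latent states in \code{trueState()}.
#' @export
simulateUnambiguous <- function(scenario, design, seed = 1L, K = NULL) {
  stopifnot(inherits(scenario, "ocScenario"),
            inherits(design, "ocDesignSpec"))
  n <- design$nSites; J <- design$nVisits
  set.seed(.deriveSeed(seed, 1L))
  Z <- stats::rbinom(n, 1L, scenario$psi)
  if (is.null(K)) K <- generateK(design, seed)
  stopifnot(nrow(K) == n, ncol(K) == J)

  kvec <- as.vector(t(K))                      # site-major visit order
  s1 <- detectionProb(scenario$betaS1, kvec)
  s0 <- detectionProb(scenario$betaS0, kvec)
  zvec <- rep(Z, each = J)

  P <- matrix(0, length(kvec), 4L)
  occ <- zvec == 1L
  if (any(occ)) P[occ, ] <- nuOutcomeProbs(s1[occ], s0[occ], z = 1)
  if (any(!occ)) P[!occ, ] <- nuOutcomeProbs(s1[!occ], s0[!occ], z = 0)

  set.seed(.deriveSeed(seed, 3L))
  u <- stats::runif(length(kvec))
  c1 <- P[, 1L]; c2 <- c1 + P[, 2L]; c3 <- c2 + P[, 3L]
  nu <- (u > c1) + (u > c2) + (u > c3)          # 0..3

  visits <- data.frame(site = rep(seq_len(n), each = J),
                       visit = rep(seq_len(J), times = n),
                       K = kvec,
                       y_ambig = as.integer(nu %in% 1:3),
                       nu = as.integer(nu),
                       confirmed = 1L)
  ocSurvey(visits, trueZ = stats::setNames(as.numeric(Z), seq_len(n)),
           scenario = list(label = scenario$label, psi = scenario$psi,
                           betaS1 = scenario$betaS1,
                           betaS0 = scenario$betaS0, seed = seed))
}

#' Derive REMOVE / IGNORE detection histories from confirmed outcomes
#'
#' \code{y_ambig} (the IGNORE history) is 1 when any auto ID named the
#' focal species (\eqn{\nu \in \{1,2,3\}}); \code{y_confirmed} (the REMOVE
#' history) is 1 only when at least one auto ID was verified
#' (\eqn{\nu \in \{2,3\}}).
#'
#' @param survey an \linkS4class{ocSurvey} with \code{nu} at every visit.
#' @return list with \code{yAmbig} and \code{yConfirmed}
#'   (\code{nSites x J} matrices) and the matching \code{K} matrix.
#' @export
deriveHistories <- function(survey) {
  v <- surveyData(survey)
  if (any(is.na(v$nu))) stop("nu missing at some visits; cannot derive histories")
  sites <- unique(v$site)
  J <- max(table(v$site))
  if (!all(table(v$site) == J)) stop("ragged designs not supported here")
  ord <- order(match(v$site, sites), v$visit)
  shape <- function(x) matrix(x[ord], nrow = length(sites), ncol = J,
                              byrow = TRUE, dimnames = list(sites, NULL))
  list(yAmbig = shape(as.integer(v$nu %in% 1:3)),
       yConfirmed = shape(as.integer(v$nu %in% 2:3)),
       K = shape(v$K))
}

#' Apply a reduced confirmation design to a fully confirmed survey
#'
#' Selects \code{round(p * n)} sites (round half up) uniformly at random;
#' within each selected site, \code{d} visits are confirmed with ambiguous
#' detections taking priority over non-detections (ties broken uniformly at
#' random). Unconfirmed visits keep only the ambiguous indicator: their
#' \code{nu} is masked to \code{NA}. The site-selection permutation depends
#' only on \code{seed}, so designs with increasing \code{p} confirm nested
#' site sets, reducing Monte-Carlo differences between designs.
#'
#' @param survey a fully confirmed \linkS4class{ocSurvey}.
#' @param cd a \code{\link{confirmationDesign}}.
#' @param seed integer seed for site selection and tie-breaking.
#' @return an \linkS4class{ocSurvey} with the confirmation pattern applied.
#' @export
applyConfirmation <- function(survey, cd, seed = 1L) {
  stopifnot(inherits(cd, "ocConfirmationDesign"))
  v <- surveyData(survey)
  if (any(is.na(v$nu))) stop("expected a fully confirmed survey")
  sites <- unique(v$site)
  n <- length(sites)
  Jmin <- min(table(v$site))
  if (cd$d > Jmin) stop("d exceeds the number of visits at some site")
  nSel <- floor(cd$p * n + 0.5)

  set.seed(.deriveSeed(seed, 4L))
  perm <- sample.int(n)
  chosen <- sites[perm[seq_len(nSel)]]

  set.seed(.deriveSeed(seed, 5L))
  tie <- stats::runif(nrow(v))
  v$confirmed <- 0L
  for (s in chosen) {
    rows <- which(v$site == s)
    ord <- rows[order(-v$y_ambig[rows], tie[rows])]
    v$confirmed[ord[seq_len(cd$d)]] <- 1L
  }
  v$nu[v$confirmed == 0L] <- NA_integer_
  ocSurvey(v, siteCovs = survey@siteCovs, trueZ = survey@trueZ,
           scenario = survey@scenario)
}

#' Shared-data bundles for comparing approaches and confirmation designs
#'
#' For each replicate, one master fully confirmed dataset is drawn and all
#' comparison datasets are deterministic functions of it: the REMOVE and
#' IGNORE detection histories and one masked survey per requested
#' confirmation design. Sharing the master draw minimizes Monte-Carlo error
#' in between-approach comparisons. Bundles are reproducible bit-for-bit
#' from \code{seed}.
#'
#' @param scenario an \code{\link{ocScenario}}.
#' @param design an \code{\link{surveyDesign}}.
#' @param nDatasets number of replicates.
#' @param seed master seed; replicate \code{r} uses a seed derived from
#'   \code{(seed, r)}.
#' @param designs list of \code{\link{confirmationDesign}} objects to
#'   materialize per replicate (may be empty).
#' @return list of bundles, each with elements \code{master}
#'   (\linkS4class{ocSurvey}), \code{remove}, \code{ignore}, \code{K}
#'   (matrices) and \code{variants} (named list of masked surveys).
#' @export
scenarioBundles <- function(scenario, design, nDatasets, seed = 1L,
                            designs = list()) {
  stopifnot(nDatasets >= 1)
  lapply(seq_len(nDatasets), function(r) {
    rs <- .deriveSeed(seed, 100L, r)
    master <- simulateUnambiguous(scenario, design, seed = rs)
    h <- deriveHistories(master)
    variants <- lapply(designs, function(cd) applyConfirmation(master, cd, seed = rs))
    if (length(designs))
      names(variants) <- vapply(designs, .designLabel, "")
    list(master = master, remove = h$yConfirmed, ignore = h$yAmbig,
         K = h$K, variants = variants, seed = rs)
  })
}
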