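#' Negative log-likelihood of the extended observation-confirmation model
#'
#' Evaluates the mixed-confirmation likelihood: per site, a two-component
#' mixture over the latent occupancy state in which each confirmed visit
#' contributes its multinomial outcome probability
#' (\code{\link{nuOutcomeProbs}}) and each unconfirmed visit contributes a
#' Bernoulli term in the ambiguous detection probability (\eqn{p_{11}} when
#' occupied, \eqn{p_{10}} when not). Occupancy and the two detection
#' probabilities are driven by logit-linear predictors defined by
#' \code{spec}. All computation is on the log scale with a log-sum-exp over
#' the two occupancy states; probabilities coming through the links are
#' clipped to \code{[1e-12, 1 - 1e-12]} so optimizer excursions to extreme
#' coefficients stay finite, while the structural zeros of the unoccupied
#' outcome distribution remain exact.
#'
#' @param params an \code{ocParams} object (see \code{\link{parameterSet}})
#'   with coefficient vectors matching \code{spec}.
#' @param survey an \linkS4class{ocSurvey}.
#' @param spec a \code{\link{covariateSpec}}.
#' @return A list of class \code{"ocLik"}: \code{value} (the negative
#'   log-likelihood) and \code{perSite} (per-site log-likelihood
#'   contributions; \code{-sum(perSite) == value}).
#' @export
ocNegLogLik <- function(params, survey, spec = covariateSpec()) {
  stopifnot(inherits(params, "ocParams"))
  validObject(survey)
  dd <- .buildDesign(survey, spec)
  dims <- .designDims(dd)
  if (length(params$theta) != dims[1L] || length(params$betaS1) != dims[2L] ||
      length(params$betaS0) != dims[3L])
    stop("coefficient lengths do not match the covariate specification")
  res <- .ocNLL(.flattenParams(params), dd, perSite = TRUE)
  structure(list(value = res$value,
                 perSite = stats::setNames(res$perSite, dd$sites)),
            class = "ocLik")
}

#' @export
print.ocLik <- function(x, ...) {
  cat("negative log-likelihood:", format(x$value, digits = 8), "over",
      length(x$perSite), "sites\n")
  invisible(x)
}

# core evaluator on a prebuilt design; par in optimizer order
.ocNLL <- function(par, dd, perSite = FALSE) {
  dims <- .designDims(dd)
  theta <- par[seq_len(dims[1L])]
  b1 <- par[dims[1L] + seq_len(dims[2L])]
  b0 <- par[dims[1L] + dims[2L] + seq_len(dims[3L])]
  psi <- .clipProb(stats::plogis(drop(dd$X %*% theta)))
  s1 <- .clipProb(stats::plogis(drop(dd$W1 %*% b1)))
  s0 <- .clipProb(stats::plogis(drop(dd$W0 %*% b0)))

  conf <- dd$confirmed == 1L
  nu <- dd$nu
  y <- dd$y
  lc1 <- numeric(length(y))  # log Pr(visit obs | z = 1)
  lc0 <- numeric(length(y))  # log Pr(visit obs | z = 0)

  if (any(conf)) {
    nuc <- nu[conf]
    s1c <- s1[conf]; s0c <- s0[conf]
    l1 <- numeric(sum(conf)); l0 <- numeric(sum(conf))
    i0 <- nuc == 0L; i1 <- nuc == 1L; i2 <- nuc == 2L; i3 <- nuc == 3L
    l1[i0] <- log1p(-s0c[i0]) + log1p(-s1c[i0])
    l1[i1] <- log(s0c[i1]) + log1p(-s1c[i1])
    l1[i2] <- log(s1c[i2]) + log1p(-s0c[i2])
    l1[i3] <- log(s0c[i3]) + log(s1c[i3])
    l0[i0] <- log1p(-s0c[i0])
    l0[i1] <- log(s0c[i1])
    l0[i2 | i3] <- -Inf   # structural zeros: no verified IDs when unoccupied
    lc1[conf] <- l1
    lc0[conf] <- l0
  }
  if (any(!conf)) {
    yu <- y[!conf]
    p11 <- .clipProb(s1[!conf] + s0[!conf] - s1[!conf] * s0[!conf])
    p10 <- s0[!conf]
    lc1[!conf] <- yu * log(p11) + (1 - yu) * log1p(-p11)
    lc0[!conf] <- yu * log(p10) + (1 - yu) * log1p(-p10)
  }

  acc <- rowsum(cbind(lc1, lc0), dd$siteIdx, reorder = TRUE)
  lA <- log(psi) + acc[, 1L]
  lB <- log1p(-psi) + acc[, 2L]
  m <- pmax(lA, lB)
  siteLL <- m + log(exp(lA - m) + exp(lB - m))
  # both branches -Inf cannot occur after clipping, but guard anyway
  siteLL[!is.finite(m)] <- -Inf
  val <- -sum(siteLL)
  if (!is.finite(val)) val <- .Machine$double.xmax / 1e10
  if (perSite) list(value = val, perSite = siteLL) else val
}

#' Negative log-likelihood of the standard single-season occupancy model
#'
#' The MacKenzie-style zero-inflated detection-history likelihood used by
#' the REMOVE and IGNORE analyses:
#' \deqn{L = \prod_i \left[\psi_i \prod_j p_{ij}^{y_{ij}}
#'   (1-p_{ij})^{1-y_{ij}} + (1-\psi_i)\, I(\mathrm{all}\ y_{ij}=0)\right]}
#' with logit links on \eqn{\psi} and \eqn{p}. Detection heterogeneity is
#' carried by \code{detect}, by default \code{~ logK} mirroring the OC
#' model's call-quality structure; pass \code{detect = ~ 1} for
#' intercept-only detection.
#'
#' @param params list with components \code{theta} (occupancy coefficients)
#'   and \code{betaP} (detection coefficients).
#' @param history n x J binary detection matrix (no missing cells).
#' @param K n x J activity matrix (needed when \code{detect} uses
#'   \code{logK}); may be NULL for intercept-only detection.
#' @param occupancy,detect one-sided formulas for the two predictors.
#' @param siteCovs optional site-covariate data.frame (column \code{site}).
#' @return A list of class \code{"ocLik"} (total and per-site
#'   contributions).
#' @export
standardNegLogLik <- function(params, history, K = NULL, occupancy = ~ 1,
                              detect = ~ logK, siteCovs = NULL) {
  dd <- .buildStdDesign(history, K, occupancy, detect, siteCovs)
  if (length(params$theta) != ncol(dd$X) ||
      length(params$betaP) != ncol(dd$W))
    stop("coefficient lengths do not match the covariate specification")
  res <- .stdNLL(c(params$theta, params$betaP), dd, perSite = TRUE)
  structure(list(value = res$value, perSite = res$perSite), class = "ocLik")
}

.buildStdDesign <- function(history, K, occupancy = ~ 1, detect = ~ logK,
                            siteCovs = NULL) {
  history <- as.matrix(history)
  if (nrow(history) < 1L || ncol(history) < 1L)
    stop("empty detection history")
  if (any(is.na(history)) || !all(history %in% c(0, 1)))
    stop("detection history must be binary with no missing cells")
  n <- nrow(history); J <- ncol(history)
  vdat <- data.frame(site = rep(seq_len(n), each = J))
  if (!is.null(K)) {
    K <- as.matrix(K)
    stopifnot(dim(K) == dim(history))
    if (any(K < 0)) stop("K must be >= 0")
    vdat$K <- as.vector(t(K))
    vdat$logK <- log(vdat$K + 1)
  }
  sdat <- if (is.null(siteCovs)) data.frame(site = seq_len(n)) else siteCovs
  X <- stats::model.matrix(occupancy, sdat)
  W <- stats::model.matrix(detect, vdat)
  list(X = X, W = W, y = as.vector(t(history)), siteIdx = vdat$site,
       n = n)
}

.stdNLL <- function(par, dd, perSite = FALSE) {
  k <- ncol(dd$X)
  psi <- .clipProb(stats::plogis(drop(dd$X %*% par[seq_len(k)])))
  p <- .clipProb(stats::plogis(drop(dd$W %*% par[k + seq_len(ncol(dd$W))])))
  lvis <- dd$y * log(p) + (1 - dd$y) * log1p(-p)
  accA <- rowsum(lvis, dd$siteIdx, reorder = TRUE)[, 1L]
  anyDet <- rowsum(dd$y, dd$siteIdx, reorder = TRUE)[, 1L] > 0
  lA <- log(psi) + accA
  lB <- ifelse(anyDet, -Inf, log1p(-psi))
  m <- pmax(lA, lB)
  siteLL <- m + log(exp(lA - m) + pmax(exp(lB - m), 0))
  siteLL[!is.finite(m)] <- -Inf
  val <- -sum(siteLL)
  if (!is.finite(val)) val <- .Machine$double.xmax / 1e10
  if (perSite) list(value = val, perSite = siteLL) else val
}

#' Brute-force likelihood by exhaustive enumeration (test oracle)
#'
#' Computes the probability of the observed dataset by explicit summation
#' over all latent occupancy configurations, multiplying exact per-visit
#' outcome probabilities (multinomial at confirmed visits, Bernoulli at
#' unconfirmed ones). No log-scale tricks and no clipping: an independent
#' check of \code{\link{ocNegLogLik}} on tiny designs. Refuses designs with
#' more than 3 sites or more than 3 visits at any site.
#'
#' @inheritParams ocNegLogLik
#' @return The probability of the observed data (a bare number).
#' @export
enumLikelihood <- function(params, survey, spec = covariateSpec()) {
  stopifnot(inherits(params, "ocParams"))
  dd <- .buildDesign(survey, spec)
  n <- length(dd$sites)
  J <- max(table(dd$siteIdx))
  if (n > 3L || J > 3L)
    stop("design too large to enumerate (need n <= 3 and J <= 3)")
  psi <- stats::plogis(drop(dd$X %*% params$theta))
  s1 <- stats::plogis(drop(dd$W1 %*% params$betaS1))
  s0 <- stats::plogis(drop(dd$W0 %*% params$betaS0))

  visitProb <- function(i, z) {
    rows <- which(dd$siteIdx == i)
    pr <- 1
    for (r in rows) {
      if (dd$confirmed[r] == 1L) {
        probs <- nuOutcomeProbs(s1[r], s0[r], z)
        pr <- pr * probs[[dd$nu[r] + 1L]]
      } else {
        ap <- ambiguousProbs(s1[r], s0[r])
        pd <- if (z == 1) ap$p11 else ap$p10
        pr <- pr * if (dd$y[r] == 1L) pd else 1 - pd
      }
    }
    pr
  }
  total <- 0
  for (code in 0:(2^n - 1)) {
    zvec <- as.integer(intToBits(code))[seq_len(n)]
    w <- prod(ifelse(zvec == 1, psi, 1 - psi))
    pr <- 1
    for (i in seq_len(n)) pr <- pr * visitProb(i, zvec[i])
    total <- total + w * pr
  }
  total
}
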