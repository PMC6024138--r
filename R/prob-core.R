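#' Inverse logit (logistic) link
#'
#' Maps a linear predictor on the logit scale to a probability. Numerically
#' stable for large \code{|x|}: saturates to 0/1 without overflow.
#'
#' @param x Numeric vector of finite linear-predictor values.
#' @return Probabilities in \code{[0, 1]}.
#' @examples
#' inverseLogit(0)      # 0.5
#' inverseLogit(-2.2)   # ~0.10, a 10% baseline misidentification rate
#' @export
inverseLogit <- function(x) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) stop("non-finite linear predictor")
  stats::plogis(x)
}

#' Logit link
#'
#' @param p Probabilities in (0, 1).
#' @return Log-odds.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p), all(p > 0 & p < 1))
  stats::qlogis(p)
}

#' Visit-level detection probability from the activity covariate
#'
#' Evaluates the logit-linear model
#' \deqn{logit(s) = \beta_0 + \beta_1 \log(K + 1)}
#' where \code{K} is the number of automatically classified recordings
#' (auto IDs) obtained during a visit, used as a proxy for overall call
#' quality. The \code{+1} offset keeps the logged value positive; the same
#' form is used for the correct-classification probability \eqn{s_1} and the
#' misidentification probability \eqn{s_0}.
#'
#' @param beta Length-2 coefficient vector \code{(intercept, slope)} on the
#'   logit scale.
#' @param K Nonnegative activity values. Integers in real data; continuous
#'   values are accepted (the link is defined for any \code{K >= 0}).
#' @return Detection probabilities, one per element of \code{K}.
#' @examples
#' detectionProb(c(0, 1.6), 0)        # intercept only: 0.5
#' detectionProb(c(-2.2, 1.5), 0:10)  # increasing in K for positive slope
#' @export
detectionProb <- function(beta, K) {
  stopifnot(is.numeric(beta), length(beta) == 2L, all(is.finite(beta)))
  if (!is.numeric(K) || any(!is.finite(K)) || any(K < 0))
    stop("K must be finite and >= 0 (negative K signals corrupt input)")
  inverseLogit(beta[1L] + beta[2L] * log(K + 1))
}

#' Ambiguous detection probabilities from the component probabilities
#'
#' Given the per-visit probabilities of at least one correctly classified
#' (\code{s1}) and at least one misclassified (\code{s0}) recording of the
#' focal species, returns the visit-level ambiguous detection probabilities:
#' \deqn{p_{11} = s_1 + s_0 - s_1 s_0 \quad (occupied), \qquad p_{10} = s_0
#' \quad (unoccupied).}
#'
#' @param s1,s0 Probabilities in \code{[0, 1]} (vectorized, recycled).
#' @return A list with components \code{p11} and \code{p10}.
#' @examples
#' ambiguousProbs(0.8, 0.1)  # p11 = 0.82, p10 = 0.1
#' @export
ambiguousProbs <- function(s1, s0) {
  .checkProb(s1, "s1")
  .checkProb(s0, "s0")
  list(p11 = s1 + s0 - s1 * s0, p10 = s0 + 0 * s1)
}

#' Outcome probabilities for the confirmed (unambiguous) visit result
#'
#' A confirmed visit yields a four-category outcome \eqn{\nu} describing the
#' agreement between the automatic classifications and their expert review:
#' 0 = nothing to confirm (no auto ID named the focal species), 1 = all
#' overturned, 2 = all verified, 3 = mixed. Conditional on site occupancy
#' \code{z} the outcome is multinomial with probabilities
#' \deqn{z = 1: \{(1-s_0)(1-s_1),\; s_0(1-s_1),\; s_1(1-s_0),\; s_0 s_1\}}
#' \deqn{z = 0: \{1-s_0,\; s_0,\; 0,\; 0\}}
#' At an unoccupied site every focal auto ID is a misidentification, so the
#' only possible outcomes are "nothing to confirm" (probability \eqn{1-s_0})
#' and "all overturned" (probability \eqn{s_0}); verified outcomes have
#' probability exactly zero. This assignment keeps
#' \eqn{\Pr(\nu \in \{1,2,3\} \mid z)} equal to the ambiguous detection
#' probability (\eqn{p_{11}} or \eqn{p_{10}}).
#'
#' @param s1,s0 Probabilities in \code{[0, 1]} (vectorized, equal length or
#'   scalar).
#' @param z Occupancy state, 0 or 1 (scalar).
#' @return For scalar input, a named numeric vector over
#'   \code{nu0 ... nu3}; for vector input an \code{n x 4} matrix with those
#'   column names. Rows sum to 1.
#' @examples
#' nuOutcomeProbs(0.8, 0.1, z = 1)
#' nuOutcomeProbs(0.8, 0.3, z = 0)  # (0.7, 0.3, 0, 0)
#' @export
nuOutcomeProbs <- function(s1, s0, z) {
  .checkProb(s1, "s1")
  .checkProb(s0, "s0")
  stopifnot(length(z) == 1L, z %in% c(0, 1))
  n <- max(length(s1), length(s0))
  s1 <- rep_len(s1, n)
  s0 <- rep_len(s0, n)
  out <- if (z == 1) {
    cbind(nu0 = (1 - s0) * (1 - s1), nu1 = s0 * (1 - s1),
          nu2 = s1 * (1 - s0), nu3 = s0 * s1)
  } else {
    cbind(nu0 = 1 - s0, nu1 = s0, nu2 = 0 * s0, nu3 = 0 * s0)
  }
  if (n == 1L) out[1L, ] else out
}

#' Model coefficients for the observation-confirmation occupancy model
#'
#' Bundles the occupancy coefficients \code{theta} and the detection
#' coefficient vectors for the true-detection (\code{betaS1}) and
#' misidentification (\code{betaS0}) linear predictors, all on the logit
#' scale.
#'
#' @param theta Occupancy coefficients (site-level linear predictor).
#' @param betaS1 Coefficients for \eqn{logit(s_1)}.
#' @param betaS0 Coefficients for \eqn{logit(s_0)}.
#' @return An object of class \code{"ocParams"}.
#' @export
parameterSet <- function(theta, betaS1, betaS0) {
  for (v in list(theta, betaS1, betaS0))
    if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)))
      stop("all coefficient vectors must be finite and non-empty")
  structure(list(theta = as.numeric(theta), betaS1 = as.numeric(betaS1),
                 betaS0 = as.numeric(betaS0)),
            class = "ocParams")
}

#' @export
print.ocParams <- function(x, ...) {
  cat("OC model coefficients (logit scale)\n")
  cat("  occupancy theta :", format(x$theta, digits = 4), "\n")
  cat("  detect  beta_s1 :", format(x$betaS1, digits = 4), "\n")
  cat("  misID   beta_s0 :", format(x$betaS0, digits = 4), "\n")
  invisible(x)
}

# flatten / unflatten between ocParams and the optimizer's vector
.flattenParams <- function(params) {
  c(params$theta, params$betaS1, params$betaS0)
}

.unflattenParams <- function(par, dims) {
  i1 <- seq_len(dims[1L])
  i2 <- dims[1L] + seq_len(dims[2L])
  i3 <- dims[1L] + dims[2L] + seq_len(dims[3L])
  parameterSet(par[i1], par[i2], par[i3])
}

.checkProb <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("%s must be a probability in [0, 1]", name))
  invisible(TRUE)
}

# clip a probability away from {0, 1} before logging; structural zeros are
# handled separately and never pass through here
.clipProb <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
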