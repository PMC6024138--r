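#' Class "ocFit": a maximum-likelihood fit
#'
#' Result of fitting the observation-confirmation model
#' (\code{\link{fitOC}}) or the standard occupancy model
#' (\code{\link{fitStandard}}). Coefficients live on the logit scale;
#' \code{psiHat}/\code{ciPsi} give the occupancy estimate and its interval
#' on the probability scale (intercept-only occupancy; \code{NA} when
#' occupancy has covariates). \code{status} classifies the outcome:
#' \code{converged}, or one of the failure categories
#' \code{nll_eval_failed} (objective not evaluable at the starting values),
#' \code{optimizer_failed}, \code{hessian_failed} (Hessian not invertible /
#' not positive definite), \code{unreasonable} (estimates or interval
#' widths beyond the plausibility thresholds, see
#' \code{\link{classifyConvergence}}).
#'
#' @slot approach character: "MODEL", "REMOVE", "IGNORE" or "STANDARD".
#' @slot estimates named numeric coefficient vector (logit scale).
#' @slot se standard errors (same order).
#' @slot vcov variance-covariance matrix (inverted Hessian).
#' @slot ciLogit two-column matrix of +/- 2 SE intervals.
#' @slot psiHat,ciPsi occupancy estimate and interval, probability scale.
#' @slot status character status code.
#' @slot nll final negative log-likelihood.
#' @slot nRestarts integer, restarts consumed.
#' @slot details list (optimizer code, seed, start values).
#' @export
setClass("ocFit",
  representation(approach = "character", estimates = "numeric",
                 se = "numeric", vcov = "matrix", ciLogit = "matrix",
                 psiHat = "numeric", ciPsi = "numeric", status = "character",
                 nll = "numeric", nRestarts = "integer", details = "list"))

setValidity("ocFit", function(object) {
  ok <- c("converged", "nll_eval_failed", "optimizer_failed",
          "hessian_failed", "unreasonable")
  if (!object@status %in% ok) return("unknown status code")
  if (object@status == "converged") {
    if (any(!is.finite(object@se)) || any(object@se < 0))
      return("converged fit must carry finite nonnegative SEs")
    if (any(object@ciLogit[, 1L] > object@estimates) ||
        any(object@ciLogit[, 2L] < object@estimates))
      return("interval endpoints must bracket the estimates")
  }
  TRUE
})

setMethod("show", "ocFit", function(object) {
  cat(sprintf("ocFit [%s] status: %s\n", object@approach, object@status))
  if (length(object@estimates)) {
    tab <- data.frame(estimate = object@estimates, se = object@se,
                      lower = object@ciLogit[, 1L],
                      upper = object@ciLogit[, 2L])
    print(round(tab, 4))
  }
  if (is.finite(object@psiHat))
    cat(sprintf("psi-hat = %.4f  (%.4f, %.4f)\n", object@psiHat,
                object@ciPsi[1L], object@ciPsi[2L]))
  cat("negative log-likelihood:", format(object@nll, digits = 8), "\n")
  invisible(NULL)
})

#' @describeIn ocFit-accessors coefficient estimates (logit scale)
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))
#' @describeIn ocFit-accessors standard errors
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))
#' @describeIn ocFit-accessors occupancy estimate, probability scale
#' @export
setGeneric("psiHat", function(object) standardGeneric("psiHat"))
#' @describeIn ocFit-accessors occupancy interval, probability scale
#' @export
setGeneric("psiInterval", function(object) standardGeneric("psiInterval"))
#' @describeIn ocFit-accessors status code
#' @export
setGeneric("fitStatus", function(object) standardGeneric("fitStatus"))

#' Accessors for ocFit objects
#' @param object an \linkS4class{ocFit}.
#' @name ocFit-accessors
NULL

#' @rdname ocFit-accessors
#' @export
setMethod("estimates", "ocFit", function(object) object@estimates)
#' @rdname ocFit-accessors
#' @export
setMethod("stdErrors", "ocFit", function(object) object@se)
#' @rdname ocFit-accessors
#' @export
setMethod("psiHat", "ocFit", function(object) object@psiHat)
#' @rdname ocFit-accessors
#' @export
setMethod("psiInterval", "ocFit", function(object) object@ciPsi)
#' @rdname ocFit-accessors
#' @export
setMethod("fitStatus", "ocFit", function(object) object@status)

#' Fitting options
#'
#' @param nRestarts independent random starts to attempt (the first
#'   successful one is kept). Default 1, so failure rates reflect single
#'   attempts.
#' @param startSD standard deviation of the mean-zero normal start values.
#' @param maxit optimizer iteration limit.
#' @param seed seed for the start-value draws.
#' @return classed list \code{"ocFitOptions"}.
#' @export
fitOptions <- function(nRestarts = 1L, startSD = 0.5, maxit = 500L,
                       seed = 1L) {
  stopifnot(nRestarts >= 1, startSD > 0, maxit >= 1)
  structure(list(nRestarts = as.integer(nRestarts), startSD = startSD,
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "ocFitOptions")
}

#' Wald (+/- 2 SE) interval
#'
#' Approximate 95% interval on the scale of the estimate. For occupancy on
#' the probability scale, compute the interval on the logit scale and map
#' the endpoints through \code{\link{inverseLogit}}, which keeps the
#' interval inside (0, 1).
#'
#' @param estimate point estimate.
#' @param se nonnegative standard error.
#' @return numeric \code{c(lower, upper)}.
#' @export
waldInterval <- function(estimate, se) {
  stopifnot(is.finite(estimate), is.finite(se), se >= 0)
  c(estimate - 2 * se, estimate + 2 * se)
}

#' Classify a fit against the plausibility thresholds
#'
#' A fit counts as converged only when the Hessian was invertible with
#' positive diagonal variance, every logit-scale estimate satisfies
#' \code{|estimate| <= 10}, every logit-scale interval has width
#' \code{<= 30}, and the probability-scale occupancy interval has width
#' \code{<= 0.7}. The absolute-value reading of the estimate bound is
#' applied symmetrically: a logit-scale coefficient of -12 is as
#' implausible as +12. Anything else is \code{"unreasonable"}.
#'
#' @param estimates logit-scale coefficients.
#' @param ciLogit two-column interval matrix.
#' @param ciPsi probability-scale occupancy interval (may be \code{NA}
#'   when occupancy has covariates; the width rule is then skipped).
#' @param hessianOK logical, Hessian inverted successfully.
#' @return status string (\code{"converged"}, \code{"unreasonable"} or
#'   \code{"hessian_failed"}).
#' @export
classifyConvergence <- function(estimates, ciLogit, ciPsi, hessianOK = TRUE) {
  if (!isTRUE(hessianOK)) return("hessian_failed")
  widths <- ciLogit[, 2L] - ciLogit[, 1L]
  ok <- all(abs(estimates) <= 10) && all(widths <= 30) &&
    (any(is.na(ciPsi)) || (ciPsi[2L] - ciPsi[1L]) <= 0.7)
  if (ok) "converged" else "unreasonable"
}

# central-difference Hessian of f at x
.numHessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(abs(x), 1)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# shared ML driver: nll(par) minimized from random starts; returns ocFit
.mlFit <- function(nll, npar, coefNames, approach, options,
                   psiIndex = 1L, psiScalar = TRUE) {
  status <- "nll_eval_failed"
  best <- NULL
  nUsed <- 0L
  for (r in seq_len(options$nRestarts)) {
    nUsed <- r
    set.seed(.deriveSeed(options$seed, 7L, r))
    start <- stats::rnorm(npar, 0, options$startSD)
    f0 <- tryCatch(nll(start), error = function(e) NA_real_)
    if (!is.finite(f0)) { status <- "nll_eval_failed"; next }
    opt <- tryCatch(
      suppressWarnings(stats::nlm(nll, start, iterlim = options$maxit)),
      error = function(e) NULL)
    if (is.null(opt) || !opt$code %in% c(1L, 2L, 3L)) {
      status <- "optimizer_failed"; next
    }
    best <- opt
    status <- "optimized"
    break
  }
  mkFail <- function(st) new("ocFit", approach = approach,
    estimates = stats::setNames(rep(NA_real_, npar), coefNames),
    se = rep(NA_real_, npar), vcov = matrix(NA_real_, npar, npar),
    ciLogit = matrix(NA_real_, npar, 2L), psiHat = NA_real_,
    ciPsi = c(NA_real_, NA_real_), status = st, nll = NA_real_,
    nRestarts = nUsed, details = list())
  if (is.null(best)) return(mkFail(status))

  est <- stats::setNames(best$estimate, coefNames)
  H <- tryCatch(.numHessian(nll, best$estimate), error = function(e) NULL)
  V <- if (is.null(H) || any(!is.finite(H))) NULL else
    tryCatch(solve(H), error = function(e) NULL)
  hessOK <- !is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)
  if (!hessOK) {
    out <- mkFail("hessian_failed")
    out@estimates <- est
    out@nll <- best$minimum
    return(out)
  }
  se <- sqrt(diag(V))
  ci <- t(vapply(seq_len(npar), function(i) waldInterval(est[i], se[i]),
                 numeric(2L)))
  rownames(ci) <- coefNames
  if (psiScalar) {
    psiH <- unname(inverseLogit(est[psiIndex]))
    ciP <- unname(inverseLogit(ci[psiIndex, ]))
  } else {
    psiH <- NA_real_; ciP <- c(NA_real_, NA_real_)
  }
  status <- classifyConvergence(est, ci, ciP, hessianOK = TRUE)
  new("ocFit", approach = approach, estimates = est, se = se, vcov = V,
      ciLogit = ci, psiHat = psiH, ciPsi = ciP, status = status,
      nll = best$minimum, nRestarts = nUsed,
      details = list(code = best$code, iterations = best$iterations,
                     seed = options$seed))
}

#' Fit the observation-confirmation model by maximum likelihood
#'
#' Minimizes the negative log-likelihood (\code{\link{ocNegLogLik}}) with
#' an unconstrained quasi-Newton search (\code{nlm}, finite-difference
#' gradients) from random normal starting values, inverts a
#' central-difference Hessian at the optimum for the coefficient
#' covariance, and classifies the outcome with
#' \code{\link{classifyConvergence}}. Refitting with the same options is
#' deterministic.
#'
#' @param survey an \linkS4class{ocSurvey}.
#' @param spec a \code{\link{covariateSpec}}.
#' @param options a \code{\link{fitOptions}}.
#' @return an \linkS4class{ocFit} with approach \code{"MODEL"}.
#' @export
fitOC <- function(survey, spec = covariateSpec(), options = fitOptions()) {
  validObject(survey)
  dd <- .buildDesign(survey, spec)
  npar <- sum(.designDims(dd))
  nll <- function(par) .ocNLL(par, dd)
  .mlFit(nll, npar, .coefNames(dd), "MODEL", options,
         psiIndex = 1L, psiScalar = ncol(dd$X) == 1L)
}

#' Fit the standard occupancy model by maximum likelihood
#'
#' Same optimization and standard-error machinery as \code{\link{fitOC}},
#' applied to the standard detection-history likelihood
#' (\code{\link{standardNegLogLik}}). Used for the REMOVE analysis
#' (confirmed histories) and the IGNORE analysis (ambiguous histories).
#'
#' @param history n x J binary detection matrix.
#' @param K n x J activity matrix (or NULL with \code{detect = ~ 1}).
#' @param occupancy,detect one-sided formulas.
#' @param siteCovs optional site covariates.
#' @param options a \code{\link{fitOptions}}.
#' @param approach label stored on the fit ("STANDARD", "REMOVE",
#'   "IGNORE").
#' @return an \linkS4class{ocFit}.
#' @export
fitStandard <- function(history, K = NULL, occupancy = ~ 1, detect = ~ logK,
                        siteCovs = NULL, options = fitOptions(),
                        approach = "STANDARD") {
  dd <- .buildStdDesign(history, K, occupancy, detect, siteCovs)
  npar <- ncol(dd$X) + ncol(dd$W)
  coefNames <- c(paste0("psi_", colnames(dd$X)), paste0("p_", colnames(dd$W)))
  nll <- function(par) .stdNLL(par, dd)
  .mlFit(nll, npar, coefNames, approach, options,
         psiIndex = 1L, psiScalar = ncol(dd$X) == 1L)
}

#' Fit one of the three analysis approaches to a survey
#'
#' Dispatches on the approach tag: \code{MODEL} fits the OC model to the
#' mixed confirmed/ambiguous data; \code{REMOVE} fits the standard model to
#' the confirmed detection histories (requires every ambiguous detection to
#' be confirmed); \code{IGNORE} fits the standard model to the raw
#' ambiguous histories.
#'
#' @param survey an \linkS4class{ocSurvey}.
#' @param approach "MODEL", "REMOVE" or "IGNORE".
#' @param spec \code{\link{covariateSpec}} (MODEL).
#' @param detect detection formula for the standard model approaches.
#' @param options \code{\link{fitOptions}}.
#' @return an \linkS4class{ocFit}.
#' @export
fitApproach <- function(survey, approach = c("MODEL", "REMOVE", "IGNORE"),
                        spec = covariateSpec(), detect = ~ logK,
                        options = fitOptions()) {
  approach <- match.arg(approach)
  if (approach == "MODEL") return(fitOC(survey, spec, options))
  v <- surveyData(survey)
  if (approach == "REMOVE") {
    if (any(v$y_ambig == 1L & v$confirmed == 0L))
      stop("REMOVE requires confirmation for all visit-level ambiguous detections")
    h <- .historiesFromMixed(survey, confirmedOnly = TRUE)
  } else {
    h <- .historiesFromMixed(survey, confirmedOnly = FALSE)
  }
  fitStandard(h$y, h$K, detect = detect, options = options,
              approach = approach)
}

# build matrices from a (possibly partially confirmed) survey
.historiesFromMixed <- function(survey, confirmedOnly) {
  v <- surveyData(survey)
  sites <- unique(v$site)
  J <- max(table(v$site))
  if (!all(table(v$site) == J)) stop("ragged designs not supported here")
  ord <- order(match(v$site, sites), v$visit)
  y <- if (confirmedOnly) as.integer(!is.na(v$nu) & v$nu %in% 2:3)
       else v$y_ambig
  shape <- function(x) matrix(x[ord], nrow = length(sites), ncol = J,
                              byrow = TRUE)
  list(y = shape(y), K = shape(v$K))
}
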