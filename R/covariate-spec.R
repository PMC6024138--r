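#' Covariate specification for the occupancy and detection linear predictors
#'
#' Formulas in the style of \code{glm}: \code{occupancy} is evaluated
#' against the site-covariate table, \code{detect1} / \code{detect0}
#' against the visit table. The visit table automatically gains a
#' \code{logK} column equal to \code{log(K + 1)}, the call-quality proxy;
#' the default detection predictor is \code{~ logK} for both the
#' true-detection and misidentification probabilities. An intercept is
#' always included (formulas removing it are rejected).
#'
#' @param occupancy formula for \eqn{logit(\psi)} (site level).
#' @param detect1 formula for \eqn{logit(s_1)} (visit level).
#' @param detect0 formula for \eqn{logit(s_0)} (visit level).
#' @return An object of class \code{"ocCovariateSpec"}.
#' @examples
#' covariateSpec()                       # ~1, ~logK, ~logK
#' covariateSpec(detect0 = ~ 1)          # intercept-only misidentification
#' @export
covariateSpec <- function(occupancy = ~ 1, detect1 = ~ logK,
                          detect0 = ~ logK) {
  specs <- list(occupancy = occupancy, detect1 = detect1, detect0 = detect0)
  for (nm in names(specs)) {
    f <- specs[[nm]]
    if (!inherits(f, "formula") || length(f) != 2L)
      stop(sprintf("%s must be a one-sided formula", nm))
    if (attr(stats::terms(f), "intercept") != 1L)
      stop(sprintf("%s must keep its intercept", nm))
  }
  structure(specs, class = "ocCovariateSpec")
}

#' @export
print.ocCovariateSpec <- function(x, ...) {
  cat("covariate specification\n")
  cat("  psi:", deparse(x$occupancy), " s1:", deparse(x$detect1),
      " s0:", deparse(x$detect0), "\n")
  invisible(x)
}

# Build the design matrices used by the likelihoods.
# Returns: X (site-level, one row per site, sites in first-appearance order),
# W1/W0 (visit-level), siteIdx (visit -> row of X), plus the response columns.
.buildDesign <- function(survey, spec) {
  v <- surveyData(survey)
  v$logK <- log(v$K + 1)
  sites <- unique(v$site)
  siteIdx <- match(v$site, sites)

  sc <- survey@siteCovs
  siteTab <- if (is.null(sc)) data.frame(site = sites) else {
    if (is.null(sc$site)) stop("siteCovs must carry a 'site' column")
    m <- match(sites, sc$site)
    if (any(is.na(m))) stop("siteCovs missing rows for some sites")
    sc[m, , drop = FALSE]
  }

  mm <- function(f, dat, what) {
    tt <- tryCatch(stats::model.matrix(f, dat), error = function(e)
      stop(sprintf("%s formula term not found in data: %s", what,
                   conditionMessage(e)), call. = FALSE))
    tt
  }
  list(X = mm(spec$occupancy, siteTab, "occupancy"),
       W1 = mm(spec$detect1, v, "detect1"),
       W0 = mm(spec$detect0, v, "detect0"),
       siteIdx = siteIdx, sites = sites,
       nu = v$nu, y = v$y_ambig, confirmed = v$confirmed)
}

# parameter dimensions implied by a design
.designDims <- function(dd) c(ncol(dd$X), ncol(dd$W1), ncol(dd$W0))

# coefficient names in optimizer order
.coefNames <- function(dd) {
  c(paste0("psi_", colnames(dd$X)), paste0("s1_", colnames(dd$W1)),
    paste0("s0_", colnames(dd$W0)))
}

# Parse a one-sided formula given as a string (CLI surface).
.parseFormula <- function(s) {
  f <- tryCatch(stats::as.formula(s), error = function(e)
    stop(sprintf("cannot parse formula '%s'", s), call. = FALSE))
  f
}
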