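#' @import methods
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Class "ocSurvey": a visit-level acoustic survey dataset
#'
#' Long-format container for the data consumed by the
#' observation-confirmation occupancy model. Each row of \code{visits} is
#' one visit (one detector-night) and carries: \code{site} (identifier),
#' \code{visit} (index within site), \code{K} (number of auto-classified
#' recordings), \code{y_ambig} (0/1 ambiguous detection: at least one auto
#' ID named the focal species), \code{nu} (four-category confirmed outcome,
#' \code{NA} at unconfirmed visits), \code{confirmed} (0/1 confirmation
#' indicator), plus any visit-level covariate columns. Simulated surveys
#' additionally store the latent occupancy states and the generating
#' scenario.
#'
#' Validity enforces: \code{confirmed = 1} implies \code{nu} present;
#' wherever \code{nu} is present, \code{y_ambig = 1} exactly when
#' \code{nu} is 1, 2 or 3; \code{K >= 0}; every site has at least one visit.
#'
#' @slot visits data.frame of visit records (see above).
#' @slot siteCovs optional data.frame of site-level covariates, one row per
#'   site, with a \code{site} column.
#' @slot trueZ optional numeric vector of latent occupancy states (simulated
#'   data only), named by site.
#' @slot scenario optional list describing the generating scenario.
#' @aliases ocSurvey
#' @export
setClass("ocSurvey",
  representation(visits = "data.frame", siteCovs = "dfOrNULL",
                 trueZ = "numericOrNULL", scenario = "listOrNULL"),
  prototype(siteCovs = NULL, trueZ = NULL, scenario = NULL))

setValidity("ocSurvey", function(object) {
  v <- object@visits
  need <- c("site", "visit", "K", "y_ambig", "nu", "confirmed")
  miss <- setdiff(need, names(v))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(v) == 0L) return("survey has no visits")
  if (any(!is.finite(v$K)) || any(v$K < 0)) return("K must be finite and >= 0")
  if (!all(v$y_ambig %in% c(0L, 1L))) return("y_ambig must be 0/1")
  if (!all(v$confirmed %in% c(0L, 1L))) return("confirmed must be 0/1")
  if (!all(is.na(v$nu) | v$nu %in% 0:3)) return("nu must be in {0,1,2,3} or NA")
  bad <- v$confirmed == 1L & is.na(v$nu)
  if (any(bad))
    return(sprintf("confirmed visit without a nu outcome (site %s, visit %s)",
                   v$site[which(bad)[1L]], v$visit[which(bad)[1L]]))
  has <- !is.na(v$nu)
  if (any(v$y_ambig[has] != as.integer(v$nu[has] %in% 1:3)))
    return("y_ambig inconsistent with nu (y_ambig = 1 iff nu in {1,2,3})")
  if (!is.null(object@trueZ) && !all(object@trueZ %in% c(0, 1)))
    return("trueZ must be 0/1")
  TRUE
})

#' Construct an ocSurvey from a visit table
#'
#' @param visits data.frame with columns \code{site}, \code{visit},
#'   \code{K}, \code{y_ambig}, \code{nu}, \code{confirmed} and optional
#'   covariates. \code{y_ambig} may be omitted when \code{nu} is complete
#'   (it is then derived).
#' @param siteCovs optional data.frame of site covariates (column
#'   \code{site} required).
#' @param trueZ optional latent occupancy states for simulated data.
#' @param scenario optional generating-scenario record.
#' @return An \linkS4class{ocSurvey} object.
#' @export
ocSurvey <- function(visits, siteCovs = NULL, trueZ = NULL, scenario = NULL) {
  visits <- as.data.frame(visits)
  if (is.null(visits$y_ambig)) {
    if (any(is.na(visits$nu)))
      stop("y_ambig missing and nu incomplete; cannot derive detections")
    visits$y_ambig <- as.integer(visits$nu %in% 1:3)
  }
  visits$y_ambig <- as.integer(visits$y_ambig)
  visits$confirmed <- as.integer(visits$confirmed)
  visits$nu <- as.integer(visits$nu)
  new("ocSurvey", visits = visits, siteCovs = siteCovs, trueZ = trueZ,
      scenario = scenario)
}

#' @describeIn ocSurvey-accessors number of sites
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @describeIn ocSurvey-accessors visits per site (named vector)
#' @export
setGeneric("nVisits", function(object) standardGeneric("nVisits"))

#' @describeIn ocSurvey-accessors the visit table
#' @export
setGeneric("surveyData", function(object) standardGeneric("surveyData"))

#' @describeIn ocSurvey-accessors latent occupancy states (simulated data)
#' @export
setGeneric("trueState", function(object) standardGeneric("trueState"))

#' Accessors for ocSurvey objects
#'
#' @param object an \linkS4class{ocSurvey}.
#' @name ocSurvey-accessors
NULL

#' @rdname ocSurvey-accessors
#' @export
setMethod("nSites", "ocSurvey", function(object)
  length(unique(object@visits$site)))

#' @rdname ocSurvey-accessors
#' @export
setMethod("nVisits", "ocSurvey", function(object) {
  tab <- table(object@visits$site)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname ocSurvey-accessors
#' @export
setMethod("surveyData", "ocSurvey", function(object) object@visits)

#' @rdname ocSurvey-accessors
#' @export
setMethod("trueState", "ocSurvey", function(object) object@trueZ)

setMethod("show", "ocSurvey", function(object) {
  v <- object@visits
  cat("ocSurvey:", nSites(object), "sites,", nrow(v), "visits\n")
  cat(sprintf("  confirmed visits : %d (%.0f%%)\n", sum(v$confirmed),
              100 * mean(v$confirmed)))
  cat(sprintf("  ambiguous detections: %d\n", sum(v$y_ambig)))
  if (!is.null(object@trueZ))
    cat(sprintf("  simulated; occupied sites: %d of %d\n",
                sum(object@trueZ), length(object@trueZ)))
  if (!is.null(object@scenario) && !is.null(object@scenario$label))
    cat("  scenario:", object@scenario$label, "\n")
  invisible(NULL)
})

#' Diagnostic validation of a survey dataset
#'
#' Runs the hard structural checks (S4 validity) plus softer diagnostics:
#' a confirmed outcome of "all verified" or "mixed" (\code{nu} 2 or 3)
#' alongside \code{K = 0} is flagged with a warning, since there was no
#' recorded auto ID to verify. The covariate-free data-generating model can
#' produce such visits, so this is a data-quality signal rather than an
#' error.
#'
#' @param object an \linkS4class{ocSurvey}.
#' @param warn emit warnings for soft diagnostics (default TRUE).
#' @return Invisibly, a character vector of diagnostic messages (empty when
#'   clean).
#' @export
validateSurvey <- function(object, warn = TRUE) {
  validObject(object)
  v <- object@visits
  msgs <- character()
  odd <- !is.na(v$nu) & v$nu %in% 2:3 & v$K < 1
  if (any(odd))
    msgs <- c(msgs, sprintf(
      "verified outcome with K = 0 at site %s, visit %s",
      v$site[odd], v$visit[odd]))
  if (warn) for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}
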