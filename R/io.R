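#' Write a survey dataset to CSV
#'
#' Long format, one row per visit, header
#' \code{site,visit,K,y_ambig,nu,confirmed} plus any covariate columns;
#' \code{nu} at unconfirmed visits is written as an empty field. The
#' write/read pair round-trips exactly.
#'
#' @param survey an \linkS4class{ocSurvey}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSurvey <- function(survey, path) {
  validObject(survey)
  v <- surveyData(survey)
  lead <- c("site", "visit", "K", "y_ambig", "nu", "confirmed")
  v <- v[, c(lead, setdiff(names(v), lead)), drop = FALSE]
  utils::write.csv(v, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a survey dataset from CSV
#'
#' @param path file written by \code{\link{writeSurvey}} (or any CSV with
#'   the same header).
#' @return an \linkS4class{ocSurvey}.
#' @export
readSurvey <- function(path) {
  v <- utils::read.csv(path, na.strings = "")
  need <- c("site", "visit", "K", "y_ambig", "nu", "confirmed")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("survey CSV missing columns: ", paste(miss, collapse = ", "))
  ocSurvey(v)
}

#' Write a fit result to CSV
#'
#' One row per parameter (\code{parameter, estimate, se, lower, upper,
#' scale}); the occupancy probability-scale row is appended when defined.
#' A run-metadata record (status, negative log-likelihood, approach,
#' restarts, seed) is written alongside as \code{<path>.meta.json}.
#'
#' @param fit an \linkS4class{ocFit}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFitCSV <- function(fit, path) {
  tab <- data.frame(parameter = names(fit@estimates),
                    estimate = unname(fit@estimates), se = fit@se,
                    lower = fit@ciLogit[, 1L], upper = fit@ciLogit[, 2L],
                    scale = "logit")
  if (is.finite(fit@psiHat))
    tab <- rbind(tab, data.frame(parameter = "psi", estimate = fit@psiHat,
                                 se = NA_real_, lower = fit@ciPsi[1L],
                                 upper = fit@ciPsi[2L],
                                 scale = "probability"))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- list(status = fit@status, nll = fit@nll,
               approach = fit@approach, nRestarts = fit@nRestarts,
               seed = fit@details$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

# read a JSON-compatible key-value config file
.readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e)
             stop("malformed config ", path, ": ", conditionMessage(e),
                  call. = FALSE))
}

# manifest written next to every CLI output
.writeManifest <- function(path, seed, config, outputs, counts = list()) {
  man <- list(tool = "ocdesign",
              version = as.character(utils::packageVersion("ocdesign")),
              seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
              config = config, outputs = outputs, counts = counts)
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
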