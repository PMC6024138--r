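# Shared fixtures and independent oracles, built in code.

# tiny mixed-confirmation survey used by the likelihood tests
toyMixedSurvey <- function() {
  v <- data.frame(site = rep(1:2, each = 2), visit = rep(1:2, 2),
                  K = c(0, 3, 1, 0),
                  nu = c(2L, 0L, NA, 1L),
                  confirmed = c(1L, 1L, 0L, 1L),
                  y_ambig = c(1L, 0L, 1L, 1L))
  ocSurvey(v)
}

# random small survey for enumeration checks (all shapes of confirmation)
randomToySurvey <- function(seed) {
  set.seed(seed)
  n <- sample(1:3, 1)
  J <- sample(1:3, 1)
  rows <- lapply(seq_len(n), function(i) {
    conf <- rbinom(J, 1, 0.6)
    nu <- ifelse(conf == 1, sample(0:3, J, replace = TRUE), NA)
    y <- ifelse(is.na(nu), rbinom(J, 1, 0.5), as.integer(nu %in% 1:3))
    data.frame(site = i, visit = seq_len(J), K = sample(0:5, J, TRUE),
               nu = as.integer(nu), confirmed = conf, y_ambig = y)
  })
  ocSurvey(do.call(rbind, rows))
}

randomParams <- function(seed) {
  set.seed(seed)
  parameterSet(rnorm(1, 0, 1), rnorm(2, 0, 0.8), rnorm(2, -0.5, 0.8))
}

# Independent multinomial-mixture likelihood for fully confirmed data:
# plain probability-scale arithmetic, no clipping, no log-sum-exp.
multinomMixtureNLL <- function(params, survey, spec = covariateSpec()) {
  v <- surveyData(survey)
  stopifnot(all(v$confirmed == 1L), all(!is.na(v$nu)))
  v$logK <- log(v$K + 1)
  psi <- plogis(params$theta[1])
  lik <- 1
  for (s in unique(v$site)) {
    rows <- v[v$site == s, ]
    p1 <- 1; p0 <- 1
    for (r in seq_len(nrow(rows))) {
      s1 <- plogis(sum(params$betaS1 * c(1, rows$logK[r])))
      s0 <- plogis(sum(params$betaS0 * c(1, rows$logK[r])))
      pr1 <- c((1 - s0) * (1 - s1), s0 * (1 - s1), s1 * (1 - s0), s0 * s1)
      pr0 <- c(1 - s0, s0, 0, 0)
      p1 <- p1 * pr1[rows$nu[r] + 1]
      p0 <- p0 * pr0[rows$nu[r] + 1]
    }
    lik <- lik * (psi * p1 + (1 - psi) * p0)
  }
  -log(lik)
}

# enumerate all observable datasets for a fixed tiny design
# (confirmed visits take values 0..3, unconfirmed 0/1) and return the
# total probability mass under enumLikelihood
totalObservableMass <- function(params, template, spec = covariateSpec()) {
  v <- surveyData(template)
  domains <- lapply(seq_len(nrow(v)), function(r)
    if (v$confirmed[r] == 1L) 0:3 else 0:1)
  grid <- expand.grid(domains)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    w <- v
    for (r in seq_len(nrow(v))) {
      val <- grid[g, r]
      if (v$confirmed[r] == 1L) {
        w$nu[r] <- val
        w$y_ambig[r] <- as.integer(val %in% 1:3)
      } else {
        w$nu[r] <- NA_integer_
        w$y_ambig[r] <- val
      }
    }
    total <- total + enumLikelihood(params, ocSurvey(w), spec)
  }
  total
}

# ML point estimate of psi from any fit where the optimizer produced
# estimates (includes "unreasonable" boundary fits; NA otherwise)
psiPointEstimate <- function(fit) {
  est <- estimates(fit)
  if (all(is.finite(est))) unname(plogis(est[1])) else NA_real_
}
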