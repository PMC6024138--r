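spec0 <- covariateSpec(detect1 = ~ 1, detect0 = ~ 1)

test_that("hand-computed likelihood values are reproduced", {
  # one site, one confirmed visit with outcome 'all verified':
  # L = psi * s1 (1 - s0) + (1 - psi) * 0 = 0.5 * 0.72 = 0.36
  v <- data.frame(site = 1, visit = 1, K = 0, nu = 2L, confirmed = 1L,
                  y_ambig = 1L)
  p <- parameterSet(0, qlogis(0.8), qlogis(0.1))
  ll <- ocNegLogLik(p, ocSurvey(v), spec0)
  expect_equal(ll$value, -log(0.36), tolerance = 1e-10)
  expect_equal(unname(sum(ll$perSite)), -ll$value, tolerance = 1e-10)

  # two confirmed visits, both 'all overturned', s0 = 0.2, s1 = 0.5,
  # psi = 0.8: L = 0.8 * (0.2 * 0.5)^2 + 0.2 * 0.2^2 = 0.016
  v2 <- data.frame(site = 1, visit = 1:2, K = 0, nu = c(1L, 1L),
                   confirmed = 1L, y_ambig = 1L)
  p2 <- parameterSet(qlogis(0.8), qlogis(0.5), qlogis(0.2))
  expect_equal(ocNegLogLik(p2, ocSurvey(v2), spec0)$value, -log(0.016),
               tolerance = 1e-9)

  # unconfirmed non-detection with psi driven to ~1: contribution is
  # -log(1 - p11)
  v3 <- data.frame(site = 1, visit = 1, K = 0, nu = NA_integer_,
                   confirmed = 0L, y_ambig = 0L)
  p3 <- parameterSet(40, qlogis(0.5), qlogis(0.2))
  p11 <- 0.5 + 0.2 - 0.1
  expect_equal(ocNegLogLik(p3, ocSurvey(v3), spec0)$value, -log(1 - p11),
               tolerance = 1e-8)
})

test_that("standard occupancy likelihood matches hand evaluation", {
  # one site, J = 2, y = (0,0), psi = p = 0.5: L = 0.5 * 0.25 + 0.5
  p <- list(theta = 0, betaP = 0)
  y <- matrix(c(0, 0), nrow = 1)
  expect_equal(standardNegLogLik(p, y, detect = ~ 1)$value, -log(0.625),
               tolerance = 1e-10)
  # a detection kills the unoccupied branch
  y1 <- matrix(c(1, 0), nrow = 1)
  expect_equal(standardNegLogLik(p, y1, detect = ~ 1)$value,
               -log(0.5 * 0.25), tolerance = 1e-10)
  # degenerate certainty: psi ~ 1, p ~ 1, all detections
  pHi <- list(theta = 50, betaP = 50)
  expect_equal(standardNegLogLik(pHi, matrix(1, 1, 2), detect = ~ 1)$value,
               0, tolerance = 1e-8)
  expect_error(standardNegLogLik(p, matrix(numeric(0), 0, 0)), "empty")
  expect_error(standardNegLogLik(p, matrix(NA, 1, 2), detect = ~ 1),
               "binary")
})

test_that("log-scale likelihood agrees with brute-force enumeration", {
  for (seed in 1:40) {
    sv <- randomToySurvey(seed)
    pp <- randomParams(seed + 500)
    nll <- ocNegLogLik(pp, sv)$value
    expect_lt(abs(nll + log(enumLikelihood(pp, sv))), 1e-10)
  }
})

test_that("total probability over the observable outcome space is one", {
  # 2 sites x 2 visits, mixed confirmation pattern
  template <- toyMixedSurvey()
  for (seed in c(3, 17, 91)) {
    pp <- randomParams(seed)
    expect_lt(abs(totalObservableMass(pp, template) - 1), 1e-8)
    # and the log-scale implementation carries the same mass
    v <- surveyData(template)
    massLog <- 0
    domains <- lapply(seq_len(nrow(v)), function(r)
      if (v$confirmed[r] == 1L) 0:3 else 0:1)
    grid <- expand.grid(domains)
    for (g in seq_len(nrow(grid))) {
      w <- v
      for (r in seq_len(nrow(v))) {
        val <- grid[g, r]
        if (v$confirmed[r] == 1L) {
          w$nu[r] <- val; w$y_ambig[r] <- as.integer(val %in% 1:3)
        } else { w$nu[r] <- NA_integer_; w$y_ambig[r] <- val }
      }
      massLog <- massLog + exp(-ocNegLogLik(pp, ocSurvey(w))$value)
    }
    expect_lt(abs(massLog - 1), 1e-8)
  }
})

test_that("full confirmation reduces to the pure multinomial mixture", {
  set.seed(21)
  v <- data.frame(site = rep(1:3, each = 3), visit = rep(1:3, 3),
                  K = sample(0:8, 9, TRUE),
                  nu = c(2L, 0L, 3L, 0L, 0L, 0L, 1L, 2L, 0L),
                  confirmed = 1L)
  v$y_ambig <- as.integer(v$nu %in% 1:3)
  sv <- ocSurvey(v)
  for (seed in c(5, 6, 7)) {
    pp <- randomParams(seed)
    expect_equal(ocNegLogLik(pp, sv)$value, multinomMixtureNLL(pp, sv),
                 tolerance = 1e-8)
  }
})

test_that("zero misidentification with no confirmation reduces to the standard model", {
  set.seed(31)
  n <- 6; J <- 3
  y <- matrix(rbinom(n * J, 1, 0.5), n, J)
  K <- matrix(sample(0:10, n * J, TRUE), n, J)
  v <- data.frame(site = rep(1:n, each = J), visit = rep(1:J, n),
                  K = as.vector(t(K)), nu = NA_integer_, confirmed = 0L,
                  y_ambig = as.vector(t(y)))
  sv <- ocSurvey(v)
  theta <- 0.4; b1 <- c(-0.3, 0.9)
  # beta_s0 intercept capped far below: s0 effectively zero, p11 = s1
  pOC <- parameterSet(theta, b1, c(-40, 0))
  pStd <- list(theta = theta, betaP = b1)
  expect_equal(ocNegLogLik(pOC, sv)$value,
               standardNegLogLik(pStd, y, K)$value, tolerance = 1e-8)
})

test_that("likelihood rejects corrupt inputs and oversized enumerations", {
  v <- data.frame(site = 1, visit = 1:2, K = 0, nu = c(2L, NA),
                  confirmed = c(1L, 1L), y_ambig = c(1L, 0L))
  expect_error(ocSurvey(v), "confirmed visit without a nu outcome")
  big <- data.frame(site = rep(1:4, each = 2), visit = rep(1:2, 4), K = 0,
                    nu = 0L, confirmed = 1L, y_ambig = 0L)
  expect_error(enumLikelihood(randomParams(1), ocSurvey(big)),
               "too large")
  sv <- toyMixedSurvey()
  expect_error(ocNegLogLik(parameterSet(0, 0, 0), sv),
               "do not match")
})
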