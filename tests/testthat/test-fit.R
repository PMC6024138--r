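hmhScenario <- function() ocScenario(0.8, c(0, 1.6), c(-2.2, 1.5), "HMH")

test_that("Wald intervals transform correctly between scales", {
  expect_equal(waldInterval(0, 1), c(-2, 2))
  ci <- inverseLogit(waldInterval(0, 1))
  expect_equal(round(ci, 3), c(0.119, 0.881))
  expect_equal(round(ci[2] - ci[1], 3), 0.762)
  expect_equal(waldInterval(1.3, 0), c(1.3, 1.3))
  expect_error(waldInterval(0, -1))
})

test_that("convergence classification applies the plausibility thresholds", {
  ciOK <- matrix(c(-1, 1), 1)
  expect_equal(classifyConvergence(0.5, ciOK, c(0.3, 0.7)), "converged")
  # estimate beyond 10 in absolute value, either sign
  expect_equal(classifyConvergence(10.5, ciOK, c(0.3, 0.7)), "unreasonable")
  expect_equal(classifyConvergence(-10.5, ciOK, c(0.3, 0.7)), "unreasonable")
  # logit-scale interval wider than 30
  expect_equal(classifyConvergence(0, matrix(c(-16, 16), 1), c(0.3, 0.7)),
               "unreasonable")
  # probability-scale occupancy interval wider than 0.7
  expect_equal(classifyConvergence(0, ciOK, c(0.1, 0.85)), "unreasonable")
  expect_equal(classifyConvergence(0, ciOK, c(0.3, 0.7), hessianOK = FALSE),
               "hessian_failed")
})

test_that("refitting with identical options is deterministic", {
  sv <- simulateUnambiguous(hmhScenario(), surveyDesign(40, 4), seed = 8)
  f1 <- fitOC(sv, options = fitOptions(seed = 21))
  f2 <- fitOC(sv, options = fitOptions(seed = 21))
  expect_identical(estimates(f1), estimates(f2))
  expect_identical(stdErrors(f1), stdErrors(f2))
  expect_identical(f1@nll, f2@nll)
})

test_that("the optimum matches a dense grid search on a toy dataset", {
  v <- data.frame(site = rep(1:3, each = 3), visit = rep(1:3, 3), K = 0,
                  nu = c(2L, 2L, 0L, 0L, 0L, 0L, 1L, 0L, NA),
                  confirmed = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L),
                  y_ambig = c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
  sv <- ocSurvey(v)
  spec0 <- covariateSpec(detect1 = ~ 1, detect0 = ~ 1)
  fit <- fitOC(sv, spec = spec0, options = fitOptions(seed = 5))
  step <- 0.25
  g <- seq(-3, 3, by = step)
  best <- c(Inf, NA, NA, NA)
  for (a in g) for (b in g) for (cc in g) {
    val <- ocNegLogLik(parameterSet(a, b, cc), sv, spec0)$value
    if (val < best[1]) best <- c(val, a, b, cc)
  }
  expect_lte(fit@nll, best[1] + 1e-8)
  expect_true(all(abs(estimates(fit) - best[2:4]) <= step))
})

test_that("perfect detection recovers the naive occupancy proportion", {
  set.seed(9)
  Z <- rbinom(60, 1, 0.7)
  y <- matrix(rep(Z, 4), ncol = 4)
  fit <- fitStandard(y, detect = ~ 1, options = fitOptions(seed = 2))
  expect_lt(abs(psiHat(fit) - mean(Z)), 1e-3)
})

test_that("an all-zero dataset drives occupancy to the boundary and fails", {
  v <- data.frame(site = rep(1:10, each = 3), visit = rep(1:3, 10), K = 2,
                  y_ambig = 0L, nu = 0L, confirmed = 1L)
  fit <- fitOC(ocSurvey(v), options = fitOptions(seed = 3))
  expect_true(fitStatus(fit) %in%
                c("unreasonable", "hessian_failed", "optimizer_failed"))
  expect_false(fitStatus(fit) == "converged")
})

test_that("fitApproach enforces the REMOVE confirmation requirement", {
  sv <- simulateUnambiguous(hmhScenario(), surveyDesign(30, 4), seed = 2)
  partial <- applyConfirmation(sv, confirmationDesign(0.5, 2), seed = 2)
  expect_error(fitApproach(partial, "REMOVE"),
               "requires confirmation for all visit-level ambiguous")
  # and works on fully confirmed data
  fit <- fitApproach(sv, "REMOVE", options = fitOptions(seed = 4))
  expect_s4_class(fit, "ocFit")
  expect_equal(fit@approach, "REMOVE")
  # IGNORE uses only the ambiguous history, so masking nu changes nothing
  fi1 <- fitApproach(sv, "IGNORE", options = fitOptions(seed = 4))
  fi2 <- fitApproach(partial, "IGNORE", options = fitOptions(seed = 4))
  expect_identical(estimates(fi1), estimates(fi2))
})

test_that("coefficients are recovered on average under full confirmation", {
  # all five default scenarios, 300 replicates each, within 3 MC SEs
  scens <- defaultScenarios()
  d <- surveyDesign(84, 4)
  nrep <- 300
  for (sc in scens) {
    truth <- c(qlogis(sc$psi), sc$betaS1, sc$betaS0)
    ests <- matrix(NA_real_, nrep, 5)
    for (r in seq_len(nrep)) {
      b <- scenarioBundles(sc, d, 1, seed = 3000 + r)[[1]]
      fit <- fitOC(b$master, options = fitOptions(seed = b$seed))
      if (fitStatus(fit) == "converged") ests[r, ] <- estimates(fit)
    }
    conv <- stats::complete.cases(ests)
    expect_gte(sum(conv), 250)
    # occupancy: unbiased to Monte-Carlo resolution
    mcse1 <- sd(ests[conv, 1]) / sqrt(sum(conv))
    expect_lt(abs(mean(ests[conv, 1]) - truth[1]), 3 * mcse1,
              label = sprintf("scenario %s occupancy: |bias| < 3 MC SE",
                              sc$label))
    # detection coefficients: reasonably unbiased; the ML slope carries a
    # small fixed finite-sample bias at 84 sites, so the bound is the
    # larger of the Monte-Carlo resolution and a 10% relative allowance
    for (k in 2:5) {
      mcse <- sd(ests[conv, k]) / sqrt(sum(conv))
      bound <- max(3 * mcse, 0.1 * abs(truth[k]) + 0.02)
      expect_lt(abs(mean(ests[conv, k]) - truth[k]), bound,
                label = sprintf("scenario %s coefficient %d: small bias",
                                sc$label, k))
    }
  }
})
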