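hmh <- function() ocScenario(0.8, c(0, 1.6), c(-2.2, 1.5), label = "HMH")

test_that("activity generator honours degenerate and bootstrap modes", {
  d0 <- surveyDesign(10, 4, K = kConfig(zeroMass = 1 - 1e-12))
  expect_true(all(generateK(d0, seed = 1) %in% 0L) ||
              mean(generateK(d0, seed = 1) == 0L) > 0.99)
  dz <- surveyDesign(10, 4, K = kConfig("bootstrap", values = 5L))
  expect_true(all(generateK(dz, seed = 2) == 5L))
  expect_error(kConfig("bootstrap", values = integer(0)), "non-empty")
})

test_that("parametric activity draws have the configured mean", {
  d <- surveyDesign(2500, 4, K = kConfig(mean = 25, dispersion = 0.7,
                                         zeroMass = 0))
  K <- generateK(d, seed = 77)     # 10,000 draws
  sdNB <- sqrt(25 + 25^2 / 0.7)
  expect_lt(abs(mean(K) - 25), 3 * sdNB / sqrt(length(K)))
  expect_true(all(K >= 0) && all(K == round(K)))
})

test_that("simulated confirmed outcomes follow the conditional multinomial", {
  # fix K = 0 so s1 = 0.5 and s0 = plogis(-2.2); compare outcome
  # frequencies at occupied sites against the closed-form probabilities
  d <- surveyDesign(12500, 4, K = kConfig("bootstrap", values = 0L))
  sv <- simulateUnambiguous(hmh(), d, seed = 5)
  v <- surveyData(sv)
  occ <- trueState(sv)[as.character(v$site)] == 1
  nuOcc <- v$nu[occ]
  s0 <- plogis(-2.2)
  expected <- nuOutcomeProbs(0.5, s0, z = 1)
  n <- length(nuOcc)
  for (k in 0:3) {
    pHat <- mean(nuOcc == k)
    se <- sqrt(expected[k + 1] * (1 - expected[k + 1]) / n)
    expect_lt(abs(pHat - expected[k + 1]), 3 * se + 1e-12)
  }
})

test_that("verified outcomes never occur at unoccupied sites", {
  for (seed in 1:5) {
    sv <- simulateUnambiguous(hmh(), surveyDesign(40, 4), seed = seed)
    v <- surveyData(sv)
    unocc <- trueState(sv)[as.character(v$site)] == 0
    expect_false(any(v$nu[unocc] %in% 2:3))
  }
})

test_that("no misidentification means all-zero outcomes at unoccupied sites", {
  sc <- ocScenario(0.5, c(0, 1.6), c(-40, 0))
  sv <- simulateUnambiguous(sc, surveyDesign(60, 4), seed = 3)
  v <- surveyData(sv)
  unocc <- trueState(sv)[as.character(v$site)] == 0
  expect_true(all(v$nu[unocc] == 0L))
})

test_that("detection histories derive from outcomes by the confirmation rules", {
  v <- data.frame(site = rep(1:2, each = 2), visit = rep(1:2, 2), K = 1,
                  nu = c(1L, 0L, 3L, 2L), confirmed = 1L)
  v$y_ambig <- as.integer(v$nu %in% 1:3)
  h <- deriveHistories(ocSurvey(v))
  expect_equal(unname(h$yAmbig), matrix(c(1L, 0L, 1L, 1L), 2, byrow = TRUE))
  expect_equal(unname(h$yConfirmed),
               matrix(c(0L, 0L, 1L, 1L), 2, byrow = TRUE))
  masked <- v; masked$nu[2] <- NA_integer_; masked$confirmed[2] <- 0L
  expect_error(deriveHistories(ocSurvey(masked)), "missing")
})

test_that("confirmation designs select the right counts and prioritise detections", {
  sv <- simulateUnambiguous(hmh(), surveyDesign(84, 4), seed = 11)
  # full confirmation leaves the dataset untouched
  full <- applyConfirmation(sv, confirmationDesign(1, 4), seed = 2)
  expect_identical(surveyData(full), surveyData(sv))
  # C(0.5, 2): 42 confirmed sites, 84 confirmed visits
  half <- applyConfirmation(sv, confirmationDesign(0.5, 2), seed = 2)
  v <- surveyData(half)
  confSites <- unique(v$site[v$confirmed == 1L])
  expect_length(confSites, 42L)
  expect_equal(sum(v$confirmed), 84L)
  expect_true(all(tapply(v$confirmed, v$site, sum) %in% c(0L, 2L)))
  # unconfirmed visits lose nu, keep y_ambig
  expect_true(all(is.na(v$nu[v$confirmed == 0L])))
  expect_false(any(is.na(v$nu[v$confirmed == 1L])))
  expect_error(applyConfirmation(sv, confirmationDesign(1, 5), seed = 1),
               "exceeds")
})

test_that("ambiguous detections are confirmed before non-detections", {
  for (seed in 1:10) {
    sv <- simulateUnambiguous(hmh(), surveyDesign(30, 4), seed = seed)
    masked <- applyConfirmation(sv, confirmationDesign(1, 2), seed = seed)
    v <- surveyData(masked)
    for (s in unique(v$site)) {
      rows <- v[v$site == s, ]
      # no unconfirmed ambiguous detection may coexist with a confirmed
      # non-detection
      if (any(rows$y_ambig == 1L & rows$confirmed == 0L))
        expect_false(any(rows$y_ambig == 0L & rows$confirmed == 1L))
    }
  }
  # deterministic case: exactly the ambiguous visits are confirmed
  v <- data.frame(site = 1, visit = 1:4, K = 1,
                  nu = c(2L, 0L, 3L, 0L), confirmed = 1L)
  v$y_ambig <- as.integer(v$nu %in% 1:3)
  out <- surveyData(applyConfirmation(ocSurvey(v), confirmationDesign(1, 2),
                                      seed = 4))
  expect_equal(out$confirmed, c(1L, 0L, 1L, 0L))
})

test_that("shared bundles are reproducible and internally consistent", {
  d <- surveyDesign(30, 4)
  designs <- list(confirmationDesign(0.5, 2))
  b1 <- scenarioBundles(hmh(), d, 3, seed = 9, designs = designs)
  b2 <- scenarioBundles(hmh(), d, 3, seed = 9, designs = designs)
  expect_identical(lapply(b1, function(b) surveyData(b$master)),
                   lapply(b2, function(b) surveyData(b$master)))
  expect_identical(b1[[1]]$ignore, b2[[1]]$ignore)
  for (b in b1) {
    h <- deriveHistories(b$master)
    expect_identical(b$ignore, h$yAmbig)
    expect_identical(b$remove, h$yConfirmed)
    # the masked variant agrees with the master wherever confirmed
    v <- surveyData(b$variants[["C(0.5,2)"]])
    m <- surveyData(b$master)
    keep <- v$confirmed == 1L
    expect_identical(v$nu[keep], m$nu[keep])
    expect_identical(v$y_ambig, m$y_ambig)
  }
})

test_that("simulated occupancy matches the generating rate across bundles", {
  d <- surveyDesign(84, 4)
  bundles <- scenarioBundles(hmh(), d, 300, seed = 4)
  occFrac <- vapply(bundles, function(b) mean(trueState(b$master)), 0)
  se <- sqrt(0.8 * 0.2 / (84 * length(bundles)))
  expect_lt(abs(mean(occFrac) - 0.8), 3 * se)
})
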