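# Survival association: log-rank, Cox, one-vs-rest screens, therapy benefit.

# hand log-rank oracle: observed vs expected events at each event time
handLogRank <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

test_that("log-rank agrees with the textbook tabulation oracle", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 40
    time <- rexp(n, 0.1)
    event <- rbinom(n, 1, 0.8)
    group <- rep(c("x", "y"), each = n / 2)
    sv <- SurvivalData(paste0("s", 1:n), time, event)
    res <- logRankTest(sv, setNames(group, paste0("s", 1:n)))
    expect_equal(res$statistic, handLogRank(time, event, group),
                 tolerance = 1e-10)
    expect_equal(res$df, 1L)
    expect_gt(res$p, 0)
  }
})

test_that("identical groups give statistic 0 and p 1", {
  time <- c(1, 3, 2, 4, 1, 3, 2, 4)
  event <- c(1, 0, 1, 1, 1, 0, 1, 1)
  sv <- SurvivalData(paste0("s", 1:8), time, event)
  res <- logRankTest(sv, setNames(rep(c("a", "b"), each = 4),
                                  paste0("s", 1:8)))
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p, 0.999)
  # label swap invariance
  res2 <- logRankTest(sv, setNames(rep(c("b", "a"), each = 4),
                                   paste0("s", 1:8)))
  expect_equal(res$statistic, res2$statistic)
})

test_that("log-rank preconditions are enforced", {
  sv <- SurvivalData(c("a", "b"), c(1, 2), c(1L, 1L))
  expect_error(logRankTest(sv, c(a = "g", b = "g")), "2 non-empty groups")
  sv0 <- SurvivalData(c("a", "b"), c(1, 2), c(0L, 0L))
  expect_error(logRankTest(sv0, c(a = "g1", b = "g2")), "event")
})

test_that("log-rank rejection is calibrated under the null", {
  set.seed(77)
  rej <- mean(vapply(1:2000, function(i) {
    time <- rexp(100, 0.1)
    cens <- rexp(100, 0.025)  # ~20% censoring
    ev <- as.integer(time <= cens)
    sv <- SurvivalData(paste0("s", 1:100), pmin(time, cens), ev)
    logRankTest(sv, setNames(rep(c("a", "b"), 50), paste0("s", 1:100)))$p < 0.05
  }, TRUE))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.065)
})

test_that("Cox recovers a planted hazard ratio and nulls stay near 1", {
  set.seed(88)
  x <- rbinom(500, 1, 0.5)
  time <- rexp(500, 0.1 * 2^x)  # true HR = 2
  sv <- SurvivalData(paste0("s", 1:500), time, rep(1L, 500))
  fit <- fitCox(sv, setNames(x, paste0("s", 1:500)))
  expect_true(fit$converged)
  expect_lt(abs(fit$HR - 2) / 2, 0.15)
  expect_true(fit$ciLow <= fit$HR && fit$HR <= fit$ciHigh)
  expect_equal(exp(fit$logHR), fit$HR)

  xnull <- rbinom(2000, 1, 0.5)
  tnull <- rexp(2000, 0.1)
  svn <- SurvivalData(paste0("n", 1:2000), tnull, rep(1L, 2000))
  fn <- fitCox(svn, setNames(xnull, paste0("n", 1:2000)))
  expect_gte(fn$HR, 0.9)
  expect_lte(fn$HR, 1.1)

  expect_error(fitCox(sv, setNames(rep(1, 500), paste0("s", 1:500))),
               "vary")
})

test_that("Cox and log-rank point the same way on two-group data", {
  set.seed(99)
  x <- rep(0:1, each = 100)
  time <- rexp(200, 0.1 * ifelse(x == 1, 3, 1))
  sv <- SurvivalData(paste0("s", 1:200), time, rep(1L, 200))
  fit <- fitCox(sv, setNames(x, paste0("s", 1:200)))
  lr <- logRankTest(sv, setNames(x, paste0("s", 1:200)))
  expect_gt(fit$HR, 1)
  expect_lt(lr$p, 0.05)
  expect_lt(fit$p, 0.05)
})

test_that("survival screen flags a planted adverse community", {
  tr <- generateTruth(nSamples = 500, nCommunities = 3,
                      hazardMultipliers = c(1, 1, 2), seed = 111)
  sv <- simulateSurvival(tr, baselineHazard = 0.1, censoringRate = 0.2,
                         seed = 113)
  units <- setNames(paste0("C", tr@sampleCommunity),
                    names(tr@sampleCommunity))
  tab <- stateSurvivalScreen(units, sv)
  row <- tab[tab$unit == "C3", ]
  expect_equal(row$direction, "adverse")
  expect_lt(row$coxP, 0.05)
  expect_true(row$significant)
  # undersized units are skipped with a reason
  units2 <- units
  units2[1:3] <- "tiny"
  units2[-(1:3)] <- "rest"
  tab2 <- stateSurvivalScreen(units2, sv)
  expect_match(tab2$reason[tab2$unit == "tiny"], "in-group size")
  expect_false(tab2$significant[tab2$unit == "tiny"])
})

test_that("screens are roughly calibrated under the null", {
  set.seed(222)
  flags <- vapply(1:200, function(i) {
    n <- 120
    sv <- SurvivalData(paste0("s", 1:n), rexp(n, 0.1), rep(1L, n))
    units <- setNames(rep(c("u1", "u2"), n / 2), paste0("s", 1:n))
    any(stateSurvivalScreen(units, sv)$significant)
  }, TRUE)
  # two perfectly anti-correlated one-vs-rest tests: family rate ~ alpha
  expect_lt(mean(flags), 0.12)
})

test_that("therapy benefit flags planted responder advantage only", {
  tr <- generateTruth(nSamples = 500, hazardMultipliers = c(1, 1, 1),
                      seed = 331)
  rs <- simulateResponse(tr, baselineHazard = 0.1,
                         benefitHazardReduction = 0.4, seed = 337)
  benefit <- EcoStates:::inBenefitState(tr)
  units <- setNames(ifelse(benefit, "inBenefit", "outside"),
                    names(tr@sampleCommunity))
  tab <- therapyBenefit(units, rs)
  expect_true(tab$benefit[tab$unit == "inBenefit"])
  expect_false(tab$benefit[tab$unit == "outside"])
  expect_gt(tab$rmstResponder[tab$unit == "inBenefit"],
            tab$rmstNonResponder[tab$unit == "inBenefit"])

  # a unit with no responders is skipped
  rs2 <- rs
  rs2@response[units == "outside"] <- "non_responder"
  tab2 <- therapyBenefit(units, rs2)
  expect_match(tab2$reason[tab2$unit == "outside"], "arm")
})

test_that("null therapy benefit is rare", {
  set.seed(444)
  flags <- vapply(1:200, function(i) {
    n <- 100
    rs <- SurvivalData(paste0("s", 1:n), rexp(n, 0.1), rep(1L, n),
                       sample(c("responder", "non_responder"), n, TRUE))
    units <- setNames(rep("all", n), paste0("s", 1:n))
    therapyBenefit(units, rs)$benefit
  }, TRUE)
  expect_lt(mean(flags), 0.06)
})
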