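test_that("cohort summaries use interpolated quantiles", {
  tab <- data.frame(metric = c(1, 2, 3, 4, 5), group = "A")
  s <- summarizeCohort(tab, "metric")
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$n, 5)

  tab1 <- data.frame(metric = 7, group = "A")
  s1 <- summarizeCohort(tab1, "metric")
  expect_equal(c(s1$median, s1$q1, s1$q3), c(7, 7, 7))

  set.seed(131)
  tabN <- data.frame(metric = rnorm(10000), group = "A")
  expect_lt(abs(summarizeCohort(tabN, "metric")$q1 - (-0.674)), 0.03)

  expect_error(summarizeCohort(data.frame(metric = c(1, NA),
                                          group = c("A", "B")),
                               "metric"), "'B'")
})

test_that("the normality gate chooses the right test branch", {
  set.seed(137)
  norm <- data.frame(metric = c(rnorm(30), rnorm(30, 2)),
                     group = rep(c("A", "B"), each = 30))
  cN <- compareGroups(norm, "metric")
  expect_equal(cN@test, "t_test")
  expect_lt(cN@pValue, 0.001)

  expo <- data.frame(metric = c(rexp(30), rexp(30)),
                     group = rep(c("A", "B"), each = 30))
  cE <- compareGroups(expo, "metric")
  expect_equal(cE@test, "mann_whitney")

  same <- data.frame(metric = rep(c(1, 2, 3, 4, 5), 2),
                     group = rep(c("A", "B"), each = 5))
  cS <- compareGroups(same, "metric")
  expect_gt(cS@pValue, 0.95)

  small <- data.frame(metric = c(1, 2, 1, 2, 3),
                      group = c("A", "A", "B", "B", "B"))
  expect_error(compareGroups(small, "metric"), "fewer than 3")
})

test_that("the pipeline runs end to end, deterministically, on a small cohort", {
  mkRec <- function(g, i, seed) {
    list(id = sprintf("%s%d", g, i), group = g,
         simConfig = inVivoSimConfig(duration = 60, juxtaRate = 2000,
                                     spikeRateUp = 4, spikeRateDown = 0.5,
                                     kappa = if (g == "A") 0 else 1.5,
                                     seed = seed))
  }
  config <- list(
    recordings = c(lapply(1:4, function(i) mkRec("A", i, 200 + i)),
                   lapply(1:4, function(i) mkRec("B", i, 300 + i))),
    metrics = c("spikingRate", "ppc_20_40"),
    bands = list(c(20, 40)), computeStLFP = FALSE, seed = 1)
  out <- withr::local_tempdir()
  r1 <- runPipeline(config, outDir = out)
  expect_equal(nrow(r1$cohort), 8)
  expect_length(r1$failures, 0)
  expect_true(file.exists(file.path(out, "cohort.tsv")))
  expect_true(file.exists(file.path(out, "comparisons.json")))
  expect_true(file.exists(file.path(out, "run.log")))
  ## strong kappa contrast at 60 s: B locks, A does not
  cmp <- r1$comparisons[["ppc_20_40"]]
  expect_true(is(cmp, "GroupComparison"))
  ## determinism: identical numeric report on rerun
  r2 <- runPipeline(config)
  expect_identical(r1$cohort, r2$cohort)
  expect_identical(r1$comparisons[["spikingRate"]]@pValue,
                   r2$comparisons[["spikingRate"]]@pValue)
})

test_that("an empty recording list is refused before any work", {
  expect_error(runPipeline(list(recordings = list())), "no recordings")
})

test_that("per-recording failures are recorded and the pipeline continues", {
  config <- list(
    recordings = list(
      list(id = "bad", group = "A", lfpPath = "nope.csv",
           juxtaPath = "nope.csv"),
      list(id = "ok1", group = "A",
           simConfig = inVivoSimConfig(duration = 20, juxtaRate = 2000,
                                       spikeRateUp = 3, seed = 1)),
      list(id = "ok2", group = "B",
           simConfig = inVivoSimConfig(duration = 20, juxtaRate = 2000,
                                       spikeRateUp = 3, seed = 2))),
    metrics = "spikingRate", bands = list(c(20, 40)),
    computeStLFP = FALSE, seed = 1)
  r <- runPipeline(config)
  expect_named(r$failures, "bad")
  expect_equal(nrow(r$cohort), 2)
})
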