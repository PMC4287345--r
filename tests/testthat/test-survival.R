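test_that("product-limit estimates match hand computation", {
  fit <- kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(fit$surv, c(2/3, 1/3, 0))
  expect_equal(fit$n_risk, c(3L, 2L, 1L))
  # all censored: the curve never drops
  expect_identical(nrow(kaplan_meier(c(1, 2, 3), c(FALSE, FALSE, FALSE))), 0L)
  # censoring fixture, hand product-limit:
  # t=1 (5 at risk, 1 event) -> 4/5; t=2 (4 at risk incl. the tied
  # censoring, 1 event) -> 3/5; t=3 (2 at risk, 1 event) -> 3/10
  fit <- kaplan_meier(c(1, 2, 2, 3, 5), c(1, 0, 1, 1, 0))
  expect_equal(fit$time, c(1, 2, 3))
  expect_equal(fit$surv, c(4/5, 3/5, 3/10))
  expect_equal(fit$n_risk, c(5L, 4L, 2L))
  expect_error(kaplan_meier(numeric(), logical()), "non-empty")
})

test_that("the estimator agrees with the survival package on random data", {
  set.seed(19)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    times <- sample(1:15, n, replace = TRUE)
    events <- runif(n) < 0.7
    fit <- kaplan_meier(times, events)
    ref <- survival::survfit(survival::Surv(times, events) ~ 1)
    ref_at_events <- summary(ref, times = fit$time)$surv
    expect_equal(fit$surv, ref_at_events, tolerance = 1e-12)
  }
})

test_that("log-rank statistic matches the hand-computed O-E table", {
  # A: events at 1, 2, 3; B: events at 10, 20, 30; no censoring.
  # Event-time contributions to E_A and the variance:
  #  t=1: E=3/6,  V=(5/5)*(3*3/36)=0.25 ; t=2: E=2/5, V=6/25
  #  t=3: E=1/4,  V=3/16 ; t=10,20,30: A no longer at risk, E=V=0
  gA <- list(times = c(1, 2, 3), events = c(1, 1, 1))
  gB <- list(times = c(10, 20, 30), events = c(1, 1, 1))
  E <- 3/6 + 2/5 + 1/4
  V <- 0.25 + 6/25 + 3/16
  lr <- logrank_test(list(gA, gB))
  expect_equal(lr$statistic, (3 - E)^2 / V)
  expect_equal(lr$observed[1], 3)
  expect_equal(lr$expected[1], E)
  expect_equal(lr$direction, 1L)           # A has excess events
  ref <- survival::survdiff(
    survival::Surv(c(gA$times, gB$times), c(gA$events, gB$events)) ~
      rep(1:2, each = 3))
  expect_equal(lr$statistic, unname(ref$chisq), tolerance = 1e-12)
})

test_that("identical groups and rescaled times leave the test unchanged", {
  g <- list(times = c(1, 3, 5, 7), events = c(1, 0, 1, 1))
  lr <- logrank_test(list(g, g))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
  set.seed(29)
  gA <- list(times = sample(1:20, 12, TRUE), events = runif(12) < 0.8)
  gB <- list(times = sample(1:30, 15, TRUE), events = runif(15) < 0.8)
  lr1 <- logrank_test(list(gA, gB))
  lr2 <- logrank_test(list(
    list(times = gA$times * 2, events = gA$events),
    list(times = gB$times * 2, events = gB$events)))
  expect_equal(lr1$statistic, lr2$statistic)
  expect_error(logrank_test(list(gA)), "at least 2")
  expect_error(logrank_test(list(gA, list(times = numeric(),
                                          events = logical()))), "non-empty")
})

test_that("k-sample log-rank agrees with survdiff and detects the worse group", {
  set.seed(37)
  mk <- function(rate, n) list(times = round(rexp(n, rate), 2) + 0.01,
                               events = runif(n) < 0.85)
  gs <- list(mk(1, 20), mk(1, 20), mk(4, 20))   # third group dies fast
  lr3 <- logrank_test(gs)
  expect_equal(lr3$df, 2L)
  times <- unlist(lapply(gs, `[[`, "times"))
  events <- unlist(lapply(gs, `[[`, "events"))
  grp <- rep(1:3, each = 20)
  ref <- survival::survdiff(survival::Surv(times, events) ~ grp)
  expect_equal(lr3$statistic, unname(ref$chisq), tolerance = 1e-10)
  # the two similar groups alone show much less signal
  lr_sim <- logrank_test(gs[1:2])
  expect_lt(lr3$p, lr_sim$p)
})

test_that("patients are stratified with resistance-region precedence", {
  regions <- data.frame(
    region_id = "RES", gene_id = "G1", isoform_id = "G1.1", source = "pfam",
    start = 1L, end = 50L, name = "r")
  clinical <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5"), drug_id = "d",
    time_days = c(100, 200, 300, 400, 500), event = c(1, 1, 0, 1, 0))
  muts <- rbind(
    mut_row("P1", "G1", "G1.1", 10),    # inside the resistance region
    mut_row("P2", "G1", "G1.1", 80),    # same gene, outside
    mut_row("P3", "G1", "G1.1", 20),    # both inside and outside
    mut_row("P3", "G1", "G1.1", 90),
    mut_row("P4", "G2", "G2.1", 5))     # unrelated gene
  labels <- classify_patients(clinical, muts, regions)
  expect_equal(unname(labels[c("P1", "P2", "P3", "P4", "P5")]),
               c("resistant_pfr_mutated", "other_region_mutated",
                 "resistant_pfr_mutated", "gene_unmutated", "gene_unmutated"))
  # partition property with exclusions
  labels2 <- classify_patients(clinical, muts, regions,
                               profiled = c("P1", "P2", "P3"))
  expect_equal(length(labels2) + attr(labels2, "n_excluded"),
               nrow(clinical))
})

test_that("stratification separates survival when resistance mutations shorten it", {
  set.seed(47)
  regions <- data.frame(
    region_id = "RES", gene_id = "G1", isoform_id = "G1.1", source = "pfam",
    start = 1L, end = 50L, name = "r")
  n <- 60
  ids <- sprintf("P%02d", 1:n)
  group <- rep(c("res", "other", "none"), each = 20)
  muts <- rbind(
    do.call(rbind, lapply(ids[group == "res"], mut_row, gene = "G1",
                          iso = "G1.1", pos = 25)),
    do.call(rbind, lapply(ids[group == "other"], mut_row, gene = "G1",
                          iso = "G1.1", pos = 75)))
  times <- ifelse(group == "res", rexp(n, 1/100), rexp(n, 1/400))
  clinical <- data.frame(patient_id = ids, drug_id = "d",
                         time_days = round(times) + 1,
                         event = as.integer(runif(n) < 0.9))
  strat <- survival_stratification(clinical, muts, regions)
  expect_setequal(names(strat$fits),
                  c("resistant_pfr_mutated", "other_region_mutated",
                    "gene_unmutated"))
  expect_lt(strat$logrank$p, 0.01)
})
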