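test_that("stage I separates shifted region mutants from unmutated lines", {
  set.seed(101)
  samples <- sprintf("S%02d", 1:30)
  act <- activity_matrix(c(rnorm(10, 1.0, 0.2), rnorm(20, 3.0, 0.2)), samples)
  muts <- do.call(rbind, lapply(samples[1:10], mut_row, pos = 10))
  cohort <- tiny_cohort(act, muts)
  s1 <- stage1_test("R1", "d1", cohort)
  expect_lt(s1$p, 1e-4)
  expect_lt(s1$delta_median, 0)
  expect_equal(s1$n_mut, 10)
  expect_equal(s1$n_comp, 20)
  # oracle recheck: same groups through the enumeration-backed test
  expect_equal(s1$p, as.numeric(rank_sum_test(act[1:10, 1], act[11:30, 1])))
})

test_that("identically distributed groups give p = 1 and zero shift", {
  samples <- sprintf("S%02d", 1:12)
  act <- activity_matrix(rep(2.5, 12), samples)
  muts <- do.call(rbind, lapply(samples[1:4], mut_row))
  cohort <- tiny_cohort(act, muts)
  s1 <- stage1_test("R1", "d1", cohort)
  expect_equal(s1$p, 1)
  expect_equal(s1$delta_median, 0)
  expect_equal(effect_direction(s1$delta_median), "undetermined")
})

test_that("pairs below the minimum mutation count are not tested", {
  set.seed(5)
  samples <- sprintf("S%02d", 1:20)
  act <- activity_matrix(rnorm(20, 3, 0.5), samples)
  cohort <- tiny_cohort(act, mut_row("S01", pos = 10))
  res <- run_edrug(cohort)
  r1 <- res[res$region_id == "R1", ]
  expect_equal(r1$status, "insufficient_mutations")
  expect_true(is.na(r1$p_stage1))
  expect_equal(r1$n_region_mut, 1L)
})

test_that("opposite region effects cancel at the gene level but not regionally", {
  oc <- opposed_cohort(seed = 9)
  res <- run_edrug(oc$cohort)
  sig <- res[res$status == "significant", ]
  expect_setequal(sig$region_id, oc$regions$region_id[1:2])
  expect_setequal(sig$direction, c("sensitizing", "resistance"))
  up <- sig[sig$direction == "sensitizing", ]
  expect_equal(up$region_id, oc$truth$effects$region_id[oc$truth$effects$delta > 0])
  expect_true(all(sig$p_gene >= 0.01))
  expect_true(all(sig$p_stage1 < 0.01))
  expect_true(all(sig$p_stage2 < 0.05))
  # the gene-level contrast alone sees nothing
  expect_gt(gene_level_test(oc$regions$gene_id[1], "d1", oc$cohort), 0.01)
})

test_that("a uniformly shifted gene is excluded as a gene-level signal", {
  set.seed(303)
  samples <- sprintf("S%02d", 1:40)
  # all G1 mutations inside R1; carriers strongly shifted
  act <- activity_matrix(c(rnorm(12, 1.0, 0.3), rnorm(28, 3.0, 0.3)), samples)
  muts <- do.call(rbind, lapply(samples[1:12], mut_row, pos = 25))
  cohort <- tiny_cohort(act, muts)
  res <- run_edrug(cohort)
  r1 <- res[res$region_id == "R1", ]
  expect_equal(r1$status, "gene_level")
  expect_lt(r1$p_gene, 0.01)
  # gene-level and stage-I p coincide: the groups are identical
  expect_equal(r1$p_stage1, r1$p_gene)
  expect_error(gene_level_test("G2", "d1", cohort), "no profiled mutated")
})

test_that("stage II is absent when the whole gene mutates inside one region", {
  # same construction as above: no other-region mutants exist
  set.seed(71)
  samples <- sprintf("S%02d", 1:30)
  act <- activity_matrix(rnorm(30, 3, 0.4), samples)
  muts <- do.call(rbind, lapply(samples[1:5], mut_row, pos = 30))
  cohort <- tiny_cohort(act, muts)
  expect_true(is.na(stage2_test("R1", "d1", cohort)))
  # and with other-region mutants drawn from the same distribution, p is large
  muts2 <- rbind(muts, do.call(rbind, lapply(samples[6:10], mut_row, pos = 80)))
  cohort2 <- tiny_cohort(act, muts2)
  expect_gt(stage2_test("R1", "d1", cohort2), 0.2)
})

test_that("no significant call violates the three-threshold rule", {
  thr <- association_thresholds()
  for (seed in 1:6) {
    proteome <- generate_proteome(6, seed = seed)
    k <- min(2L, nrow(proteome$regions))
    truth <- synthetic_truth(
      data.frame(region_id = proteome$regions$region_id[seq_len(k)],
                 drug_id = "d1",
                 delta = c(1.5, -1.5)[seq_len(k)]),
      seed = seed)
    cohort <- generate_cohort(proteome, 60, truth = truth,
                              drugs = c("d1", "d2"))
    res <- run_edrug(cohort, thr)
    sig <- res[res$status == "significant", ]
    expect_true(all(sig$p_stage1 < thr$p_stage1))
    expect_true(all(sig$p_gene >= thr$p_gene))
    expect_true(all(sig$p_stage2 < thr$p_stage2))
    expect_true(all(res$n_region_mut[!is.na(res$p_stage1)] >= thr$min_mutated))
  }
})

test_that("the result table is deterministic and completely ordered", {
  oc <- opposed_cohort(seed = 17)
  res1 <- run_edrug(oc$cohort)
  res2 <- run_edrug(oc$cohort)
  expect_identical(res1, res2)
  expect_identical(order(res1$drug_id, res1$region_id), seq_len(nrow(res1)))
})

test_that("the comparison group flag switches the stage-I contrast", {
  set.seed(55)
  samples <- sprintf("S%02d", 1:30)
  act <- activity_matrix(rnorm(30, 3, 0.5), samples)
  muts <- rbind(
    do.call(rbind, lapply(samples[1:5], mut_row, pos = 10)),   # in R1
    do.call(rbind, lapply(samples[6:12], mut_row, pos = 90)))  # in R2 only
  cohort <- tiny_cohort(act, muts)
  gene_cmp <- stage1_test("R1", "d1", cohort, comparison = "gene_unmutated")
  region_cmp <- stage1_test("R1", "d1", cohort, comparison = "region_unmutated")
  expect_equal(gene_cmp$n_comp, 18)    # excludes all 12 gene mutants
  expect_equal(region_cmp$n_comp, 25)  # excludes only the 5 R1 mutants
})

test_that("effect directions map sign to resistance and sensitization", {
  expect_equal(effect_direction(c(-0.8, 0.8, 0, NA)),
               c("resistance", "sensitizing", "undetermined", NA))
})

test_that("threshold objects reject out-of-range levels", {
  expect_error(association_thresholds(p_stage1 = 0), "between 0 and 1")
  expect_error(association_thresholds(p_stage2 = 1), "between 0 and 1")
  expect_error(association_thresholds(min_mutated = 0), ">= 1")
})
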