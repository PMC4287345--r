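test_that("proteome generation is reproducible and structurally valid", {
  p1 <- generate_proteome(4, seed = 7)
  p2 <- generate_proteome(4, seed = 7)
  expect_identical(p1, p2)
  p3 <- generate_proteome(4, seed = 8)
  expect_false(identical(p1$isoforms$sequence, p3$isoforms$sequence))
  # regions lie within their isoform and never overlap within a gene
  lens <- setNames(nchar(p1$isoforms$sequence), p1$isoforms$isoform_id)
  expect_true(all(p1$regions$start >= 1))
  expect_true(all(p1$regions$end <= lens[p1$regions$isoform_id]))
  for (iso in unique(p1$regions$isoform_id)) {
    r <- p1$regions[p1$regions$isoform_id == iso, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
  }
})

test_that("genes without regions and infeasible packings are handled", {
  p0 <- generate_proteome(3, regions_per_gene = c(0, 0), idr_prob = 0,
                          seed = 2)
  expect_identical(nrow(p0$regions), 0L)
  expect_error(
    generate_proteome(2, regions_per_gene = c(5, 5),
                      length_range = c(100, 120),
                      region_length_range = c(50, 60), seed = 1),
    "infeasible packing")
})

test_that("cohort generation is a pure function of truth and seed", {
  proteome <- generate_proteome(3, seed = 4)
  truth <- synthetic_truth(seed = 12)
  c1 <- generate_cohort(proteome, 30, truth = truth, drugs = c("a", "b"))
  c2 <- generate_cohort(proteome, 30, truth = truth, drugs = c("a", "b"))
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$activity, c2$activity)
  c3 <- generate_cohort(proteome, 30, truth = synthetic_truth(seed = 13),
                        drugs = c("a", "b"))
  expect_false(identical(c1$mutations$position, c3$mutations$position))
  expect_true(all(c1$activity >= 0, na.rm = TRUE))
  # mutations carry consistent reference residues
  seqs <- setNames(proteome$isoforms$sequence, proteome$isoforms$isoform_id)
  expect_identical(
    unname(substring(seqs[c1$mutations$isoform_id], c1$mutations$position,
                     c1$mutations$position)),
    unname(c1$mutations$ref_aa))
})

test_that("a planted resistance effect shifts its carriers detectably", {
  proteome <- generate_proteome(2, seed = 21)
  region <- proteome$regions$region_id[1]
  truth <- synthetic_truth(
    data.frame(region_id = region, drug_id = "dA", delta = -2.0),
    noise_sd = 0.2, seed = 31)
  cohort <- generate_cohort(proteome, 120, truth = truth,
                            drugs = c("dA", "dB"),
                            min_mutated_per_effect = 15)
  res <- run_edrug(cohort)
  hit <- res[res$region_id == region & res$drug_id == "dA", ]
  expect_lt(hit$p_stage1, 1e-6)
  expect_equal(hit$direction, "resistance")
  # a lone shifted region drags the whole gene with it, so the gene-level
  # exclusion claims the pair: the region signal is not region-specific
  expect_equal(hit$status, "gene_level")
  # whereas the opposed two-region construction is fully region-specific
  oc <- opposed_cohort(seed = 21)
  rep <- recovery_report(run_edrug(oc$cohort), oc$truth)
  expect_equal(rep$tp, 2L)
  expect_equal(rep$sensitivity, 1.0)
})

test_that("carrier top-up guarantees the requested group size", {
  proteome <- generate_proteome(1, regions_per_gene = c(2, 2), idr_prob = 0,
                                seed = 6)
  truth <- synthetic_truth(
    data.frame(region_id = proteome$regions$region_id,
               drug_id = "d", delta = c(1, -1)),
    seed = 6)
  cohort <- generate_cohort(proteome, 100, per_sample_mutation_rate = 0.01,
                            truth = truth, drugs = "d",
                            min_mutated_per_effect = 12)
  asg <- assign_mutations_to_regions(cohort$mutations, proteome$regions)
  counts <- tapply(asg$sample_id, asg$region_id, function(s) length(unique(s)))
  expect_true(all(counts[proteome$regions$region_id] >= 12))
})

test_that("truth referencing unknown identifiers is rejected", {
  proteome <- generate_proteome(1, seed = 5)
  bad <- synthetic_truth(
    data.frame(region_id = "nope", drug_id = "d", delta = 1), seed = 5)
  expect_error(generate_cohort(proteome, 10, truth = bad, drugs = "d"),
               "unknown region")
  bad2 <- synthetic_truth(
    data.frame(region_id = proteome$regions$region_id[1],
               drug_id = "other", delta = 1), seed = 5)
  expect_error(generate_cohort(proteome, 10, truth = bad2, drugs = "d"),
               "drug not in")
})

test_that("recovery reports count direction mismatches as false positives", {
  results <- data.frame(
    region_id = c("R1", "R2", "R3"), drug_id = "d",
    status = c("significant", "significant", "fail_stage1"),
    direction = c("resistance", "sensitizing", NA),
    p_stage1 = c(1e-5, 1e-5, 0.5))
  truth <- synthetic_truth(
    data.frame(region_id = c("R1", "R2"), drug_id = "d",
               delta = c(-2, -2)),  # R2 planted as resistance...
    seed = 1)
  rep <- recovery_report(results, truth)
  expect_equal(rep$tp, 1L)   # R1 matches
  expect_equal(rep$fp, 1L)   # R2 called with the wrong direction
  expect_equal(rep$sensitivity, 0.5)
  # null truth: sensitivity undefined, false-positive rate reported
  null_rep <- recovery_report(results, synthetic_truth(seed = 1))
  expect_true(is.na(null_rep$sensitivity))
  expect_equal(null_rep$type_i_error, 2 / 3)
  expect_error(
    recovery_report(results[1:2, ], truth = synthetic_truth(
      data.frame(region_id = "RX", drug_id = "d", delta = 1), seed = 1)),
    "absent from results")
})
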