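toy_props <- function(values, group = "grp") {
  n <- length(values)
  props <- tibble::tibble(
    sample_id = rep(sprintf("s%d", seq_len(n)), 2),
    ancestry = rep(c("AF", "EU"), each = n),
    proportion = c(values, 1 - values)
  )
  meta <- tibble::tibble(sample_id = sprintf("s%d", seq_len(n)),
                         population_label = NA_character_,
                         declared_group = group, role = "query")
  list(props = props, meta = meta)
}

test_that("group summaries match hand arithmetic", {
  tp <- toy_props(c(0.1, 0.2, 0.3, 0.4))
  s <- summarize_groups(tp$props, tp$meta)
  af <- s[s$ancestry == "AF", ]
  expect_equal(af$mean, 0.25)
  expect_equal(af$sd, sd(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(af$median, 0.25)
  # type-7 quantiles of (.1, .2, .3, .4), worked by hand
  expect_equal(af$q25, 0.175)
  expect_equal(af$q75, 0.325)
  expect_equal(af$p10, 0.13)
  expect_equal(af$p90, 0.37)
  expect_equal(af$n, 4L)

  # percentile monotonicity and unit-sum of group means over ancestries
  expect_true(all(s$p10 <= s$q25 & s$q25 <= s$median &
                    s$median <= s$q75 & s$q75 <= s$p90))
  expect_equal(sum(s$mean), 1, tolerance = 1e-6)

  # identical individuals: all spread measures are 0
  tp0 <- toy_props(rep(0.3, 5))
  s0 <- summarize_groups(tp0$props, tp0$meta)
  expect_equal(s0$sd, c(0, 0))
  expect_equal(s0$q75 - s0$q25, c(0, 0))
})

test_that("group comparisons use the Welch t-test with degenerate guard", {
  tp <- toy_props(c(0.1, 0.2, 0.3, 0.15, 0.25, 0.35), group = "A")
  tp$meta$declared_group <- rep(c("A", "B"), each = 3)
  cmp <- compare_groups(tp$props, tp$meta, "A", "B", "AF")
  # hand Welch formula on the two triples
  xa <- c(0.1, 0.2, 0.3); xb <- c(0.15, 0.25, 0.35)
  t_hand <- (mean(xa) - mean(xb)) /
    sqrt(var(xa) / 3 + var(xb) / 3)
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_value, t.test(xa, xb)$p.value)
  expect_false(cmp$degenerate)

  # identical groups: t = 0, p = 1
  tp2 <- toy_props(rep(c(0.2, 0.3), 2), group = "A")
  tp2$meta$declared_group <- rep(c("A", "B"), each = 2)
  cmp2 <- compare_groups(tp2$props, tp2$meta, "A", "B", "AF")
  expect_equal(cmp2$statistic, 0)
  expect_equal(cmp2$p_value, 1)

  # constant equal groups: flagged degenerate, p = 1 by convention
  tp3 <- toy_props(rep(0.4, 4), group = "A")
  tp3$meta$declared_group <- rep(c("A", "B"), each = 2)
  cmp3 <- compare_groups(tp3$props, tp3$meta, "A", "B", "AF")
  expect_true(cmp3$degenerate)
  expect_equal(cmp3$p_value, 1)

  expect_error(compare_groups(tp$props, tp$meta[1:3, ], "A", "B", "AF"),
               "at least 2")
})

test_that("well-separated groups are detected in every seeded replicate", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    xa <- pmin(pmax(rnorm(50, 0.04, 0.1), 0), 1)
    xb <- pmin(pmax(rnorm(50, 0.24, 0.1), 0), 1)
    props <- tibble::tibble(
      sample_id = sprintf("s%d", 1:100),
      ancestry = "AF",
      proportion = c(xa, xb))
    props <- dplyr::bind_rows(props,
      dplyr::mutate(props, ancestry = "EU", proportion = 1 - proportion))
    meta <- tibble::tibble(sample_id = sprintf("s%d", 1:100),
                           population_label = NA_character_,
                           declared_group = rep(c("HC", "HNC"), each = 50),
                           role = "query")
    compare_groups(props, meta, "HC", "HNC", "AF")$p_value < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("discordance flags fire only on confident mismatches", {
  tp <- toy_props(c(0.99, 0.10, 0.50), group = "declaredEU")
  mapping <- c(declaredEU = "EU")
  # s1 is 0.99 AF under a group expected EU: exactly one flag
  fl <- flag_discordant(tp$props, tp$meta, mapping, cutoff = 0.95)
  expect_equal(fl$sample_id, "s1")
  expect_equal(fl$dominant_ancestry, "AF")
  expect_gte(fl$dominant_proportion, 0.95)

  # concordant confident samples are silent
  fl2 <- flag_discordant(tp$props, tp$meta, c(declaredEU = "AF"),
                         cutoff = 0.95)
  expect_equal(nrow(fl2), 0)
  # an impossible cutoff silences everything
  fl3 <- flag_discordant(tp$props, tp$meta, mapping, cutoff = 1.01)
  expect_equal(nrow(fl3), 0)
  # unmapped groups are never flagged
  fl4 <- flag_discordant(tp$props, tp$meta, c(other = "EU"), cutoff = 0.95)
  expect_equal(nrow(fl4), 0)
})

test_that("the pipeline runs end to end deterministically", {
  cfg <- sim_config(k = 3, loci = 16, alleles = 8, fst = 0.25, n_ref = 20,
                    cohorts = list(cohort("mixed", 8, alpha = c(2, 1, 1))),
                    seed = 61)
  p1 <- run_pipeline(cfg, k_fixed = 3, replicates = 2, burn_in = 300,
                     iterations = 300, master_seed = 4)
  p2 <- run_pipeline(cfg, k_fixed = 3, replicates = 2, burn_in = 300,
                     iterations = 300, master_seed = 4)
  expect_identical(p1$proportions, p2$proportions)
  expect_identical(p1$fst$theta, p2$fst$theta)

  # labels cover the three simulated populations bijectively
  expect_setequal(p1$labels$ancestry, paste0("pop", 1:3))
  expect_equal(nrow(p1$labels), 3)
  # cohort summary rows sum to 1 across ancestries within each group
  sums <- dplyr::summarise(dplyr::group_by(p1$summary, group),
                           total = sum(mean))
  expect_equal(sums$total, rep(1, nrow(sums)), tolerance = 1e-6)
})

test_that("panel reduction inside the pipeline preserves K recovery", {
  cfg <- sim_config(k = 3, loci = 16, alleles = 8, fst = 0.3, n_ref = 20,
                    seed = 67)
  p <- run_pipeline(cfg, k_range = 1:4, replicates = 2, burn_in = 300,
                    iterations = 300, master_seed = 2,
                    panel_sizes = c(12, 10))
  expect_equal(names(p$panels$panels), c("12", "10"))
  expect_equal(dplyr::n_distinct(p$genotypes$locus), 10)
  expect_equal(p$best_k, 3L)
  expect_setequal(p$labels$ancestry, paste0("pop", 1:3))
})
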