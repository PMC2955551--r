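# independent step-by-step transcription of the moment estimator, kept
# deliberately separate from the package implementation
oracle_theta <- function(counts, het, n) {
  r <- nrow(counts)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  num <- 0; den <- 0
  for (u in seq_len(ncol(counts))) {
    p <- counts[, u] / (2 * n)
    h <- het[, u] / n
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  num / den
}

test_that("locus theta matches an independent evaluation of the formulas", {
  cnt <- rbind(p1 = c(18, 2), p2 = c(2, 18))
  het <- rbind(p1 = c(2, 2), p2 = c(2, 2))
  n <- c(10, 10)
  lt <- locus_theta(cnt, het, n)
  expect_equal(lt$theta, oracle_theta(cnt, het, n), tolerance = 1e-12)

  # biallelic symmetry of the per-allele a component
  expect_equal(lt$components$a[1], lt$components$a[2], tolerance = 1e-12)

  # several random count configurations against the oracle
  set.seed(42)
  for (i in 1:10) {
    r <- sample(2:4, 1); A <- sample(2:5, 1); n_i <- sample(5:30, r)
    cnt_i <- matrix(0, r, A)
    het_i <- matrix(0, r, A)
    for (pp in seq_len(r)) {
      geno <- matrix(sample(A, 2 * n_i[pp], TRUE), ncol = 2)
      for (u in seq_len(A)) {
        cnt_i[pp, u] <- sum(geno == u)
        het_i[pp, u] <- sum(geno[, 1] != geno[, 2] &
                              (geno[, 1] == u | geno[, 2] == u))
      }
    }
    expect_equal(locus_theta(cnt_i, het_i, n_i)$theta,
                 oracle_theta(cnt_i, het_i, n_i), tolerance = 1e-12)
  }
})

test_that("theta is 1 at a fixed difference and <= 0 for identical populations", {
  fixed <- locus_theta(rbind(c(20, 0), c(0, 20)),
                       rbind(c(0, 0), c(0, 0)), c(10, 10))
  expect_equal(fixed$theta, 1)

  same <- locus_theta(rbind(c(12, 8), c(12, 8)),
                      rbind(c(6, 6), c(6, 6)), c(10, 10))
  expect_equal(same$components$s2, c(0, 0))
  expect_lte(same$theta, 0)
})

test_that("monomorphic loci are excluded and degenerate inputs error", {
  mono <- locus_theta(rbind(c(20, 0), c(20, 0)),
                      rbind(c(0, 0), c(0, 0)), c(10, 10))
  expect_true(is.nan(mono$theta))
  expect_error(locus_theta(rbind(c(2, 0)), rbind(c(0, 0)), 1), "2 populations")
  expect_error(locus_theta(rbind(c(1, 1), c(1, 1)),
                           rbind(c(1, 1), c(1, 1)), c(1, 1)), "nbar")
})

test_that("multi-locus theta is a ratio of sums and equals locus theta for one locus", {
  g1 <- build_geno(rbind(120L, 120L, 122L, 122L),
                   rbind(120L, 122L, 122L, 122L),
                   pops = c("A", "A", "B", "B"))
  res <- fst_global(g1)
  mats <- list(counts = rbind(A = c(3, 1), B = c(0, 4)),
               het = rbind(A = c(1, 1), B = c(0, 0)), n = c(2, 2))
  expect_equal(res$theta, oracle_theta(mats$counts, mats$het, mats$n))
  expect_equal(tidy(res)$theta, res$theta)

  # ratio of sums across loci differs from the mean of per-locus ratios
  d <- sim_dataset(sim_config(k = 2, loci = 10, alleles = 6, fst = 0.2,
                              n_ref = 25, seed = 2))
  res2 <- fst_global(d$genotypes)
  expect_false(isTRUE(all.equal(res2$theta,
                                mean(tidy(res2)$theta, na.rm = TRUE))))
  expect_lte(res2$theta, 1)
})

test_that("theta estimates track the simulated divergence", {
  d <- sim_dataset(sim_config(k = 2, loci = 36, alleles = 10, fst = 0.15,
                              n_ref = 100, seed = 31))
  expect_equal(fst_global(d$genotypes)$theta, 0.15, tolerance = 0.25)
})

test_that("pairwise theta is symmetric, ordered by divergence, and ~0 within", {
  d <- sim_dataset(sim_config(k = 3, loci = 30, alleles = 8,
                              fst = c(0.05, 0.05, 0.25), n_ref = 60,
                              seed = 9))
  pw <- fst_pairwise(d$genotypes)
  m <- as.matrix(pw)
  expect_equal(m, t(m))
  # pop3 drifted far more: its pairs exceed the close (pop1, pop2) pair
  expect_gt(m["pop1", "pop3"], m["pop1", "pop2"])
  expect_gt(m["pop2", "pop3"], m["pop1", "pop2"])

  # two copies of the same population: theta ~ 0 up to estimator noise
  g <- d$genotypes[d$genotypes$population_label == "pop1", ]
  half <- unique(g$sample_id)[1:30]
  g$population_label <- ifelse(g$sample_id %in% half, "copy1", "copy2")
  expect_lt(abs(fst_global(g)$theta), 0.02)
})

test_that("theta is invariant to population order and count doubling keeps frequencies", {
  g <- rand_geno(n = 30, L = 6, n_alleles = 5, seed = 13)
  base <- fst_global(g)$theta
  relab <- dplyr::mutate(g, population_label =
    dplyr::recode(population_label, A = "Z", B = "A", .default = ""))
  expect_equal(fst_global(relab)$theta, base, tolerance = 1e-12)

  cnt <- rbind(c(18, 2), c(2, 18)); het <- rbind(c(2, 2), c(2, 2))
  l1 <- locus_theta(cnt, het, c(10, 10))
  l2 <- locus_theta(2 * cnt, 2 * het, c(20, 20))
  expect_equal(l2$components$pbar, l1$components$pbar)
  expect_equal(l2$components$hbar, l1$components$hbar)
  expect_false(identical(l1$theta, l2$theta))  # n-dependent corrections move
})
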