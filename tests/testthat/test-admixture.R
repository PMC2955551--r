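# minimal hand-built copy data: one individual, one biallelic locus is the
# smallest state the update kernels accept; `one_copy` trims to a single
# gene copy for the closed-form assignment checks
one_copy_data <- function() {
  list(ind = 1L, fa = 1L, locus_of_flat = c(1L, 1L), n = 1L)
}

test_that("assignment update follows the closed-form posterior", {
  d <- one_copy_data()
  # K = 1: everything lands in the single cluster
  z1 <- admix_update_z(d, matrix(1, 1, 1), matrix(c(0.7, 0.3), 1, 2))
  expect_equal(z1$z, 1L)

  # exclusive allele: zero frequency in cluster 2 forces cluster 1
  Q <- matrix(0.5, 1, 2)
  P_excl <- rbind(c(1, 0), c(0, 1))
  set.seed(1)
  expect_true(all(replicate(50, admix_update_z(d, Q, P_excl)$z) == 1L))

  # q = (.5, .5), p = (.8, .2): posterior P(z = 1) = 0.8
  P <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  set.seed(2)
  draws <- replicate(2e4, admix_update_z(d, Q, P)$z)
  expect_equal(mean(draws == 1L), 0.8, tolerance = 0.01)
})

test_that("frequency update draws from Dirichlet(lambda + counts)", {
  d <- one_copy_data()
  # counts (8, 0) with lambda = 1: posterior mean (9/10, 1/10)
  d8 <- list(ind = rep(1L, 8), fa = rep(1L, 8),
             locus_of_flat = c(1L, 1L), n = 1L)
  set.seed(3)
  draws <- replicate(2e4, admix_update_p(d8, rep(1L, 8), k = 1)[1, ])
  expect_equal(rowMeans(draws), c(0.9, 0.1), tolerance = 0.01)

  # no copies assigned to cluster 2: its row is a pure prior draw (uniform mean)
  set.seed(4)
  draws2 <- replicate(2e4, admix_update_p(d8, rep(1L, 8), k = 2)[2, ])
  expect_equal(rowMeans(draws2), c(0.5, 0.5), tolerance = 0.01)

  # every draw satisfies the per-locus simplex constraint
  d2loc <- list(ind = 1:2, fa = c(1L, 3L),
                locus_of_flat = c(1L, 1L, 2L, 2L, 2L), n = 2L)
  set.seed(5)
  for (i in 1:20) {
    P <- admix_update_p(d2loc, c(1L, 2L), k = 2)
    expect_equal(rowSums(P[, 1:2]), c(1, 1), tolerance = 1e-12)
    expect_equal(rowSums(P[, 3:5]), c(1, 1), tolerance = 1e-12)
  }
})

test_that("ancestry update draws from Dirichlet(alpha + copy counts)", {
  # both copies of a single locus in cluster 1, K = 2, alpha = (1, 1):
  # posterior mean q1 = (1 + 2) / (2 + 2) = 3/4
  d <- list(ind = c(1L, 1L), fa = c(1L, 1L), locus_of_flat = c(1L, 1L), n = 1L)
  set.seed(6)
  draws <- replicate(2e4, admix_update_q(d, c(1L, 1L), k = 2,
                                         alpha = c(1, 1))[1, ])
  expect_equal(rowMeans(draws), c(0.75, 0.25), tolerance = 0.01)
  expect_true(all(abs(colSums(draws) - 1) < 1e-12))

  # an all-missing individual (no copies) draws from the prior
  d_empty <- list(ind = integer(0), fa = integer(0),
                  locus_of_flat = c(1L, 1L), n = 1L)
  set.seed(7)
  draws2 <- replicate(2e4, admix_update_q(d_empty, integer(0), k = 2,
                                          alpha = c(2, 1))[1, ])
  expect_equal(rowMeans(draws2), c(2, 1) / 3, tolerance = 0.01)
})

test_that("alpha Metropolis decision matches an independent density ratio", {
  ldirichlet <- function(q, a) {
    sum(apply(q, 1, function(r) lgamma(sum(a)) - sum(lgamma(a)) +
                sum((a - 1) * log(r))))
  }
  Q <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  for (s in 1:20) {
    alpha <- c(0.5, 0.5)
    set.seed(s)
    got <- admix_update_alpha(Q, alpha, proposal_sd = 0.3, alpha_max = 10,
                              separate = FALSE)
    # replay the kernel's RNG stream: one normal proposal, then (only when
    # the log ratio is negative) one uniform accept draw
    set.seed(s)
    prop <- alpha[1] + rnorm(1) * 0.3
    want <- alpha
    if (prop > 0 && prop <= 10) {
      logr <- ldirichlet(Q, rep(prop, 2)) - ldirichlet(Q, rep(alpha[1], 2))
      accept <- logr >= 0 || runif(1) < exp(logr)
      if (accept) want <- rep(prop, 2)
    }
    expect_equal(got, want, tolerance = 1e-12)
  }

  # separate alphas update componentwise and stay inside (0, alpha_max]
  set.seed(99)
  a <- c(1, 1)
  for (i in 1:200) a <- admix_update_alpha(Q, a, proposal_sd = 0.5,
                                           alpha_max = 2, separate = TRUE)
  expect_true(all(a > 0 & a <= 2))
})

test_that("log-likelihood integrates assignments out", {
  g <- rand_geno(n = 6, L = 3, n_alleles = 3, seed = 21)
  d <- admix_data(g)
  # K = 1 with pooled observed frequencies: multinomial log-probability
  pooled <- vapply(seq_len(d$atot), function(j) sum(d$fa == j), 1)
  P <- matrix(0, 1, d$atot)
  for (l in unique(d$locus_of_flat)) {
    idx <- which(d$locus_of_flat == l)
    P[1, idx] <- pooled[idx] / sum(pooled[idx])
  }
  Q <- matrix(1, d$n, 1)
  expect_equal(admix_loglik(d, Q, P), sum(log(P[1, d$fa])))

  # label symmetry: permuting clusters of Q and P together changes nothing
  set.seed(22)
  K <- 3
  Q3 <- matrix(rgamma(d$n * K, 1), d$n, K); Q3 <- Q3 / rowSums(Q3)
  P3 <- admix_update_p(d, sample.int(K, length(d$fa), TRUE), k = K)
  perm <- c(3, 1, 2)
  expect_equal(admix_loglik(d, Q3[, perm], P3[perm, ]),
               admix_loglik(d, Q3, P3), tolerance = 1e-12)
})

test_that("the sampler is reproducible and respects simplex constraints", {
  g <- rand_geno(n = 12, L = 4, n_alleles = 4, seed = 31)
  f1 <- run_admixture(g, k = 2, burn_in = 50, iterations = 50, seed = 5)
  f2 <- run_admixture(g, k = 2, burn_in = 50, iterations = 50, seed = 5)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$logliks, f2$logliks)
  expect_identical(f1$alpha, f2$alpha)

  expect_equal(rowSums(as.matrix(f1$Q[, -1])), rep(1, 12), tolerance = 1e-9)
  for (p in f1$P) expect_equal(unname(rowSums(p)), rep(1, 2), tolerance = 1e-9)
  expect_lte(f1$lnpd, f1$loglik_mean)

  fk1 <- run_admixture(g, k = 1, burn_in = 20, iterations = 20, seed = 1)
  expect_equal(fk1$Q$cluster1, rep(1, 12))

  expect_error(run_admixture(g[1:4, ], k = 50, burn_in = 5, iterations = 5,
                             seed = 1), "clusters")
})

test_that("posterior Q approaches truth as loci grow", {
  rmse_at <- function(L) {
    d <- sim_dataset(sim_config(k = 2, loci = L, alleles = 8, fst = 0.3,
                                n_ref = 20, seed = 101))
    fit <- run_admixture(d$genotypes, k = 2, burn_in = 400,
                         iterations = 400, seed = 11)
    aligned_q_rmse(fit$Q, d$truth$Q)
  }
  r <- vapply(c(6L, 24L, 72L), rmse_at, 1)
  expect_lt(r[2], r[1])
  expect_lt(r[3], r[2])
  expect_lt(r[3], 0.1)
})

test_that("clusters are labelled by the dominant reference group", {
  Q <- tibble::tibble(sample_id = c("r1", "r2", "q1"),
                      cluster1 = c(1, 0, 0.5),
                      cluster2 = c(0, 1, 0.5))
  meta <- tibble::tibble(sample_id = c("r1", "r2", "q1"),
                         population_label = c("AF", "EU", NA),
                         declared_group = NA_character_,
                         role = c("reference", "reference", "query"))
  labs <- label_clusters_by_reference(Q, meta)
  expect_equal(labs$ancestry, c("AF", "EU"))
  expect_false(any(labs$tied))

  # tie: both groups contribute equally; lexicographic winner, flagged
  Q2 <- tibble::tibble(sample_id = c("r1", "r2"),
                       cluster1 = c(0.5, 0.5), cluster2 = c(0.5, 0.5))
  labs2 <- label_clusters_by_reference(Q2, meta[1:2, ])
  expect_equal(labs2$ancestry, c("AF", "AF"))
  expect_true(all(labs2$tied))

  expect_error(label_clusters_by_reference(Q, meta[3, ]), "no reference")

  # simulated five-population references: the map recovers every identity
  d <- sim_dataset(sim_config(k = 5, loci = 30, alleles = 8, fst = 0.3,
                              n_ref = 15, seed = 77))
  fit <- run_admixture(d$genotypes, k = 5, burn_in = 500, iterations = 500,
                       seed = 3)
  labs5 <- label_clusters_by_reference(fit, sample_metadata(d$genotypes))
  expect_setequal(labs5$ancestry, paste0("pop", 1:5))
})
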