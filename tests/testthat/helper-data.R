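# shared fixture builders (all data generated in code)

# two individuals x two loci, one missing call
toy_geno <- function() {
  genotype_tibble(
    sample_id = rep(c("s1", "s2"), each = 2),
    locus = rep(c("L1", "L2"), 2),
    a1 = c(120L, 200L, 120L, NA),
    a2 = c(124L, 204L, 124L, NA),
    population_label = rep(c("popA", "popB"), each = 2)
  )
}

# genotype tibble from allele-code matrices (rows = individuals)
build_geno <- function(a1, a2, pops, ids = NULL) {
  n <- nrow(a1); L <- ncol(a1)
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  genotype_tibble(
    sample_id = rep(ids, each = L),
    locus = rep(sprintf("L%02d", seq_len(L)), n),
    a1 = as.vector(t(a1)), a2 = as.vector(t(a2)),
    population_label = rep(pops, each = L)
  )
}

# random multi-allelic genotypes, optional missing calls
rand_geno <- function(n = 20, L = 5, n_alleles = 4, pops = NULL,
                      missing_rate = 0, seed = 1) {
  set.seed(seed)
  codes <- 100L + 2L * seq_len(n_alleles)
  a1 <- matrix(sample(codes, n * L, TRUE), n, L)
  a2 <- matrix(sample(codes, n * L, TRUE), n, L)
  if (missing_rate > 0) {
    drop <- matrix(runif(n * L) < missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  pops <- pops %||% rep(c("A", "B"), length.out = n)
  build_geno(a1, a2, pops)
}

# all permutations of 1..n (independent of the package's internals)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# label-aligned RMSE between an estimated Q tibble (sample_id + cluster cols)
# and a truth Q tibble (sample_id + population cols): minimum over all
# column permutations
aligned_q_rmse <- function(q_hat, q_true) {
  m_hat <- as.matrix(q_hat[match(q_true$sample_id, q_hat$sample_id), -1])
  m_true <- as.matrix(q_true[, -1])
  best <- Inf
  for (p in all_perms(ncol(m_true))) {
    best <- min(best, sqrt(mean((m_hat[, p] - m_true)^2)))
  }
  best
}
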