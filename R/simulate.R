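#' Dirichlet draws (internal)
#'
#' One row per draw; zero gamma variates are clamped at 1e-300 so the
#' simplex never carries exact zeros.
#' @noRd
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1), n, k)
  g <- pmax(g, 1e-300)
  g / rowSums(g)
}

#' Cohort specification for the genotype simulator
#'
#' A cohort is a block of query samples sharing a self-declared group
#' label whose true ancestry is either a fixed proportion vector `q` or a
#' per-individual draw from `Dirichlet(alpha)`.
#'
#' @param label self-declared group label.
#' @param n number of individuals.
#' @param q fixed ancestry proportion vector (length = number of ancestral
#'   populations, sums to 1), or `NULL`.
#' @param alpha Dirichlet parameter vector for per-individual ancestry, or
#'   `NULL`. Exactly one of `q`, `alpha` must be given.
#' @return A cohort spec list, for [sim_config()]'s `cohorts`.
#' @export
cohort <- function(label, n, q = NULL, alpha = NULL) {
  if (is.null(q) == is.null(alpha)) {
    abort("give exactly one of `q` (fixed) or `alpha` (Dirichlet) per cohort")
  }
  if (!is.null(q) && abs(sum(q) - 1) > 1e-8) abort("cohort q must sum to 1")
  list(label = label, n = as.integer(n), q = q, alpha = alpha)
}

#' Configuration for the Balding-Nichols genotype simulator
#'
#' Describes the generative model every analysis stage is tested against:
#' `k` ancestral populations whose allele frequencies at each locus drift
#' away from a shared ancestral frequency vector under the Balding-Nichols
#' Dirichlet model with per-population divergence `fst`; reference panels
#' of known one-hot ancestry; and optional admixed query cohorts carrying
#' self-declared labels. Defaults mirror a compact continental-AIM panel:
#' 5 populations, 36 microsatellite-like loci with 10 alleles each,
#' divergence 0.2, 50 reference samples per population.
#'
#' @param k number of ancestral populations.
#' @param loci number of loci.
#' @param alleles alleles per locus (scalar or per-locus vector, all >= 2).
#' @param fst divergence parameter in (0, 1), scalar or one per population.
#' @param gamma concentration of the ancestral Dirichlet frequency draw.
#' @param n_ref reference individuals per population (scalar or vector).
#' @param cohorts list of [cohort()] specs.
#' @param missing_rate per-(individual, locus) missing probability.
#' @param seed RNG seed for [sim_dataset()]; `NULL` leaves the RNG alone.
#' @param pop_names ancestral population names.
#' @return A `sim_config` list.
#' @export
sim_config <- function(k = 5, loci = 36, alleles = 10, fst = 0.2,
                       gamma = 1, n_ref = 50, cohorts = list(),
                       missing_rate = 0, seed = NULL, pop_names = NULL) {
  alleles <- rep_len(as.integer(alleles), loci)
  fst <- rep_len(as.numeric(fst), k)
  n_ref <- rep_len(as.integer(n_ref), k)
  if (any(alleles < 2)) abort("every locus needs at least 2 alleles")
  if (any(fst <= 0 | fst >= 1)) abort("fst must lie in (0, 1)")
  if (gamma <= 0) abort("gamma must be positive")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate in [0, 1)")
  pop_names <- pop_names %||% paste0("pop", seq_len(k))
  for (co in cohorts) {
    len <- length(co$q %||% co$alpha)
    if (len != k) abort(paste0("cohort '", co$label, "' ancestry law has ",
                               len, " entries; expected ", k))
  }
  structure(list(k = k, loci = loci, alleles = alleles, fst = fst,
                 gamma = gamma, n_ref = n_ref, cohorts = cohorts,
                 missing_rate = missing_rate, seed = seed,
                 pop_names = pop_names),
            class = "sim_config")
}

#' Draw ancestral and population allele frequencies
#'
#' Ancestral frequencies at each locus are `Dirichlet(gamma, ..., gamma)`;
#' each population's frequencies drift from them as
#' `Dirichlet(p_anc * (1 - F_k) / F_k)` (the multi-allelic Balding-Nichols
#' form), so each allele frequency has mean `p_anc` and variance
#' `p_anc * (1 - p_anc) * F_k`.
#'
#' @param cfg a [sim_config()].
#' @return A list: `p_anc`, per-locus ancestral frequency vectors, and `P`,
#'   per-locus population-by-allele frequency matrices.
#' @export
draw_frequencies <- function(cfg) {
  p_anc <- vector("list", cfg$loci)
  P <- vector("list", cfg$loci)
  for (l in seq_len(cfg$loci)) {
    A <- cfg$alleles[l]
    p_anc[[l]] <- as.numeric(rdirichlet(1, rep(cfg$gamma, A)))
    P[[l]] <- matrix(NA_real_, cfg$k, A,
                     dimnames = list(cfg$pop_names, NULL))
    for (kk in seq_len(cfg$k)) {
      f <- cfg$fst[kk]
      P[[l]][kk, ] <- rdirichlet(1, p_anc[[l]] * (1 - f) / f)
    }
  }
  list(p_anc = p_anc, P = P)
}

#' Simulate one individual's genotypes
#'
#' Each of the two gene copies at every locus first draws an ancestral
#' population from `Categorical(q)`, then an allele from that population's
#' frequency vector; this is the generative twin of the admixture model
#' fitted by [run_admixture()].
#'
#' @param q ancestry proportion vector (length k, sums to 1).
#' @param freqs frequency object from [draw_frequencies()].
#' @param missing_rate per-locus probability the call is masked.
#' @return A list: `genotypes`, a tibble with `locus`, `a1`, `a2` (integer
#'   allele codes `100 + 2 * index`), and `z`, the loci x 2 matrix of true
#'   copy ancestries (`NA` where masked).
#' @export
simulate_individual <- function(q, freqs, missing_rate = 0) {
  L <- length(freqs$P)
  z <- matrix(NA_integer_, L, 2)
  a <- matrix(NA_integer_, L, 2)
  for (l in seq_len(L)) {
    zk <- sample.int(length(q), 2, replace = TRUE, prob = q)
    for (cp in 1:2) a[l, cp] <- sample.int(ncol(freqs$P[[l]]), 1,
                                           prob = freqs$P[[l]][zk[cp], ])
    z[l, ] <- zk
  }
  if (missing_rate > 0) {
    drop <- runif(L) < missing_rate
    a[drop, ] <- NA_integer_
    z[drop, ] <- NA_integer_
  }
  list(genotypes = tibble::tibble(locus = locus_names(L),
                                  a1 = allele_code(a[, 1]),
                                  a2 = allele_code(a[, 2])),
       z = z)
}

locus_names <- function(L) sprintf("L%03d", seq_len(L))
allele_code <- function(idx) ifelse(is.na(idx), NA_integer_,
                                    100L + 2L * as.integer(idx))

#' Simulate a full reference-plus-cohort dataset
#'
#' Generates reference panels (one-hot true ancestry, `role = "reference"`)
#' for every ancestral population and admixed query cohorts per the config,
#' all from one Balding-Nichols frequency draw. Allele indices are emitted
#' as fragment-size-like codes `100 + 2 * index` with no semantic content.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_dataset`: `genotypes` (genotype tibble),
#'   `truth` (list: `Q`, tibble of true ancestry proportions per sample;
#'   `P`, per-locus population frequency matrices; `p_anc`), and `config`.
#' @export
#' @examples
#' d <- sim_dataset(sim_config(k = 2, loci = 6, n_ref = 10, seed = 42))
#' dplyr::count(d$genotypes, population_label)
sim_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  freqs <- draw_frequencies(cfg)
  K <- cfg$k; L <- cfg$loci

  ids <- character(0); pop <- character(0); grp <- character(0)
  role <- character(0)
  Q <- NULL
  for (kk in seq_len(K)) {
    nk <- cfg$n_ref[kk]
    if (nk == 0) next
    ids <- c(ids, sprintf("ref_%s_%03d", cfg$pop_names[kk], seq_len(nk)))
    pop <- c(pop, rep(cfg$pop_names[kk], nk))
    grp <- c(grp, rep(NA_character_, nk))
    role <- c(role, rep("reference", nk))
    qk <- matrix(0, nk, K); qk[, kk] <- 1
    Q <- rbind(Q, qk)
  }
  for (co in cfg$cohorts) {
    ids <- c(ids, sprintf("%s_%03d", co$label, seq_len(co$n)))
    pop <- c(pop, rep(NA_character_, co$n))
    grp <- c(grp, rep(co$label, co$n))
    role <- c(role, rep("query", co$n))
    qc <- if (!is.null(co$q)) {
      matrix(rep(co$q, each = co$n), co$n, K)
    } else {
      rdirichlet(co$n, co$alpha)
    }
    Q <- rbind(Q, qc)
  }
  N <- length(ids)
  if (N == 0) abort("config yields no individuals")

  # per-locus vectorized draws: copy ancestry from each row of Q, then an
  # allele from that ancestry's frequency vector
  cumQ <- t(apply(Q, 1, cumsum))
  a1 <- matrix(NA_integer_, N, L); a2 <- matrix(NA_integer_, N, L)
  draw_copy <- function(P_l, cumP) {
    u <- runif(N)
    zk <- rep(1L, N)
    if (K > 1) for (k in seq_len(K - 1)) zk <- zk + (u > cumQ[, k])
    u2 <- runif(N)
    av <- rep(1L, N)
    A <- ncol(P_l)
    if (A > 1) for (j in seq_len(A - 1)) av <- av + (u2 > cumP[zk, j])
    av
  }
  for (l in seq_len(L)) {
    cumP <- t(apply(freqs$P[[l]], 1, cumsum))
    a1[, l] <- draw_copy(freqs$P[[l]], cumP)
    a2[, l] <- draw_copy(freqs$P[[l]], cumP)
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(N * L) < cfg$missing_rate, N, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }

  geno <- genotype_tibble(
    sample_id = rep(ids, each = L),
    locus = rep(locus_names(L), times = N),
    a1 = allele_code(as.vector(t(a1))),
    a2 = allele_code(as.vector(t(a2))),
    population_label = rep(pop, each = L),
    declared_group = rep(grp, each = L),
    role = rep(role, each = L)
  )
  Q_tbl <- tibble::as_tibble(Q, .name_repair = ~cfg$pop_names)
  Q_tbl <- dplyr::bind_cols(tibble::tibble(sample_id = ids), Q_tbl)
  structure(list(genotypes = geno,
                 truth = list(Q = Q_tbl, P = freqs$P, p_anc = freqs$p_anc),
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated genotype dataset:",
      dplyr::n_distinct(x$genotypes$sample_id), "samples x",
      x$config$loci, "loci,", x$config$k, "ancestral populations\n")
  invisible(x)
}
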