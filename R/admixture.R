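#' Prepare a genotype table for the admixture sampler
#'
#' Flattens a genotype tibble into the indexed gene-copy representation the
#' Gibbs updates operate on: one entry per non-missing gene copy with its
#' individual index and its (locus, allele) column in a flattened allele
#' space. Missing calls are simply absent, so they contribute to no update.
#'
#' @param geno a genotype tibble.
#' @return An `admix_data` list: `ind`, `fa` (1-based copy indices),
#'   `locus_of_flat`, `n`, `samples`, `loci`, `alleles` (per-locus observed
#'   allele codes), `atot`.
#' @export
admix_data <- function(geno) {
  geno <- validate_genotypes(geno)
  samples <- unique(geno$sample_id)
  loci <- unique(geno$locus)
  alleles <- locus_alleles(geno) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(codes = list(sort(.data$allele)), .groups = "drop")
  alleles <- setNames(alleles$codes, alleles$locus)[loci]
  sizes <- lengths(alleles)
  offset <- setNames(cumsum(c(0L, sizes[-length(sizes)])), loci)

  obs <- geno[!is.na(geno$a1), ]
  li <- match(obs$locus, loci)
  fa1 <- offset[li] + vapply(seq_len(nrow(obs)), function(r)
    match(obs$a1[r], alleles[[li[r]]]), 1L)
  fa2 <- offset[li] + vapply(seq_len(nrow(obs)), function(r)
    match(obs$a2[r], alleles[[li[r]]]), 1L)
  ii <- match(obs$sample_id, samples)
  structure(list(
    ind = as.integer(c(ii, ii)),
    fa = as.integer(c(fa1, fa2)),
    locus_of_flat = as.integer(rep(seq_along(loci), times = sizes)),
    n = length(samples),
    samples = samples,
    loci = loci,
    alleles = alleles,
    atot = sum(sizes)
  ), class = "admix_data")
}

#' Admixture sampler configuration
#'
#' Desk-scale defaults (5,000 burn-in + 5,000 kept sweeps) suit simulated
#' panels of tens of loci; production-scale runs on real panels use far
#' longer chains (hundreds of thousands of sweeps) via these fields.
#' `lambda` is the symmetric Dirichlet prior on cluster allele frequencies;
#' `alpha` is the Dirichlet admixture parameter, either one per cluster
#' (`separate_alpha = TRUE`) or shared, updated by a Metropolis step with a
#' uniform prior on `(0, alpha_max]` when `infer_alpha` is on.
#'
#' @param k number of clusters (K >= 1).
#' @param burn_in,iterations discarded and kept Gibbs sweeps.
#' @param lambda allele-frequency Dirichlet prior parameter.
#' @param infer_alpha update alpha by Metropolis? (otherwise fixed).
#' @param separate_alpha one alpha per cluster?
#' @param alpha_init initial alpha.
#' @param alpha_proposal_sd Metropolis normal proposal sd.
#' @param alpha_max upper bound of the uniform prior on alpha.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed RNG seed for the run.
#' @return An `admixture_config` list.
#' @export
admixture_config <- function(k, burn_in = 5000, iterations = 5000,
                             lambda = 1, infer_alpha = TRUE,
                             separate_alpha = TRUE, alpha_init = 1,
                             alpha_proposal_sd = 0.025, alpha_max = 10,
                             thin = 1, seed = NULL) {
  k <- as.integer(k)
  if (k < 1) abort("k must be >= 1")
  if (burn_in < 1 || iterations < 1) abort("burn_in and iterations must be >= 1")
  if (lambda <= 0) abort("lambda must be positive")
  if (alpha_init <= 0 || alpha_max <= 0 || alpha_proposal_sd <= 0) {
    abort("alpha_init, alpha_max and alpha_proposal_sd must be positive")
  }
  structure(list(k = k, burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), lambda = lambda,
                 infer_alpha = infer_alpha, separate_alpha = separate_alpha,
                 alpha_init = alpha_init,
                 alpha_proposal_sd = alpha_proposal_sd,
                 alpha_max = alpha_max, thin = as.integer(thin),
                 seed = seed),
            class = "admixture_config")
}

#' Single Gibbs updates of the admixture sampler
#'
#' These expose one sweep's building blocks on explicit state, mainly for
#' checking the sampler against closed-form conditionals; [run_admixture()]
#' cycles the same kernels. `admix_update_z` resamples each gene copy's
#' cluster with probability proportional to `q[i, k] * p[k, allele]` and
#' also returns the assignment-integrated data log-likelihood of the
#' current `(Q, P)`; `admix_update_p` draws cluster allele frequencies from
#' `Dirichlet(lambda + counts)`; `admix_update_q` draws each individual's
#' ancestry from `Dirichlet(alpha + copy counts)`; `admix_update_alpha`
#' performs the Metropolis step.
#'
#' @param data an [admix_data()] object.
#' @param Q individuals x K ancestry matrix.
#' @param P K x total-alleles frequency matrix (rows normalized within each
#'   locus block).
#' @param z integer vector of per-copy cluster assignments.
#' @param k number of clusters.
#' @param lambda,alpha prior parameters.
#' @param proposal_sd,alpha_max,separate Metropolis settings.
#' @return `admix_update_z`: list with `z` and `loglik`; `admix_update_p`:
#'   a new `P`; `admix_update_q`: a new `Q`; `admix_update_alpha`: a new
#'   `alpha` vector; `admix_loglik`: a scalar.
#' @name admix-updates
NULL

#' @rdname admix-updates
#' @export
admix_update_z <- function(data, Q, P) {
  .cpp_update_z(Q, P, data$ind, data$fa)
}

#' @rdname admix-updates
#' @export
admix_update_p <- function(data, z, k, lambda = 1) {
  .cpp_update_p(z, data$fa, data$locus_of_flat, as.integer(k), lambda)
}

#' @rdname admix-updates
#' @export
admix_update_q <- function(data, z, k, alpha) {
  .cpp_update_q(z, data$ind, data$n, as.integer(k), rep_len(alpha, k))
}

#' @rdname admix-updates
#' @export
admix_update_alpha <- function(Q, alpha, proposal_sd = 0.025,
                               alpha_max = 10, separate = TRUE) {
  .cpp_update_alpha(Q, alpha, proposal_sd, alpha_max, separate)
}

#' @rdname admix-updates
#' @export
admix_loglik <- function(data, Q, P) {
  .cpp_loglik(Q, P, data$ind, data$fa)
}

#' Fit the admixture model by Gibbs sampling
#'
#' Unsupervised Bayesian clustering of diploid multi-allelic genotypes:
#' every gene copy carries a latent cluster assignment, clusters carry
#' allele-frequency vectors with a symmetric `Dirichlet(lambda)` prior, and
#' each individual's ancestry proportions follow a `Dirichlet(alpha)`
#' prior whose parameter is itself inferred. Reference and query samples
#' are analyzed jointly with no prior population information. The model
#' score `lnP(D)` is estimated from the kept assignment-integrated
#' log-likelihoods as `mean - variance / 2`.
#'
#' The run is fully reproducible given `seed`. Cluster labels are
#' arbitrary (label switching); use [align_runs()] across replicates and
#' [label_clusters_by_reference()] to anchor them.
#'
#' @param geno a genotype tibble (or an [admix_data()] object).
#' @param k number of clusters; ignored when `config` is supplied.
#' @param ... passed to [admixture_config()].
#' @param config an [admixture_config()]; overrides `k` and `...`.
#' @return An object of class `admixture_fit`: `Q` (tibble: `sample_id`,
#'   `cluster1..K` posterior mean ancestry), `P` (per-locus K x alleles
#'   posterior mean frequency matrices), `alpha`, `lnpd`, `loglik_mean`,
#'   `loglik_var`, `logliks`, `config`. [tidy()] returns long-form Q;
#'   [glance()] the one-row model summary.
#' @export
#' @examples
#' d <- sim_dataset(sim_config(k = 2, loci = 12, n_ref = 15, fst = 0.3,
#'                             seed = 7))
#' fit <- run_admixture(d$genotypes, k = 2, burn_in = 200, iterations = 200,
#'                      seed = 1)
#' glance(fit)
run_admixture <- function(geno, k, ..., config = NULL) {
  data <- if (inherits(geno, "admix_data")) geno else admix_data(geno)
  cfg <- config %||% admixture_config(k, ...)
  if (cfg$k > 2L * data$n * length(data$loci)) {
    abort("more clusters than gene copies")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- .cpp_admix_gibbs(data$ind, data$fa, data$locus_of_flat,
                          data$n, cfg$k, cfg$lambda, cfg$burn_in,
                          cfg$iterations, cfg$thin, cfg$infer_alpha,
                          cfg$separate_alpha, cfg$alpha_init,
                          cfg$alpha_proposal_sd, cfg$alpha_max)
  ll <- res$logliks
  lv <- if (length(ll) > 1) var(ll) else 0
  Q <- tibble::as_tibble(res$Q, .name_repair = ~paste0("cluster", seq_len(cfg$k)))
  Q <- dplyr::bind_cols(tibble::tibble(sample_id = data$samples), Q)
  sizes <- lengths(data$alleles)
  ends <- cumsum(sizes)
  P <- purrr::map(seq_along(data$loci), function(l) {
    cols <- seq.int(ends[l] - sizes[l] + 1L, ends[l])
    m <- res$P[, cols, drop = FALSE]
    dimnames(m) <- list(paste0("cluster", seq_len(cfg$k)),
                        data$alleles[[l]])
    m
  })
  names(P) <- data$loci
  structure(list(Q = Q, P = P, alpha = as.numeric(res$alpha),
                 lnpd = mean(ll) - lv / 2,
                 loglik_mean = mean(ll), loglik_var = lv, logliks = ll,
                 config = cfg, n_kept = res$n_kept),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture fit: K = %d, %d samples, %d loci\n",
              x$config$k, nrow(x$Q), length(x$P)))
  cat(sprintf("  lnP(D) = %.2f (mean loglik %.2f, var %.2f, %d kept)\n",
              x$lnpd, x$loglik_mean, x$loglik_var, x$n_kept))
  cat("  alpha =", paste(sprintf("%.3f", x$alpha), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  tidyr::pivot_longer(x$Q, -"sample_id", names_to = "cluster",
                      values_to = "proportion")
}

#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(k = x$config$k, lnpd = x$lnpd,
                 loglik_mean = x$loglik_mean, loglik_var = x$loglik_var,
                 alpha_mean = mean(x$alpha), n_samples = nrow(x$Q))
}

#' Label clusters by reference populations
#'
#' Names each cluster after the reference population group with the
#' largest mean membership in it (the labelling convention for anchoring
#' unsupervised runs to known panels). Ties break to the lexicographically
#' first group name and are flagged.
#'
#' @param fit an `admixture_fit` (or a membership tibble with `sample_id`
#'   and cluster columns).
#' @param meta metadata tibble with `sample_id`, `population_label`,
#'   `role`; reference rows anchor the labels.
#' @return A tibble: `cluster`, `ancestry` (winning group),
#'   `mean_membership`, `tied`.
#' @export
label_clusters_by_reference <- function(fit, meta) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else tibble::as_tibble(fit)
  refs <- meta[meta$role == "reference" & !is.na(meta$population_label), ]
  if (nrow(refs) == 0) abort("no reference samples to label clusters with")
  qr <- dplyr::inner_join(Q, refs[, c("sample_id", "population_label")],
                          by = "sample_id")
  if (nrow(qr) == 0) abort("reference samples absent from the fitted Q")
  long <- tidyr::pivot_longer(qr, dplyr::starts_with("cluster"),
                              names_to = "cluster", values_to = "q")
  means <- long |>
    dplyr::group_by(.data$cluster, .data$population_label) |>
    dplyr::summarise(mean_membership = mean(.data$q), .groups = "drop")
  means |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$mean_membership),
                   .data$population_label, .by_group = TRUE) |>
    dplyr::summarise(
      ancestry = .data$population_label[1],
      tied = sum(.data$mean_membership == max(.data$mean_membership)) > 1,
      mean_membership = .data$mean_membership[1],
      .groups = "drop") |>
    dplyr::select("cluster", "ancestry", "mean_membership", "tied")
}

#' Ancestry proportions labelled by reference groups
#'
#' Convenience wrapper: applies [label_clusters_by_reference()] to a fit
#' and returns each sample's proportions under ancestry-group names
#' (clusters mapping to the same group are summed).
#'
#' @inheritParams label_clusters_by_reference
#' @return A tibble: `sample_id`, `ancestry`, `proportion`.
#' @export
labelled_proportions <- function(fit, meta) {
  labs <- label_clusters_by_reference(fit, meta)
  tidy(fit) |>
    dplyr::left_join(labs[, c("cluster", "ancestry")], by = "cluster") |>
    dplyr::group_by(.data$sample_id, .data$ancestry) |>
    dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
}
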