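#' Sweep the number of clusters K over replicate runs
#'
#' Runs the admixture sampler for every K in a contiguous range, several
#' replicates each, collecting the `lnP(D)` model scores used by the
#' rate-of-change criterion in [delta_k()]. Replicate seeds are derived
#' deterministically from the master seed as
#' `seed + 10007 * K + 101 * replicate`, so a sweep is exactly
#' reproducible and each (K, replicate) chain is distinct.
#'
#' @param geno a genotype tibble.
#' @param k_range contiguous integer vector of K values (e.g. `1:6`).
#' @param replicates runs per K (>= 2 for a defined replicate sd).
#' @param seed master seed.
#' @param ... further arguments to [admixture_config()] (burn_in,
#'   iterations, lambda, ...).
#' @return An object of class `k_sweep`: `scores`, a tibble with `k`,
#'   `replicate`, `seed`, `lnpd`; and `runs`, the fitted
#'   [run_admixture()] objects named `"K<k>.<rep>"` (kept for alignment).
#' @export
run_k_sweep <- function(geno, k_range, replicates = 3, seed = 1, ...) {
  k_range <- sort(as.integer(k_range))
  if (!all(diff(k_range) == 1)) abort("k_range must be contiguous integers")
  if (replicates < 2) abort("at least 2 replicates per K are required")
  data <- admix_data(geno)
  grid <- tidyr::expand_grid(k = k_range, replicate = seq_len(replicates))
  grid$seed <- as.integer(seed + 10007L * grid$k + 101L * grid$replicate)
  runs <- purrr::pmap(grid, function(k, replicate, seed) {
    run_admixture(data, config = admixture_config(k, ..., seed = seed))
  })
  names(runs) <- sprintf("K%d.%d", grid$k, grid$replicate)
  grid$lnpd <- purrr::map_dbl(runs, "lnpd")
  structure(list(scores = grid, runs = runs, master_seed = seed),
            class = "k_sweep")
}

#' @export
print.k_sweep <- function(x, ...) {
  cat("K sweep:", min(x$scores$k), "..", max(x$scores$k), "with",
      max(x$scores$replicate), "replicates each\n")
  print(delta_k(x))
  invisible(x)
}

#' Evanno-style delta-K table and best K
#'
#' From replicate `lnP(D)` scores across a contiguous K range, computes for
#' every interior K the mean and replicate standard deviation of L(K), the
#' first difference `L'(K) = mean L(K) - mean L(K-1)`, the absolute second
#' difference `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd L(K)`. The selected K is the argmax of deltaK
#' over interior K; ties break toward the larger K (and are flagged), and a
#' sweep whose mean scores are exactly linear in K (all deltaK zero) is
#' flagged unresolved. deltaK is undefined at the sweep endpoints, and
#' flagged `NA` at any interior K whose replicate sd is zero.
#'
#' @param sweep a [run_k_sweep()] result, or a tibble with columns `k` and
#'   `lnpd` (one row per replicate).
#' @return An object of class `delta_k_table`: `table`, a tibble with `k`,
#'   `mean_lnpd`, `sd_lnpd`, `lprime`, `lsecond_abs`, `delta_k`; `best_k`
#'   (`NA` when unresolved); `unresolved`; `tie`.
#' @export
delta_k <- function(sweep) {
  scores <- if (inherits(sweep, "k_sweep")) sweep$scores else
    tibble::as_tibble(sweep)
  if (!all(c("k", "lnpd") %in% names(scores))) {
    abort("need columns `k` and `lnpd`")
  }
  ks <- sort(unique(scores$k))
  if (length(ks) < 3) abort("delta-K needs at least 3 consecutive K values")
  if (!all(diff(ks) == 1)) abort("K values must be contiguous")
  reps <- table(scores$k)
  if (length(unique(reps)) != 1 || any(reps < 2)) {
    abort("every K needs the same replicate count, >= 2")
  }
  tab <- scores |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_lnpd = mean(.data$lnpd),
                     sd_lnpd = sd(.data$lnpd), .groups = "drop") |>
    dplyr::arrange(.data$k)
  n <- nrow(tab)
  tab$lprime <- c(NA, diff(tab$mean_lnpd))
  tab$lsecond_abs <- c(NA, abs(diff(tab$lprime[-1])), NA)
  tab$delta_k <- tab$lsecond_abs / tab$sd_lnpd
  interior <- seq(2, n - 1)
  zero_sd <- interior[tab$sd_lnpd[interior] == 0]
  if (length(zero_sd) > 0) {
    warn(paste0("replicate sd is 0 at K = ",
                paste(tab$k[zero_sd], collapse = ", "),
                "; delta-K undefined there"))
    tab$delta_k[zero_sd] <- NA_real_
  }
  dk <- tab$delta_k[interior]
  unresolved <- all(is.na(dk)) || all(dk[!is.na(dk)] == 0)
  tie <- FALSE
  best_k <- NA_integer_
  if (!unresolved) {
    mx <- max(dk, na.rm = TRUE)
    at <- interior[!is.na(dk) & dk == mx]
    tie <- length(at) > 1
    best_k <- tab$k[max(at)]   # ties resolve toward the larger K
  }
  structure(list(table = tab, best_k = best_k, unresolved = unresolved,
                 tie = tie),
            class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(x$table)
  if (x$unresolved) cat("best K: unresolved (no curvature in lnP(D))\n")
  else cat("best K:", x$best_k, if (x$tie) "(tie, larger K taken)" else "", "\n")
  invisible(x)
}

#' @method tidy delta_k_table
#' @export
tidy.delta_k_table <- function(x, ...) x$table

#' @method glance delta_k_table
#' @export
glance.delta_k_table <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, unresolved = x$unresolved, tie = x$tie)
}
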