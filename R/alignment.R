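#' Similarity between two membership matrices
#'
#' `G = 1 - ||Qa - Qb||_F / sqrt(2 N)`: 1 when the matrices agree exactly,
#' 0 when the rows are disjoint one-hot assignments (the maximal Frobenius
#' disagreement on the simplex).
#'
#' @param qa,qb N x K membership matrices (rows sum to 1), or tibbles with
#'   a `sample_id` column and cluster columns.
#' @return A scalar in `[0, 1]`.
#' @export
similarity <- function(qa, qb) {
  qa <- membership_matrix(qa)
  qb <- membership_matrix(qb)
  if (!all(dim(qa) == dim(qb))) abort("membership matrices differ in shape")
  1 - sqrt(sum((qa - qb)^2)) / sqrt(2 * nrow(qa))
}

membership_matrix <- function(q) {
  if (inherits(q, "admixture_fit")) q <- q$Q
  if (is.data.frame(q)) {
    q <- as.matrix(q[, grep("^cluster", names(q), value = TRUE), drop = FALSE])
  }
  as.matrix(q)
}

#' Align replicate membership matrices to a reference run
#'
#' Cluster labels are arbitrary across replicate runs (label switching);
#' before averaging, each run's columns are permuted to best match the
#' first run. The optimal permutation maximizes the `G` [similarity()],
#' which is equivalent to a linear assignment problem on the cross-product
#' matrix `t(Qref) %*% Qrun`; it is solved exhaustively over the K!
#' permutations when K <= 8 and by the Hungarian algorithm otherwise (the
#' two agree wherever both apply).
#'
#' @param runs a list of membership matrices, membership tibbles, or
#'   `admixture_fit` objects sharing N and K; the first is the reference.
#' @param method `"auto"` (exhaustive for K <= 8), `"exhaustive"`, or
#'   `"assignment"`.
#' @return An object of class `run_alignment`: `permutations` (list; entry
#'   `p` means reference column `j` is matched by run column `p[j]`),
#'   `score_before`/`score_after` (similarity of each run to the
#'   reference), `average` (mean of the aligned matrices; rows sum to 1),
#'   and `aligned` (the permuted matrices).
#' @export
align_runs <- function(runs, method = c("auto", "exhaustive", "assignment")) {
  method <- match.arg(method)
  mats <- purrr::map(runs, membership_matrix)
  dims <- purrr::map(mats, dim)
  if (length(unique(dims)) != 1) abort("all runs must share N and K")
  ref <- mats[[1]]
  K <- ncol(ref)
  use_exhaustive <- switch(method, auto = K <= 8,
                           exhaustive = TRUE, assignment = FALSE)
  perms <- purrr::map(mats, function(m) {
    benefit <- crossprod(ref, m)          # K x K; maximize sum of matched entries
    if (use_exhaustive) best_permutation_exhaustive(benefit)
    else best_permutation_assignment(benefit)
  })
  aligned <- purrr::map2(mats, perms, function(m, p) m[, p, drop = FALSE])
  aligned <- purrr::map(aligned, function(m) {
    colnames(m) <- colnames(ref); m
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  structure(list(
    permutations = perms,
    score_before = purrr::map_dbl(mats, similarity, qa = ref),
    score_after = purrr::map_dbl(aligned, similarity, qa = ref),
    average = avg,
    aligned = aligned
  ), class = "run_alignment")
}

#' @export
print.run_alignment <- function(x, ...) {
  cat("Alignment of", length(x$aligned), "runs; similarity to reference:\n")
  cat("  before:", paste(sprintf("%.3f", x$score_before), collapse = " "), "\n")
  cat("  after: ", paste(sprintf("%.3f", x$score_after), collapse = " "), "\n")
  invisible(x)
}

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (i in seq_len(n)) {
    for (s in sub) {
      rest <- seq_len(n)[-i]
      out[[idx]] <- c(i, rest[s])
      idx <- idx + 1L
    }
  }
  out
}

best_permutation_exhaustive <- function(benefit) {
  K <- nrow(benefit)
  best <- NULL; best_val <- -Inf
  for (p in permutations_of(K)) {
    val <- sum(benefit[cbind(seq_len(K), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  as.integer(best)
}

best_permutation_assignment <- function(benefit) {
  cost <- max(benefit) - benefit
  hungarian_assignment(cost)
}

# Hungarian algorithm (potentials + augmenting paths), square cost matrix;
# returns p with p[row] = assigned column, minimizing total cost
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # index j+1 <-> column j, col 0 virtual
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}
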