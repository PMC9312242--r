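#' Fit a lightweight admixture model by Gibbs sampling
#'
#' A deliberately simplified variant of the Pritchard admixture model
#' ("structure-lite"): each allele copy carries a latent cluster label; the
#' sampler alternates (i) cluster assignments given membership proportions Q
#' and cluster allele frequencies P, (ii) P given assignments (Dirichlet
#' posterior, uniform prior), and (iii) Q given assignments (Dirichlet with a
#' fixed admixture parameter `alpha`; the correlated-allele-frequencies and
#' linkage extensions are intentionally omitted). `alpha` defaults to 0.1,
#' the magnitude full admixture samplers typically infer for non-admixed
#' wild populations; a flat `alpha = 1` noticeably shrinks the membership of
#' clearly assigned individuals toward uniform at these sample sizes. Q and
#' P are reported as
#' posterior means over the sampled iterations; `mean_lnP` is the average
#' observed-data log-likelihood under the sampled (Q, P). Missing allele
#' copies are marginalized (skipped). Deterministic under a fixed seed.
#'
#' The desk-scale defaults (2,000 burn-in / 10,000 sampling sweeps) are short
#' chains suited to tens of loci and a few hundred individuals; longer chains
#' can be requested for production runs.
#'
#' @param g A [genotype_matrix()].
#' @param K Number of clusters (1 <= K <= number of individuals).
#' @param burnin,n_iter Burn-in and sampling sweeps (both >= 1).
#' @param seed Optional integer seed.
#' @param alpha Fixed Dirichlet admixture parameter (default 0.1).
#' @param lambda Dirichlet prior mass per allele for P (default 1.0).
#' @return An `admixture_fit`: list with `K`, `Q` (individuals x K, rows sum
#'   to 1), `P` (per-locus list of K x alleles frequency matrices), `mean_lnP`,
#'   `lnp_trace`, and run metadata.
#' @export
fit_admixture <- function(g, K, burnin = 2000L, n_iter = 10000L, seed = NULL,
                          alpha = 0.1, lambda = 1.0) {
  if (K < 1L) stop("K must be >= 1")
  if (K > n_individuals(g)) stop("K exceeds the number of individuals")
  if (burnin < 1L || n_iter < 1L) stop("burnin and n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(g)
  allele_sets <- lapply(seq_len(L), function(l)
    sort(unique(c(g$a1[, l], g$a2[, l]))))
  n_alleles <- vapply(allele_sets, length, integer(1))
  if (any(n_alleles == 0L)) stop("locus with no observed alleles")
  X <- matrix(0L, n_individuals(g), 2L * L)
  for (l in seq_len(L)) {
    X[, 2L * l - 1L] <- match(g$a1[, l], allele_sets[[l]], nomatch = 0L)
    X[, 2L * l] <- match(g$a2[, l], allele_sets[[l]], nomatch = 0L)
  }
  res <- gibbs_admixture(X, n_alleles, as.integer(K), as.integer(burnin),
                         as.integer(n_iter), alpha, lambda)
  Q <- res$Q
  dimnames(Q) <- list(g$ind, paste0("cluster", seq_len(K)))
  off <- cumsum(c(0L, n_alleles))
  P <- lapply(seq_len(L), function(l) {
    m <- res$P[, (off[l] + 1L):off[l + 1L], drop = FALSE]
    dimnames(m) <- list(paste0("cluster", seq_len(K)), allele_sets[[l]])
    m
  })
  names(P) <- g$loci
  structure(list(K = as.integer(K), Q = Q, P = P,
                 mean_lnP = mean(res$lnp_trace), lnp_trace = res$lnp_trace,
                 burnin = as.integer(burnin), n_iter = as.integer(n_iter),
                 seed = seed, alpha = alpha, lambda = lambda,
                 population = as.character(g$pop)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, ",", nrow(x$Q), "individuals,",
      length(x$P), "loci\n")
  cat(sprintf("mean lnP = %.2f over %d sampled sweeps (burn-in %d)\n",
              x$mean_lnP, x$n_iter, x$burnin))
  invisible(x)
}

#' Align inferred clusters to reference labels
#'
#' Cluster labels of a mixture fit are only identified up to permutation.
#' Enumerates all permutations of the K columns of Q and picks the one
#' maximizing the mean membership of each individual in the cluster matching
#' its reference label.
#'
#' @param Q Individuals x K membership matrix.
#' @param truth Factor/character of reference labels (nlevels <= K).
#' @return List with `perm` (column order applied to Q), `Q` (aligned
#'   matrix), and `self_membership` (mean aligned membership in the own
#'   cluster).
#' @export
match_clusters <- function(Q, truth) {
  truth <- factor(truth)
  K <- ncol(Q)
  if (nlevels(truth) > K) stop("more reference labels than clusters")
  perms <- .permutations(K)
  ti <- as.integer(truth)
  best <- NULL; best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    Qp <- Q[, perms[r, ], drop = FALSE]
    val <- mean(Qp[cbind(seq_len(nrow(Q)), ti)])
    if (val > best_val) { best_val <- val; best <- perms[r, ] }
  }
  list(perm = best, Q = Q[, best, drop = FALSE], self_membership = best_val)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Evanno delta-K table for selecting the number of clusters
#'
#' From the mean log-likelihoods of replicate runs at consecutive K values:
#' `L'(K) = L(K) - L(K-1)`, `L''(K) = L(K+1) - 2 L(K) + L(K-1)`, and
#' `deltaK = |L''(K)| / SD(K)` where the mean and SD are taken over runs at
#' each K. The supported cluster number `best_K` is the interior K (with
#' positive SD) maximizing deltaK.
#'
#' @param runs Data frame with columns `K` and `lnP`, one row per run; at
#'   least 3 consecutive K values with >= 2 runs each.
#' @return An `evanno_table` data frame with columns `K`, `n_runs`,
#'   `mean_lnP`, `sd_lnP`, `l_prime`, `l_second`, `delta_k`, and attribute
#'   `best_K`.
#' @examples
#' runs <- expand.grid(K = 1:4, run = 1:3)
#' runs$lnP <- c(-1000, -800, -790, -788)[runs$K] + rnorm(nrow(runs), 0, 1)
#' evanno_delta_k(runs)
#' @export
evanno_delta_k <- function(runs) {
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L || any(diff(ks) != 1L))
    stop("need at least 3 consecutive K values")
  nr <- tapply(runs$lnP, runs$K, length)
  if (any(nr < 2L)) stop("need at least 2 runs per K")
  m <- tapply(runs$lnP, runs$K, mean)[as.character(ks)]
  s <- tapply(runs$lnP, runs$K, stats::sd)[as.character(ks)]
  nk <- length(ks)
  l_prime <- c(NA, diff(m))
  l_second <- c(NA, m[-(1:2)] - 2 * m[2:(nk - 1)] + m[1:(nk - 2)], NA)
  delta_k <- abs(l_second) / s
  delta_k[s == 0] <- NA_real_   # flagged: undefined at zero SD
  out <- data.frame(K = ks, n_runs = as.integer(nr[as.character(ks)]),
                    mean_lnP = as.vector(m), sd_lnP = as.vector(s),
                    l_prime = as.vector(l_prime),
                    l_second = as.vector(l_second),
                    delta_k = as.vector(delta_k))
  interior <- which(!is.na(out$delta_k))
  attr(out, "best_K") <- if (length(interior))
    out$K[interior[which.max(out$delta_k[interior])]] else NA_integer_
  class(out) <- c("evanno_table", "data.frame")
  out
}

#' Run the admixture model over a range of K with replicate runs
#'
#' Convenience scan mirroring common practice: several independent chains per
#' K, summarized with [evanno_delta_k()].
#'
#' @param g A [genotype_matrix()].
#' @param k_range Integer vector of K values (e.g. `1:7`).
#' @param n_runs Independent runs per K (>= 2 for delta-K).
#' @param ... Passed to [fit_admixture()] (`burnin`, `n_iter`, `alpha`, ...).
#' @param seed Optional integer seed; per-run seeds are drawn from it.
#' @return List with `runs` (data frame K/run/lnP), `evanno`
#'   ([evanno_delta_k()] table), `best_K`, and `fits` (the fit with the
#'   highest lnP at each K).
#' @export
run_k_scan <- function(g, k_range = 1:5, n_runs = 3L, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(K = k_range, run = seq_len(n_runs))
  grid <- grid[order(grid$K, grid$run), ]
  fits_best <- list()
  lnp <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    fit <- fit_admixture(g, K = grid$K[r], ...)
    lnp[r] <- fit$mean_lnP
    key <- as.character(grid$K[r])
    if (is.null(fits_best[[key]]) || fit$mean_lnP > fits_best[[key]]$mean_lnP)
      fits_best[[key]] <- fit
  }
  runs <- data.frame(K = grid$K, run = grid$run, lnP = lnp)
  ev <- evanno_delta_k(runs)
  list(runs = runs, evanno = ev, best_K = attr(ev, "best_K"),
       fits = fits_best)
}

#' Write a Q matrix as TSV suitable for stacked-bar plotting
#'
#' @param fit An `admixture_fit`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(fit, path) {
  out <- data.frame(individual = rownames(fit$Q),
                    population = fit$population,
                    fit$Q, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
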