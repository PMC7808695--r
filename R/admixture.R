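## Unsupervised admixture estimation: binomial-likelihood EM (FRAPPE-style
## block relaxation) over individual ancestry fractions Q and component
## allele frequencies F, plus replicate mode alignment.

#' Unsupervised admixture by binomial-likelihood EM
#'
#' Model: individual i's alt-allele count at site j is Binomial(c_ij, p_ij)
#' with `p_ij = sum_k Q_ik F_kj`, where `c_ij` is 2 for diploid entries and
#' 1 for pseudohaploid entries; missing entries contribute nothing
#' (missing-at-random). Maximised by EM updates, which provably never
#' decrease the log-likelihood:
#' `Q_ik <- sum_j (g a_ijk + (c-g) b_ijk) / sum_j c_ij` and
#' `F_kj <- sum_i g a_ijk / sum_i (g a_ijk + (c-g) b_ijk)`, with
#' responsibilities `a_ijk = Q_ik F_kj / p_ij`,
#' `b_ijk = Q_ik (1-F_kj) / (1-p_ij)`. F is clipped to
#' `[1e-6, 1 - 1e-6]` each iteration to avoid log(0). Convergence: relative
#' log-likelihood change below `tol`.
#'
#' @param G individuals x sites matrix of alt-allele counts: 0/1/2 for
#'   diploid rows, 0/1 for pseudohaploid rows, NA missing.
#' @param K number of ancestry components (>= 1).
#' @param seed integer seed for the random initialisation.
#' @param ploidy per-individual ploidy vector (2 = diploid, 1 =
#'   pseudohaploid); default all diploid.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 2000); non-convergence warns and
#'   sets `converged = FALSE`.
#' @return An object of class `admixture_fit`: `K`, `Q` (rows sum to 1),
#'   `F` (K x sites), `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `seed`.
#' @export
admixture_fit <- function(G, K, seed = 1L, ploidy = NULL, tol = 1e-6,
                          max_iter = 2000L) {
  if (K < 1L) stop("admixture_fit: K must be >= 1")
  G <- as.matrix(G)
  N <- nrow(G); M <- ncol(G)
  ploidy <- ploidy %||% rep(2L, N)
  if (length(ploidy) != N || any(!ploidy %in% 1:2)) {
    stop("admixture_fit: ploidy must be 1 or 2 per individual")
  }
  if (any(rowSums(!is.na(G)) == 0L)) {
    stop("admixture_fit: individual(s) with no genotypes")
  }
  C <- matrix(ploidy, nrow = N, ncol = M)
  miss <- is.na(G)
  if (any(G[!miss] < 0 | G[!miss] > C[!miss])) {
    stop("admixture_fit: counts exceed ploidy")
  }
  C[miss] <- 0
  G[miss] <- 0
  storage.mode(G) <- "double"
  res <- with_seed(seed, {
    Q <- matrix(rexp(N * K), N, K)
    Q <- Q / rowSums(Q)
    F_ <- matrix(runif(K * M, 0.05, 0.95), K, M)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      P <- Q %*% F_
      P <- clamp(P, 1e-9, 1 - 1e-9)
      ll <- sum(G * log(P) + (C - G) * log1p(-P))
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_old <- ll
      R1 <- G / P
      R0 <- (C - G) / (1 - P)
      S1 <- R1 %*% t(F_)              # N x K
      S0 <- R0 %*% t(1 - F_)
      Qnum <- Q * (S1 + S0)
      Qnew <- Qnum / rowSums(C)
      Qnew <- Qnew / rowSums(Qnew)
      Fnum <- F_ * crossprod(Q, R1)   # K x M
      Fden <- Fnum + (1 - F_) * crossprod(Q, R0)
      Fnew <- clamp(Fnum / pmax(Fden, 1e-12), 1e-6, 1 - 1e-6)
      Q <- Qnew
      F_ <- Fnew
    }
    list(Q = Q, F = F_, ll = ll_trace, converged = converged, iter = iter)
  })
  if (!res$converged) {
    warning("admixture_fit: not converged after ", max_iter, " iterations")
  }
  rownames(res$Q) <- rownames(G)
  structure(list(K = as.integer(K), Q = res$Q, F = res$F,
                 loglik = res$ll[length(res$ll)], loglik_trace = res$ll,
                 n_iter = res$iter, converged = res$converged,
                 seed = as.integer(seed)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, %d individuals, loglik %.2f (%s, %d iters)\n",
              x$K, nrow(x$Q), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

## Greedy matching of columns of Q against a reference by correlation.
match_components <- function(Q_ref, Q) {
  K <- ncol(Q_ref)
  sim <- suppressWarnings(stats::cor(Q_ref, Q))
  sim[!is.finite(sim)] <- -1
  perm <- integer(K)
  used_r <- used_c <- rep(FALSE, K)
  for (step in seq_len(K)) {
    sim_masked <- sim
    sim_masked[used_r, ] <- -Inf
    sim_masked[, used_c] <- -Inf
    ij <- arrayInd(which.max(sim_masked), dim(sim))
    perm[ij[1]] <- ij[2]
    used_r[ij[1]] <- TRUE
    used_c[ij[2]] <- TRUE
  }
  perm
}

#' Align admixture replicates and select the major mode
#'
#' Replicate runs of [admixture_fit()] at one K are aligned to the first
#' replicate by greedy matching of Q columns on correlation. Replicates
#' whose aligned Q matrices differ by RMSE < 0.05 form a mode (single-link
#' clustering); the major mode is the largest cluster, ties broken by
#' highest mean log-likelihood, and its representative is the
#' highest-likelihood member.
#'
#' @param fits list of `admixture_fit` objects with identical K and
#'   individuals.
#' @param rmse_threshold mode radius on aligned Q (default 0.05).
#' @return list: `representative` (an `admixture_fit` with aligned
#'   components), `permutations` (list, one per replicate), `mode` (integer
#'   cluster id per replicate), `major_mode` (id), `mode_size`.
#' @export
align_modes <- function(fits, rmse_threshold = 0.05) {
  if (!length(fits)) stop("align_modes: no fits")
  K <- unique(vapply(fits, function(f) f$K, integer(1)))
  if (length(K) != 1L) stop("align_modes: fits differ in K")
  n <- length(fits)
  perms <- lapply(fits, function(f) match_components(fits[[1]]$Q, f$Q))
  aligned <- lapply(seq_len(n), function(i) {
    f <- fits[[i]]
    f$Q <- f$Q[, perms[[i]], drop = FALSE]
    f$F <- f$F[perms[[i]], , drop = FALSE]
    f
  })
  if (n == 1L) {
    return(list(representative = aligned[[1]], permutations = perms,
                mode = 1L, major_mode = 1L, mode_size = 1L))
  }
  rmse <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      rmse[i, j] <- rmse[j, i] <-
        sqrt(mean((aligned[[i]]$Q - aligned[[j]]$Q)^2))
    }
  }
  cl <- cutree(hclust(stats::as.dist(rmse), method = "single"),
               h = rmse_threshold)
  sizes <- table(cl)
  cand <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(cand) > 1L) {
    mean_ll <- vapply(cand, function(k) {
      mean(vapply(fits[cl == k], function(f) f$loglik, numeric(1)))
    }, numeric(1))
    cand <- cand[which.max(mean_ll)]
  }
  major <- cand[1]
  members <- which(cl == major)
  rep_idx <- members[which.max(vapply(aligned[members],
                                      function(f) f$loglik, numeric(1)))]
  list(representative = aligned[[rep_idx]], permutations = perms,
       mode = as.integer(cl), major_mode = major,
       mode_size = as.integer(max(sizes)))
}
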