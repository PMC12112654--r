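# Independent oracles. Each re-derives a quantity from first principles by a
# different route than the package implementation.

# Monte-Carlo kinship: phi_ij = P(one random allele from i is IBD to one
# random allele from j), estimated by repeated independent single-locus
# allele drops down the pedigree (no recursion, no shared code with
# kinship_matrix). Vectorized over drops.
oracle_kinship_mc <- function(ped, ndrops = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(ped)
  fidx <- match(ifelse(is.na(ped$father), NA,
                       paste(ped$fid, ped$father, sep = ":")), ped$key)
  midx <- match(ifelse(is.na(ped$mother), NA,
                       paste(ped$fid, ped$mother, sep = ":")), ped$key)
  pat <- matrix(0L, n, ndrops); mat <- matrix(0L, n, ndrops)
  lab <- 0L
  for (k in seq_len(n)) {          # rows are topologically ordered
    if (is.na(fidx[k])) {
      pat[k, ] <- lab + 1L; mat[k, ] <- lab + 2L; lab <- lab + 2L
    } else {
      pick <- stats::runif(ndrops) < 0.5
      pat[k, ] <- ifelse(pick, pat[fidx[k], ], mat[fidx[k], ])
      pick <- stats::runif(ndrops) < 0.5
      mat[k, ] <- ifelse(pick, pat[midx[k], ], mat[midx[k], ])
    }
  }
  phi_hat <- matrix(0, n, n, dimnames = list(ped$key, ped$key))
  se_hat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      # pick one random allele from each and compare
      ai <- ifelse(stats::runif(ndrops) < 0.5, pat[i, ], mat[i, ])
      aj <- ifelse(stats::runif(ndrops) < 0.5, pat[j, ], mat[j, ])
      hit <- ai == aj
      phi_hat[i, j] <- phi_hat[j, i] <- mean(hit)
      se_hat[i, j] <- se_hat[j, i] <- stats::sd(hit) / sqrt(ndrops)
    }
  }
  list(phi = phi_hat, se = se_hat)
}

# Brute-force pairwise IBD proportion from descent labels: explicit loops
# over individuals and the four allele comparisons.
oracle_ibd_bruteforce <- function(rec, locus_index) {
  n <- length(rec$ids)
  pihat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      al_i <- c(rec$pat[i, locus_index], rec$mat[i, locus_index])
      al_j <- c(rec$pat[j, locus_index], rec$mat[j, locus_index])
      m <- 0
      for (a in al_i) for (b in al_j) if (a == b) m <- m + 1
      pihat[i, j] <- m / 2
    }
  }
  pihat
}

# Exhaustive grid-search ML for the univariate polygenic model: direct dense
# MVN log-likelihood (solve/determinant, no Cholesky profiling shortcuts)
# over a (sigma2_g, sigma2_e) grid, with beta by explicit GLS.
oracle_grid_polygenic <- function(y, X, A, g_grid, e_grid) {
  best <- list(ll = -Inf)
  n <- length(y)
  for (g in g_grid) {
    for (e in e_grid) {
      O <- g * A + e * diag(n)
      Oi <- tryCatch(solve(O), error = function(err) NULL)
      if (is.null(Oi)) next
      beta <- solve(t(X) %*% Oi %*% X, t(X) %*% Oi %*% y)
      r <- y - X %*% beta
      ll <- -0.5 * (n * log(2 * pi) + determinant(O)$modulus[1] +
                    t(r) %*% Oi %*% r)[1]
      if (ll > best$ll) best <- list(ll = ll, g = g, e = e)
    }
  }
  best
}
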