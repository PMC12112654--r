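# Family-blocked multivariate-normal likelihood engine for
# variance-component models: Omega = 2*Phi*s2g + Pi*s2q + I*s2e per family
# (univariate) or the Kronecker extension over trait pairs (bivariate).
# Fixed effects are profiled out by generalized least squares at every
# evaluation, so the optimizer works on the variance parameters only.
#
# Two evaluation paths:
#  * no QTL kernel: 2*Phi and I commute, so one eigendecomposition of the
#    (block-diagonal) kinship matrix reduces every likelihood evaluation to
#    O(n) diagonal (univariate) or 2x2-block (bivariate) algebra;
#  * with a locus IBD kernel Pi the three kernels are not simultaneously
#    diagonalizable and each family block is Cholesky-factorized per
#    evaluation (families are small, so this stays cheap).

# Build the likelihood data. y: n x t matrix with rownames = pedigree keys;
# X: n x p design with the same rownames; kin/ibd are full-pedigree objects
# subset here. Rows must be complete cases already.
.vc_build <- function(y, X, kin, ibd = NULL) {
  keys <- rownames(y)
  if (is.null(keys)) stop("trait rows must be named by pedigree keys")
  if (!all(keys %in% kin$key)) stop("trait ids not all present in kinship")
  kin <- subset_kinship(kin, keys)
  P_full <- NULL
  if (!is.null(ibd)) {
    idx <- match(keys, ibd$key)
    if (anyNA(idx)) stop("trait ids not all present in IBD matrix")
    P_full <- ibd$pi[idx, idx, drop = FALSE]
  }
  t <- ncol(y)
  scale_y <- apply(y, 2, stats::sd, na.rm = TRUE)
  ys <- sweep(y, 2, scale_y, "/")
  dat <- list(n = nrow(y), t = t, p = ncol(X), scale_y = scale_y,
              keys = keys, colnames_X = colnames(X),
              trait_names = colnames(y), has_q = !is.null(P_full))
  if (is.null(P_full)) {
    # eigen fast path: family-wise eigendecomposition of 2*Phi, concatenated
    d <- numeric(0); U <- vector("list", 0)
    Vt <- matrix(0, 0, ncol(X)); ut <- matrix(0, 0, t)
    for (fam in unique(kin$fid)) {
      rows <- which(kin$fid == fam)
      A <- 2 * kin$phi[rows, rows, drop = FALSE]
      ed <- eigen(A, symmetric = TRUE)
      d <- c(d, ed$values)
      Vt <- rbind(Vt, crossprod(ed$vectors, X[rows, , drop = FALSE]))
      ut <- rbind(ut, crossprod(ed$vectors, ys[rows, , drop = FALSE]))
    }
    dat$eig <- list(d = pmax(d, 0), V = Vt, u = ut)
  } else {
    fams <- list()
    for (fam in unique(kin$fid)) {
      rows <- which(kin$fid == fam)
      nf <- length(rows)
      A <- 2 * kin$phi[rows, rows, drop = FALSE]
      P <- P_full[rows, rows, drop = FALSE]
      yf <- as.vector(ys[rows, , drop = FALSE])
      Xf <- X[rows, , drop = FALSE]
      if (t == 2) {
        Z <- matrix(0, 2 * nf, 2 * ncol(X))
        Z[seq_len(nf), seq_len(ncol(X))] <- Xf
        Z[nf + seq_len(nf), ncol(X) + seq_len(ncol(X))] <- Xf
        Xf <- Z
      }
      fams[[length(fams) + 1L]] <- list(y = yf, X = Xf, A = A, P = P, nf = nf)
    }
    dat$fams <- fams
  }
  dat
}

.cov2 <- function(v1, v2, r) {
  s <- sqrt(v1 * v2)
  matrix(c(v1, r * s, r * s, v2), 2, 2)
}

# profiled log-likelihood at variance parameters th (named numeric)
.vc_loglik <- function(th, dat) {
  if (!dat$has_q) return(.vc_loglik_eig(th, dat))
  p <- ncol(dat$fams[[1]]$X)
  XtWX <- matrix(0, p, p); XtWy <- numeric(p)
  ytWy <- 0; logdet <- 0; n <- 0
  for (fb in dat$fams) {
    O <- if (dat$t == 1) {
      th[["g"]] * fb$A + th[["q"]] * fb$P + diag(th[["e"]], fb$nf)
    } else {
      Sg <- .cov2(th[["g1"]], th[["g2"]], th[["rg"]])
      Sq <- .cov2(th[["q1"]], th[["q2"]], th[["rq"]])
      Se <- .cov2(th[["e1"]], th[["e2"]], th[["re"]])
      I <- diag(fb$nf)
      B11 <- Sg[1, 1] * fb$A + Sq[1, 1] * fb$P + Se[1, 1] * I
      B12 <- Sg[1, 2] * fb$A + Sq[1, 2] * fb$P + Se[1, 2] * I
      B22 <- Sg[2, 2] * fb$A + Sq[2, 2] * fb$P + Se[2, 2] * I
      rbind(cbind(B11, B12), cbind(B12, B22))
    }
    ch <- tryCatch(chol(O), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Ky <- backsolve(ch, fb$y, transpose = TRUE)
    KX <- backsolve(ch, fb$X, transpose = TRUE)
    XtWX <- XtWX + crossprod(KX)
    XtWy <- XtWy + crossprod(KX, Ky)[, 1]
    ytWy <- ytWy + sum(Ky^2)
    n <- n + length(fb$y)
  }
  .vc_gls(XtWX, XtWy, ytWy, logdet, n)
}

# eigen path: Omega has eigenbasis independent of the variance parameters
.vc_loglik_eig <- function(th, dat) {
  d <- dat$eig$d; V <- dat$eig$V; u <- dat$eig$u
  if (dat$t == 1) {
    w <- th[["g"]] * d + th[["e"]]
    if (any(w <= 0)) return(list(ll = -Inf))
    iw <- 1 / w
    XtWX <- crossprod(V, V * iw)
    XtWy <- crossprod(V, u[, 1] * iw)[, 1]
    ytWy <- sum(u[, 1]^2 * iw)
    logdet <- sum(log(w))
    return(.vc_gls(XtWX, XtWy, ytWy, logdet, dat$n))
  }
  Sg <- .cov2(th[["g1"]], th[["g2"]], th[["rg"]])
  Se <- .cov2(th[["e1"]], th[["e2"]], th[["re"]])
  a <- Sg[1, 1] * d + Se[1, 1]
  b <- Sg[1, 2] * d + Se[1, 2]
  cc <- Sg[2, 2] * d + Se[2, 2]
  det_k <- a * cc - b^2
  if (any(det_k <= 0) || any(a <= 0)) return(list(ll = -Inf))
  wa <- a / det_k; wb <- b / det_k; wc <- cc / det_k
  p <- ncol(V)
  XtWX <- matrix(0, 2 * p, 2 * p)
  i1 <- seq_len(p); i2 <- p + i1
  XtWX[i1, i1] <- crossprod(V, V * wc)
  XtWX[i1, i2] <- XtWX[i2, i1] <- -crossprod(V, V * wb)
  XtWX[i2, i2] <- crossprod(V, V * wa)
  u1 <- u[, 1]; u2 <- u[, 2]
  XtWy <- c(crossprod(V, wc * u1 - wb * u2)[, 1],
            crossprod(V, -wb * u1 + wa * u2)[, 1])
  ytWy <- sum(wc * u1^2 - 2 * wb * u1 * u2 + wa * u2^2)
  .vc_gls(XtWX, XtWy, ytWy, sum(log(det_k)), 2 * dat$n)
}

.vc_gls <- function(XtWX, XtWy, ytWy, logdet, n) {
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  quad <- ytWy - sum(beta * XtWy)
  list(ll = -0.5 * (n * log(2 * pi) + logdet + quad),
       beta = beta, XtWX = XtWX, n = n)
}

# parameter metadata for each model shape
.vc_par_spec <- function(t, has_q) {
  if (t == 1) {
    nm <- c("g", if (has_q) "q", "e")
    lower <- c(0, if (has_q) 0, 1e-9)
    upper <- rep(20, length(nm))
    start <- function(hg) c(hg, if (has_q) 0.05, 1 - hg)
  } else {
    nm <- c("g1", "g2", "rg", "e1", "e2", "re",
            if (has_q) c("q1", "q2", "rq"))
    lower <- c(0, 0, -0.999, 1e-9, 1e-9, -0.999,
               if (has_q) c(0, 0, -0.999))
    upper <- c(20, 20, 0.999, 20, 20, 0.999,
               if (has_q) c(20, 20, 0.999))
    start <- function(hg) c(hg, hg, 0.3, 1 - hg, 1 - hg, 0.1,
                            if (has_q) c(0.05, 0.05, 0.3))
  }
  list(names = nm, lower = lower, upper = upper, start = start)
}

# Maximize the profiled likelihood. `fixed` pins named parameters (e.g.
# q = 0 for a linkage null, rg = 0 for the genetic-correlation null).
# Deterministic multi-start (heritability fractions 0.45/0.15/0.75); an
# optional warm `start` (named, on the unit-variance scale) is tried first.
.vc_fit <- function(dat, fixed = list(), start = NULL, hessian = TRUE,
                    nstarts = 3) {
  spec <- .vc_par_spec(dat$t, dat$has_q)
  fixed <- unlist(fixed)
  free <- setdiff(spec$names, names(fixed))
  if (!length(free)) {
    th <- structure(numeric(length(spec$names)), names = spec$names)
    th[names(fixed)] <- fixed
    res <- .vc_loglik(th, dat)
    return(.vc_pack(th, res, dat, fixed, vcov = NULL))
  }
  fn <- function(par_free) {
    th <- structure(numeric(length(spec$names)), names = spec$names)
    th[free] <- par_free
    if (length(fixed)) th[names(fixed)] <- fixed
    ll <- .vc_loglik(th, dat)$ll
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  idx_free <- match(free, spec$names)
  starts <- lapply(c(0.45, 0.15, 0.75)[seq_len(nstarts)],
                   function(hg) spec$start(hg)[idx_free])
  if (!is.null(start)) {
    s0 <- spec$start(0.45)
    names(s0) <- spec$names
    s0[intersect(names(start), spec$names)] <-
      start[intersect(names(start), spec$names)]
    starts <- c(list(pmin(pmax(s0[free], spec$lower[idx_free]),
                          spec$upper[idx_free])),
                starts[seq_len(nstarts - 1)])
  }
  best <- NULL
  for (p0 in starts) {
    opt <- tryCatch(
      stats::optim(p0, fn, method = "L-BFGS-B",
                   lower = spec$lower[idx_free], upper = spec$upper[idx_free],
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("variance-component fit failed to converge ",
                          "after multi-start optimization")
  th <- structure(numeric(length(spec$names)), names = spec$names)
  th[free] <- best$par
  if (length(fixed)) th[names(fixed)] <- fixed
  res <- .vc_loglik(th, dat)

  vcov <- NULL
  if (hessian) {
    # observed information on the free parameters by central differences
    vcov <- .vc_vcov(fn, best$par, spec$lower[idx_free], spec$upper[idx_free])
    if (!is.null(vcov)) dimnames(vcov) <- list(free, free)
  }
  .vc_pack(th, res, dat, fixed, vcov = vcov)
}

.vc_vcov <- function(fn, par, lower, upper, rel_step = 5e-3) {
  k <- length(par)
  h <- pmax(abs(par), 0.05) * rel_step
  at_bound <- par <= lower + 1e-7 | par >= upper - 1e-7
  H <- matrix(NA_real_, k, k)
  f0 <- fn(par)
  for (i in seq_len(k)) {
    for (j in i:k) {
      pij <- function(si, sj) {
        pp <- par; pp[i] <- pp[i] + si * h[i]; pp[j] <- pp[j] + sj * h[j]
        fn(pp)
      }
      H[i, j] <- H[j, i] <- if (i == j) {
        (pij(1, 0) - 2 * f0 + pij(-1, 0)) / h[i]^2
      } else {
        (pij(1, 1) - pij(1, -1) - pij(-1, 1) + pij(-1, -1)) / (4 * h[i] * h[j])
      }
    }
  }
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V)) {
    if (any(!is.finite(V)) || any(diag(V) < 0)) V <- NULL
  }
  if (!is.null(V)) attr(V, "boundary") <- at_bound
  V
}

# assemble a fit object on the original trait scale
.vc_pack <- function(th, res, dat, fixed, vcov) {
  s2 <- dat$scale_y^2
  th_out <- th
  if (dat$t == 1) {
    th_out[c("g", "e")] <- th[c("g", "e")] * s2
    if ("q" %in% names(th)) th_out["q"] <- th["q"] * s2
  } else {
    th_out[c("g1", "e1")] <- th[c("g1", "e1")] * s2[1]
    th_out[c("g2", "e2")] <- th[c("g2", "e2")] * s2[2]
    if ("q1" %in% names(th)) {
      th_out["q1"] <- th["q1"] * s2[1]; th_out["q2"] <- th["q2"] * s2[2]
    }
  }
  beta <- res$beta
  if (dat$t == 1) {
    beta <- beta * dat$scale_y
    names(beta) <- dat$colnames_X
  } else {
    beta <- beta * rep(dat$scale_y, each = dat$p)
    names(beta) <- paste(rep(dat$trait_names, each = dat$p),
                         rep(dat$colnames_X, 2), sep = ".")
  }
  # Jacobian of the per-trait scaling back to the original data scale
  ll <- res$ll - dat$n * sum(log(dat$scale_y))
  list(par = th_out, par_scaled = th, loglik = ll, beta = beta,
       n_used = dat$n, t = dat$t, fixed = fixed, vcov = vcov,
       trait_names = dat$trait_names)
}
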