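#' Named trait vector keyed by pedigree membership
#'
#' Extracts one trait column from a trait table (as produced by
#' [simulate_phenotypes()] or [read_traits()]) as a numeric vector named by
#' family-qualified pedigree keys, ready for [fit_polygenic()] and friends.
#'
#' @param traits data frame with `fid`, `id` and trait columns.
#' @param name trait column name.
#' @export
trait_vector <- function(traits, name) {
  stopifnot(all(c("fid", "id") %in% names(traits)), name %in% names(traits))
  stats::setNames(traits[[name]], paste(traits$fid, traits$id, sep = ":"))
}

#' Covariate design keyed by pedigree membership
#'
#' Builds the intercept/age/sex/age-by-sex design from a trait table,
#' rownames = family-qualified keys.
#'
#' @param traits data frame with `fid`, `id`, `age`, `sex`.
#' @export
design_from_traits <- function(traits) {
  covariate_design(paste(traits$fid, traits$id, sep = ":"),
                   traits$age, traits$sex)
}

#' Fit the univariate polygenic model by maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood
#' `l = -1/2 [n log 2pi + log|Omega| + r' Omega^-1 r]` with
#' `Omega = 2 Phi sigma2_g + I sigma2_e` and fixed effects profiled out by
#' generalized least squares. The likelihood factorizes over families, so
#' the fit works on family blocks. Individuals with a missing trait or
#' covariate are dropped from the likelihood; their relatives' kinship
#' entries are unaffected because Phi comes from the full pedigree.
#'
#' Heritability is `h2 = sigma2_g / (sigma2_g + sigma2_q + sigma2_e)`; its
#' standard error comes from the observed information (central differences)
#' via the delta method. A fit on the `sigma2_g = 0` boundary is flagged and
#' reported with `h2 = 0`.
#'
#' @param trait named numeric vector (names = pedigree keys, i.e.
#'   `paste(fid, id, sep = ":")`; see [trait_vector()]).
#' @param design numeric matrix with matching rownames, e.g. from
#'   [design_from_traits()]; `NULL` for intercept only.
#' @param kinship a [kinship_matrix()].
#' @param fixed named list of variance parameters to pin, e.g.
#'   `list(g = 0)` for the no-polygene null.
#' @param se compute the observed-information standard errors (skip for
#'   speed in scans and permutation loops).
#' @return object of class `vc_fit`: `sigma2_g`, `sigma2_q` (0 here),
#'   `sigma2_e`, `beta`, `h2`, `se_h2`, `loglik`, `n_used`, `boundary`.
#' @examples
#' cfg <- sim_config(n_families = 30, seed = 7)
#' dat <- sim_dataset(cfg)
#' fit <- fit_polygenic(trait_vector(dat$traits, "trait_i"),
#'                      design_from_traits(dat$traits), dat$kin)
#' fit$h2
#' @export
fit_polygenic <- function(trait, design = NULL, kinship, fixed = list(),
                          se = TRUE) {
  prep <- .vc_prepare(list(trait), design, kinship)
  if (prep$unrelated && !("g" %in% names(fixed))) {
    # no within-family kin covariance: sigma2_g and sigma2_e are confounded
    # along a flat ridge; pin the genetic variance at its boundary
    warning("no within-family kin covariance: heritability is not ",
            "identifiable; estimate sits at the boundary")
    fit <- .vc_fit(prep$dat, fixed = c(fixed, list(g = 0)), hessian = se)
    out <- .vc_fit_summary(fit)
    out$boundary <- TRUE
    out$fixed <- unlist(fixed)   # user-facing constraint set only
    return(out)
  }
  fit <- .vc_fit(prep$dat, fixed = fixed, hessian = se)
  .vc_fit_summary(fit)
}

# shared alignment/complete-case logic for all fitting entry points
.vc_prepare <- function(trait_list, design, kinship, ibd = NULL) {
  keys0 <- names(trait_list[[1]])
  if (is.null(keys0)) stop("trait must be a named vector (pedigree keys)")
  for (tr in trait_list) {
    if (!identical(names(tr), keys0))
      stop("traits must share the same individuals in the same order")
  }
  if (is.null(design)) {
    design <- matrix(1, length(keys0), 1,
                     dimnames = list(keys0, "(Intercept)"))
  }
  keys <- intersect(keys0, rownames(design))
  y <- do.call(cbind, lapply(trait_list, function(tr) tr[keys]))
  X <- design[keys, , drop = FALSE]
  ok <- stats::complete.cases(y) & stats::complete.cases(X)
  y <- y[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]
  if (nrow(y) < ncol(X) + 2) stop("too few complete cases to fit")
  # drop collinear constant columns other than the intercept
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(cl) length(unique(cl)) > 1))
  X <- X[, keep, drop = FALSE]
  rownames(y) <- rownames(X)
  colnames(y) <- if (length(trait_list) == 2) c("trait_i", "trait_e") else "y"
  dat <- .vc_build(y, X, kinship, ibd = ibd)
  kin_sub <- subset_kinship(kinship, rownames(y))
  off <- kin_sub$phi; diag(off) <- 0
  list(dat = dat, unrelated = all(off == 0))
}

.vc_fit_summary <- function(fit, warn_unrelated = FALSE) {
  th <- fit$par
  s2q <- if ("q" %in% names(th)) unname(th["q"]) else 0
  tot <- unname(th["g"]) + s2q + unname(th["e"])
  h2 <- unname(th["g"]) / tot
  boundary <- fit$par_scaled["g"] <= 1e-7
  if (warn_unrelated && !length(fit$fixed)) {
    warning("no within-family kin covariance: heritability is not ",
            "identifiable; estimate sits at the boundary")
  }
  se_h2 <- .delta_se_h2(fit)
  structure(list(sigma2_g = unname(th["g"]), sigma2_q = s2q,
                 sigma2_e = unname(th["e"]),
                 beta = fit$beta, h2 = h2, se_h2 = se_h2,
                 loglik = fit$loglik, n_used = fit$n_used,
                 boundary = unname(boundary), fixed = fit$fixed,
                 par_scaled = fit$par_scaled, vcov = fit$vcov),
            class = "vc_fit")
}

# delta-method SE for h2 = g/(g+q+e) on the scaled parameterization
.delta_se_h2 <- function(fit) {
  V <- fit$vcov
  if (is.null(V)) return(NA_real_)
  th <- fit$par_scaled
  comps <- intersect(c("g", "q", "e"), names(th))
  free <- intersect(comps, colnames(V))
  if (!("g" %in% free)) return(NA_real_)
  tot <- sum(th[comps])
  grad <- stats::setNames(rep(-th[["g"]] / tot^2, length(free)), free)
  grad["g"] <- (tot - th[["g"]]) / tot^2
  v <- drop(t(grad) %*% V[free, free, drop = FALSE] %*% grad)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("polygenic fit: n = %d, logLik = %.3f\n", x$n_used, x$loglik))
  cat(sprintf("  h2 = %.4f (SE %s)%s\n", x$h2,
              ifelse(is.na(x$se_h2), "NA", sprintf("%.4f", x$se_h2)),
              if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  sigma2_g = %.4f, sigma2_q = %.4f, sigma2_e = %.4f\n",
              x$sigma2_g, x$sigma2_q, x$sigma2_e))
  invisible(x)
}

#' Likelihood-ratio test for heritability
#'
#' Compares a polygenic fit against the same model with `sigma2_g`
#' constrained to zero. Because the null pins a variance on its boundary,
#' the test statistic `Lambda = 2 (l_alt - l_null)` (clamped at 0) is
#' referred to the 1/2 chi2_0 : 1/2 chi2_1 mixture:
#' `p = 1/2 P(chi2_1 >= Lambda)`, so `Lambda = 0` gives `p = 1/2`.
#'
#' @param fit_alt,fit_null `vc_fit` objects on identical data; `fit_null`
#'   must have `g` fixed at 0.
#' @return list with `lambda`, `p`.
#' @export
heritability_test <- function(fit_alt, fit_null) {
  if (!isTRUE(all.equal(fit_null$fixed[["g"]], 0)))
    stop("fit_null must fix the genetic variance at zero")
  if (fit_alt$n_used != fit_null$n_used ||
      length(fit_alt$beta) != length(fit_null$beta))
    stop("alternative and null fits use different data or fixed effects")
  lambda <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  p <- 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  if (lambda == 0) p <- 0.5
  list(lambda = lambda, p = p)
}

#' Fit and test heritability in one call
#'
#' Convenience wrapper: fits the polygenic model and its no-polygene null
#' and returns the fit plus the boundary-mixture LRT p-value.
#'
#' @inheritParams fit_polygenic
#' @return the alternative `vc_fit` with elements `p` and `lambda` added.
#' @export
polygenic_heritability <- function(trait, design = NULL, kinship) {
  alt <- fit_polygenic(trait, design, kinship)
  null <- fit_polygenic(trait, design, kinship, fixed = list(g = 0))
  lrt <- heritability_test(alt, null)
  alt$p <- lrt$p
  alt$lambda <- lrt$lambda
  alt
}

#' Serialize a polygenic fit summary as JSON
#'
#' @param fit a `vc_fit` (ideally from [polygenic_heritability()]).
#' @param trait trait name recorded in the summary.
#' @param transform transform label recorded in the summary.
#' @param path output path.
#' @export
write_fit_json <- function(fit, trait, transform = "none", path) {
  obj <- list(trait = trait, n = fit$n_used, h2 = fit$h2, se = fit$se_h2,
              p = if (is.null(fit$p)) NA else fit$p,
              loglik = fit$loglik, beta = as.list(fit$beta),
              transform = transform)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
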