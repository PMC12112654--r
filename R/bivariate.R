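#' Fit the bivariate polygenic model
#'
#' Joint maximum-likelihood fit of two traits with covariance
#' `Sigma_g (x) 2 Phi + Sigma_e (x) I`, where the 2x2 genetic and
#' environmental covariance blocks are parameterized by per-trait variances
#' and the correlations `rho_g`, `rho_e`. Fixed effects are trait-specific
#' and profiled by GLS. Complete cases on the trait pair are used (pairwise
#' deletion), with kinship taken from the full pedigree.
#'
#' With `rho_g` and `rho_e` both fixed at zero the model factorizes into the
#' two univariate polygenic models and attains exactly the sum of their
#' log-likelihoods.
#'
#' @param trait_i,trait_e named numeric vectors (pedigree keys; see
#'   [trait_vector()]): index trait and candidate endophenotype.
#' @param design covariate design matrix (shared by both traits).
#' @param kinship a [kinship_matrix()].
#' @param fixed named list pinning parameters (`g1 g2 rg e1 e2 re`), e.g.
#'   `list(rg = 0)` for the no-genetic-correlation null.
#' @param se compute observed-information standard errors.
#' @return object of class `vc_bivariate_fit`: `h2_i`, `h2_e`, `rho_g`,
#'   `rho_e`, `se_rho_g`, `loglik`, `n_used`, variance components, `beta`.
#' @export
fit_bivariate <- function(trait_i, trait_e, design = NULL, kinship,
                          fixed = list(), se = TRUE) {
  common <- intersect(names(trait_i), names(trait_e))
  prep <- .vc_prepare(list(trait_i[common], trait_e[common]), design, kinship)
  fit <- .vc_fit(prep$dat, fixed = fixed, hessian = se)
  th <- fit$par
  h2_i <- unname(th["g1"] / (th["g1"] + th["e1"]))
  h2_e <- unname(th["g2"] / (th["g2"] + th["e2"]))
  se_rho_g <- NA_real_
  if (!is.null(fit$vcov) && "rg" %in% colnames(fit$vcov))
    se_rho_g <- sqrt(fit$vcov["rg", "rg"])
  structure(list(h2_i = h2_i, h2_e = h2_e,
                 rho_g = unname(th["rg"]), rho_e = unname(th["re"]),
                 se_rho_g = se_rho_g,
                 sigma2 = th, beta = fit$beta, loglik = fit$loglik,
                 n_used = fit$n_used, fixed = fit$fixed,
                 par_scaled = fit$par_scaled, vcov = fit$vcov),
            class = "vc_bivariate_fit")
}

#' @export
print.vc_bivariate_fit <- function(x, ...) {
  cat(sprintf("bivariate polygenic fit: n = %d, logLik = %.3f\n",
              x$n_used, x$loglik))
  cat(sprintf("  h2_i = %.4f, h2_e = %.4f\n", x$h2_i, x$h2_e))
  cat(sprintf("  rho_g = %.4f (SE %s), rho_e = %.4f\n", x$rho_g,
              ifelse(is.na(x$se_rho_g), "NA", sprintf("%.4f", x$se_rho_g)),
              x$rho_e))
  invisible(x)
}

#' Likelihood-ratio test for the genetic correlation
#'
#' Compares the bivariate fit against the restricted model with `rho_g`
#' fixed at zero. Zero is interior to `[-1, 1]`, so the statistic is
#' referred to a plain chi2 with 1 df (no boundary mixture):
#' `p = P(chi2_1 >= Lambda)`. By construction this p-value is identical to
#' the significance of the ERV built from the same fit.
#'
#' @param fit_alt,fit_null `vc_bivariate_fit` objects on identical data;
#'   the null must fix `rg = 0`.
#' @return list with `lambda`, `p`.
#' @export
rho_g_test <- function(fit_alt, fit_null) {
  if (!isTRUE(all.equal(fit_null$fixed[["rg"]], 0)))
    stop("fit_null must fix rho_g at zero")
  if (fit_alt$n_used != fit_null$n_used ||
      length(fit_alt$beta) != length(fit_null$beta))
    stop("alternative and null fits use different data or fixed effects")
  lambda <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  p <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  list(lambda = lambda, p = p)
}

#' Endophenotype ranking value
#'
#' `ERV = |sqrt(h2_i) * sqrt(h2_e) * rho_g|`: the shared additive-genetic
#' signal between an index trait and a candidate endophenotype, in [0, 1].
#' Monotone non-decreasing in each heritability and in `|rho_g|`, and
#' invariant to the sign of the genetic correlation.
#'
#' @param h2_i,h2_e heritabilities in [0, 1].
#' @param rho_g genetic correlation in [-1, 1].
#' @return numeric in [0, 1].
#' @examples
#' erv(0.520, 0.443, 0.847)   # 0.4065
#' @export
erv <- function(h2_i, h2_e, rho_g) {
  if (any(h2_i < 0 | h2_i > 1) || any(h2_e < 0 | h2_e > 1))
    stop("heritabilities must lie in [0, 1]")
  if (any(abs(rho_g) > 1)) stop("|rho_g| must be <= 1")
  abs(sqrt(h2_i) * sqrt(h2_e) * rho_g)
}

#' Evaluate one candidate endophenotype against the index trait
#'
#' Fits the bivariate model and its `rho_g = 0` null, and returns an ERV
#' record: heritabilities, genetic correlation, the ERV and its LRT
#' p-value.
#'
#' @inheritParams fit_bivariate
#' @param endophenotype,class name and class label stored in the record.
#' @param index_h2 optional externally supplied index-trait heritability
#'   (e.g. the univariate estimate); default uses the bivariate fit's own
#'   `h2_i`.
#' @return one-row data frame: `endophenotype`, `class`, `n`, `h2_i`,
#'   `h2_e`, `rho_g`, `se_rho_g`, `erv`, `p`.
#' @export
erv_record <- function(trait_i, trait_e, design = NULL, kinship,
                       endophenotype, class = NA_character_,
                       index_h2 = NULL) {
  alt <- fit_bivariate(trait_i, trait_e, design, kinship)
  null <- fit_bivariate(trait_i, trait_e, design, kinship,
                        fixed = list(rg = 0))
  lrt <- rho_g_test(alt, null)
  h2i <- if (is.null(index_h2)) alt$h2_i else index_h2
  data.frame(endophenotype = endophenotype, class = class,
             n = alt$n_used, h2_i = h2i, h2_e = alt$h2_e,
             rho_g = alt$rho_g, se_rho_g = alt$se_rho_g,
             erv = erv(h2i, alt$h2_e, alt$rho_g), p = lrt$p,
             stringsAsFactors = FALSE)
}

#' Rank candidate endophenotypes and select class winners
#'
#' Sorts ERV records by ERV (descending), breaking ties by smaller p then
#' by name, and selects the top record per class. A class is excluded when
#' its best record fails the significance floor on the ERV likelihood-ratio
#' p-value; individual endophenotypes can also be excluded by name (e.g. a
#' trait redundant with a higher-ranked one).
#'
#' @param records data frame of ERV records (see [erv_record()]); must have
#'   columns `endophenotype`, `class`, `erv`, `p`.
#' @param p_floor significance floor applied to class winners.
#' @param exclude endophenotype names excluded from selection (still shown
#'   in the ranking).
#' @param max_rank rank floor: a class winner must also sit within the top
#'   `max_rank` of the overall ranking (a class whose best candidate ranks
#'   near the bottom overall carries no useful signal even if nominally
#'   significant).
#' @return list: `ranking` (records sorted by ERV descending with a `rank`
#'   column) and `selected` (one winning record per passing class).
#' @export
rank_endophenotypes <- function(records, p_floor = 0.05, exclude = NULL,
                                max_rank = Inf) {
  if (!nrow(records)) stop("no ERV records to rank")
  stopifnot(all(c("endophenotype", "class", "erv", "p") %in% names(records)))
  ord <- order(-records$erv, records$p, records$endophenotype)
  ranking <- records[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  eligible <- ranking[!(ranking$endophenotype %in% exclude), , drop = FALSE]
  selected <- do.call(rbind, lapply(split(eligible, eligible$class),
                                    function(g) g[which.min(g$rank), ]))
  selected <- selected[selected$p < p_floor & selected$rank <= max_rank, ,
                       drop = FALSE]
  selected <- selected[order(selected$rank), , drop = FALSE]
  rownames(selected) <- NULL
  list(ranking = ranking, selected = selected)
}

#' Write an ERV ranking as TSV
#'
#' Columns mirror a standard endophenotype ranking table: endophenotype,
#' class, N, ERV, p, rho_g, SE, h2_e.
#'
#' @param ranking `ranking` element of [rank_endophenotypes()].
#' @param path output path.
#' @export
write_erv_table <- function(ranking, path) {
  cols <- intersect(c("rank", "endophenotype", "class", "n", "erv", "p",
                      "rho_g", "se_rho_g", "h2_e", "h2_i"), names(ranking))
  utils::write.table(ranking[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
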