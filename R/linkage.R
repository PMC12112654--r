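#' Univariate variance-component linkage at one locus
#'
#' Fits `Omega = 2 Phi sigma2_g + Pi sigma2_q + I sigma2_e` against the
#' polygenic null (`sigma2_q = 0`) and converts the likelihood-ratio to a
#' LOD score: `LOD = (l_alt - l_null) / ln 10`, clamped at zero (the QTL
#' variance is a one-sided parameter). When the locus IBD matrix is fully
#' confounded with the kinship matrix (`Pi = 2 Phi`), the QTL variance is
#' not identifiable and the LOD is reported near zero with a warning.
#'
#' @param trait named numeric vector (pedigree keys).
#' @param design covariate design matrix or `NULL`.
#' @param kinship a [kinship_matrix()].
#' @param ibd an `ibd_matrix` at the tested locus.
#' @param null_fit optional pre-computed polygenic null `vc_fit` on the same
#'   data (re-used across loci by [genome_scan()]).
#' @return list of class `linkage_fit`: `lod`, `p` (from
#'   [lod_to_pvalue()]), `fit_alt`, `fit_null`, `locus`.
#' @export
fit_linkage_univariate <- function(trait, design = NULL, kinship, ibd,
                                   null_fit = NULL) {
  prep <- .vc_prepare(list(trait), design, kinship, ibd = ibd)
  .check_ibd_confounding(prep$dat)
  if (is.null(null_fit))
    null_fit <- fit_polygenic(trait, design, kinship, se = FALSE)
  warm <- c(null_fit$par_scaled[c("g", "e")], q = 0.02)
  alt0 <- .vc_fit(prep$dat, start = warm, hessian = FALSE, nstarts = 1)
  # a warm-started optimum below the nested null signals optimizer failure
  if (alt0$loglik < null_fit$loglik - 1e-6)
    alt0 <- .vc_fit(prep$dat, start = warm, hessian = FALSE)
  alt <- .vc_fit_summary(alt0)
  if (alt$n_used != null_fit$n_used)
    stop("null fit uses different individuals than the linkage fit")
  lod <- max(0, (alt$loglik - null_fit$loglik) / log(10))
  structure(list(lod = lod, p = lod_to_pvalue(lod),
                 fit_alt = alt, fit_null = null_fit,
                 locus = ibd$locus), class = "linkage_fit")
}

.check_ibd_confounding <- function(dat) {
  dev <- 0
  for (fb in dat$fams) {
    if (!is.null(fb$P)) dev <- max(dev, max(abs(fb$P - fb$A)))
  }
  if (dev < 1e-10)
    warning("locus IBD matrix equals 2*Phi everywhere: QTL variance is ",
            "confounded with the polygenic component; LOD is not informative")
  invisible(dev)
}

#' LOD score to nominal p-value
#'
#' Under the null the univariate linkage LRT follows the boundary mixture
#' 1/2 chi2_0 : 1/2 chi2_1, so
#' `p = 1/2 P(chi2_1 >= 2 ln(10) * LOD)`; LOD 0 maps to p = 0.5.
#'
#' @param lod LOD score(s), `>= 0`.
#' @return p-value(s).
#' @examples
#' lod_to_pvalue(2.9010)   # 1.29e-4
#' @export
lod_to_pvalue <- function(lod) {
  if (any(lod < 0)) stop("LOD scores must be >= 0")
  0.5 * stats::pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE)
}

#' Nominal p-value to 1-df-equivalent LOD
#'
#' Inverse of [lod_to_pvalue()]: the LOD score a 1-df test would need for
#' the same nominal p under the 1/2 chi2_0 : 1/2 chi2_1 mixture. This is the
#' conventional scale for printing bivariate linkage results next to
#' univariate LODs. `p > 0.5` has no positive solution and returns 0 with a
#' warning.
#'
#' @param p nominal p-value(s) in (0, 0.5].
#' @return LOD-equivalent score(s).
#' @export
pvalue_to_lodeq <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  out <- numeric(length(p))
  high <- p > 0.5
  if (any(high)) {
    warning("p > 0.5 has LOD-equivalent 0")
    out[high] <- 0
  }
  out[!high] <- stats::qchisq(2 * p[!high], df = 1, lower.tail = FALSE) /
    (2 * log(10))
  out
}

#' Bivariate variance-component linkage at one locus
#'
#' Adds a QTL block `Sigma_q (x) Pi` (two QTL variances plus a freely
#' estimated QTL correlation `rho_q`) to the bivariate polygenic model and
#' tests `Sigma_q = 0` by likelihood ratio. Because two variances sit on the
#' boundary under the null, the raw p-value uses a chi-square mixture
#' (default 1/4 chi2_0 : 1/2 chi2_1 : 1/4 chi2_2, configurable), and is then
#' reported as a 1-df-equivalent LOD via [pvalue_to_lodeq()] so that
#' bivariate and univariate scores share a scale.
#'
#' @inheritParams fit_linkage_univariate
#' @param trait_i,trait_e the two traits (named vectors, pedigree keys).
#' @param null_fit optional pre-computed bivariate polygenic fit.
#' @param mixture weights for (chi2_0, chi2_1, chi2_2) under the null.
#' @return list of class `linkage_fit`: `lodeq`, `lod` (= lodeq), `p`,
#'   `lambda`, `fit_alt`, `fit_null`, `locus`.
#' @export
fit_linkage_bivariate <- function(trait_i, trait_e, design = NULL, kinship,
                                  ibd, null_fit = NULL,
                                  mixture = c(0.25, 0.5, 0.25)) {
  stopifnot(length(mixture) == 3, abs(sum(mixture) - 1) < 1e-8)
  common <- intersect(names(trait_i), names(trait_e))
  prep <- .vc_prepare(list(trait_i[common], trait_e[common]), design,
                      kinship, ibd = ibd)
  if (is.null(null_fit))
    null_fit <- fit_bivariate(trait_i, trait_e, design, kinship, se = FALSE)
  warm <- c(null_fit$par_scaled[c("g1", "g2", "rg", "e1", "e2", "re")],
            q1 = 0.02, q2 = 0.02, rq = 0)
  alt <- .vc_fit(prep$dat, start = warm, hessian = FALSE, nstarts = 1)
  if (alt$loglik < null_fit$loglik - 1e-6)
    alt <- .vc_fit(prep$dat, start = warm, hessian = FALSE)
  if (alt$n_used != null_fit$n_used)
    stop("null fit uses different individuals than the linkage fit")
  lambda <- max(0, 2 * (alt$loglik - null_fit$loglik))
  p <- if (lambda <= 0) 1 else {
    mixture[2] * stats::pchisq(lambda, df = 1, lower.tail = FALSE) +
    mixture[3] * stats::pchisq(lambda, df = 2, lower.tail = FALSE)
  }
  lodeq <- pvalue_to_lodeq(min(p, 0.5))
  structure(list(lodeq = lodeq, lod = lodeq, p = p, lambda = lambda,
                 fit_alt = alt, fit_null = null_fit, locus = ibd$locus),
            class = "linkage_fit")
}

#' Genome scan on a cM grid with adaptive fine mapping
#'
#' Computes LOD scores every `coarse_step` cM (default 5) across the map,
#' then refines to every `fine_step` cM (default 1) across the contiguous
#' super-threshold region around any coarse position with LOD above
#' `refine_above` (default 0.5), including the flanking coarse intervals.
#' IBD matrices come from a provider function; positions the provider
#' cannot serve are skipped with a warning (no interpolation).
#'
#' @param traits a named trait vector, or a list of two for a bivariate
#'   scan.
#' @param design covariate design or `NULL`.
#' @param kinship a [kinship_matrix()].
#' @param ibd_provider `function(chrom, cM)` returning an `ibd_matrix` or
#'   `NULL`; see [ibd_provider_from_descent()] and
#'   [ibd_provider_from_list()].
#' @param map data frame `chrom`, `cM` defining the scan span.
#' @param coarse_step,fine_step,refine_above scan tuning (cM, cM, LOD).
#' @return data frame of class `lod_curve`: `chrom`, `cM`, `lod` (plus
#'   `p`), attribute `trait_labels`.
#' @export
genome_scan <- function(traits, design = NULL, kinship, ibd_provider, map,
                        coarse_step = 5, fine_step = 1, refine_above = 0.5) {
  bivar <- is.list(traits) && !is.numeric(traits)
  if (bivar) stopifnot(length(traits) == 2)
  null_fit <- if (bivar) {
    fit_bivariate(traits[[1]], traits[[2]], design, kinship, se = FALSE)
  } else {
    fit_polygenic(traits, design, kinship, se = FALSE)
  }
  eval_locus <- function(chrom, cM) {
    ibd <- ibd_provider(chrom, cM)
    if (is.null(ibd)) {
      warning(sprintf("no IBD matrix available at chr%s %g cM; skipped",
                      chrom, cM))
      return(NA_real_)
    }
    f <- if (bivar) {
      fit_linkage_bivariate(traits[[1]], traits[[2]], design, kinship, ibd,
                            null_fit = null_fit)
    } else {
      fit_linkage_univariate(traits, design, kinship, ibd,
                             null_fit = null_fit)
    }
    f$lod
  }
  out <- list()
  for (ch in unique(map$chrom)) {
    span <- range(map$cM[map$chrom == ch])
    coarse <- seq(span[1], span[2], by = coarse_step)
    lods <- vapply(coarse, function(x) eval_locus(ch, x), numeric(1))
    pos <- coarse; val <- lods
    hot <- which(!is.na(lods) & lods > refine_above)
    if (length(hot)) {
      # contiguous super-threshold runs, extended one coarse interval
      runs <- split(hot, cumsum(c(1, diff(hot) != 1)))
      fine_pos <- unlist(lapply(runs, function(r) {
        lo <- max(span[1], coarse[min(r)] - coarse_step)
        hi <- min(span[2], coarse[max(r)] + coarse_step)
        seq(lo, hi, by = fine_step)
      }))
      fine_pos <- setdiff(sort(unique(fine_pos)), coarse)
      if (length(fine_pos)) {
        fl <- vapply(fine_pos, function(x) eval_locus(ch, x), numeric(1))
        pos <- c(pos, fine_pos); val <- c(val, fl)
      }
    }
    keep <- !is.na(val)
    o <- order(pos[keep])
    out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                          cM = pos[keep][o],
                                          lod = val[keep][o])
  }
  curve <- do.call(rbind, out)
  curve$p <- lod_to_pvalue(curve$lod)
  attr(curve, "trait_labels") <- if (bivar) {
    c(attr(traits[[1]], "label"), attr(traits[[2]], "label"))
  } else attr(traits, "label")
  class(curve) <- c("lod_curve", "data.frame")
  curve
}

#' IBD providers for genome scans
#'
#' `ibd_provider_from_descent()` serves exact IBD matrices at any position
#' on the gene-drop map (simulation ground truth).
#' `ibd_provider_from_list()` serves pre-computed matrices only; requests
#' at other positions return `NULL` (the scan skips them rather than
#' interpolating).
#'
#' @param rec a `descent_record`.
#' @return `function(chrom, cM) -> ibd_matrix | NULL`.
#' @export
ibd_provider_from_descent <- function(rec) {
  function(chrom, cM) {
    hit <- which(rec$loci$chrom == chrom & rec$loci$cM == cM)
    if (!length(hit)) return(NULL)
    ibd_from_descent(rec, chrom, cM)
  }
}

#' @rdname ibd_provider_from_descent
#' @param ibd_list list of `ibd_matrix` objects.
#' @export
ibd_provider_from_list <- function(ibd_list) {
  key <- vapply(ibd_list, function(im) paste(im$locus$chrom, im$locus$cM),
                character(1))
  function(chrom, cM) {
    hit <- which(key == paste(chrom, cM))
    if (!length(hit)) return(NULL)
    ibd_list[[hit[1]]]
  }
}

#' Call QTL peaks on a LOD curve
#'
#' Reports local maxima above the suggestive threshold, with status
#' `significant` (LOD >= `significant`) or `suggestive` (>= `suggestive`),
#' each with its nominal p-value and -1-LOD support interval: the maximal
#' contiguous region around the peak with LOD >= peak - 1, clipped at
#' chromosome ends. Only the highest point of each contiguous
#' super-suggestive region is called.
#'
#' @param curve a `lod_curve` (or data frame with `chrom`, `cM`, `lod`).
#' @param significant,suggestive LOD thresholds (defaults 2.87 and 1.67,
#'   genome-wide adjusted and suggestive linkage levels).
#' @return data frame of class `qtl_peaks`: `chrom`, `cM`, `lod`,
#'   `p_nominal`, `status`, `ci_lo`, `ci_hi`.
#' @export
call_peaks <- function(curve, significant = 2.87, suggestive = 1.67) {
  stopifnot(nrow(curve) > 0)
  peaks <- list()
  for (ch in unique(curve$chrom)) {
    cc <- curve[curve$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$cM), , drop = FALSE]
    above <- cc$lod >= suggestive
    if (!any(above)) next
    runs <- split(which(above), cumsum(c(1, diff(which(above)) != 1)))
    for (r in runs) {
      k <- r[which.max(cc$lod[r])]
      peak_lod <- cc$lod[k]
      # -1-LOD support interval around the peak
      lo <- k; while (lo > 1 && cc$lod[lo - 1] >= peak_lod - 1) lo <- lo - 1
      hi <- k; while (hi < nrow(cc) && cc$lod[hi + 1] >= peak_lod - 1)
        hi <- hi + 1
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, cM = cc$cM[k], lod = peak_lod,
        p_nominal = lod_to_pvalue(peak_lod),
        status = if (peak_lod >= significant) "significant" else "suggestive",
        ci_lo = cc$cM[lo], ci_hi = cc$cM[hi], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(0), cM = numeric(0), lod = numeric(0),
               p_nominal = numeric(0), status = character(0),
               ci_lo = numeric(0), ci_hi = numeric(0))
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

#' Genome-wide LOD threshold by the Ornstein-Uhlenbeck upcrossing bound
#'
#' Solves `alpha = (C + 2 rho G t*) * 1/2 P(chi2_1 >= t*)` with
#' `t* = 2 ln(10) t` for the LOD threshold `t`, where `C` is the number of
#' chromosomes, `G` the genome length in Morgans and `rho` the correlation
#' decay rate of the linkage process. This is the dense-map large-pedigree
#' approximation behind adjusted genome-wide significance levels
#' (e.g. LOD thresholds near 2.9 rather than the classical 3.0).
#'
#' @param alpha genome-wide type-I error, in (0, 1).
#' @param genome_morgans genome length G in Morgans.
#' @param n_chrom number of chromosomes C.
#' @param rho process correlation decay rate (pedigree-dependent, about
#'   0.3-0.6 for extended pedigrees).
#' @return LOD threshold.
#' @export
genomewide_threshold <- function(alpha = 0.05, genome_morgans = 35,
                                 n_chrom = 23, rho = 0.55) {
  stopifnot(alpha > 0, alpha < 1, genome_morgans > 0)
  f <- function(t) {
    tstar <- 2 * log(10) * t
    (n_chrom + 2 * rho * genome_morgans * tstar) *
      0.5 * stats::pchisq(tstar, df = 1, lower.tail = FALSE) - alpha
  }
  if (f(1e-6) < 0) return(0)
  if (f(10) > 0) stop("no LOD threshold in (0, 10] for these settings")
  stats::uniroot(f, c(1e-6, 10), tol = 1e-8)$root
}

#' Write a LOD curve as TSV
#'
#' Columns: chrom, cM, lod, trait_labels.
#'
#' @param curve a `lod_curve`.
#' @param path output path.
#' @export
write_lod_curve <- function(curve, path) {
  lab <- paste(attr(curve, "trait_labels"), collapse = "+")
  if (lab == "") lab <- NA
  out <- data.frame(chrom = curve$chrom, cM = curve$cM, lod = curve$lod,
                    trait_labels = lab)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
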