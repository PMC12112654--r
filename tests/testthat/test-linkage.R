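local_linkage_data <- function(seed = 91, n_families = 60, varfrac = 0.25,
                               h2 = 0.4) {
  cfg <- sim_config(n_families = n_families, h2 = h2, seed = seed,
                    map = data.frame(chrom = rep(1:2, each = 11),
                                     cM = rep(seq(0, 50, 5), 2)),
                    qtl = list(chrom = 1, cM = 25, varfrac = varfrac,
                               maf = 0.3))
  dat <- sim_dataset(cfg)
  list(dat = dat, y = trait_vector(dat$traits, "trait_i"),
       X = design_from_traits(dat$traits))
}

test_that("printed LOD/p pairs reproduce under the half-chi-square rule", {
  tab <- read.delim(system.file("extdata", "table3_lod_pairs.tsv",
                                package = "famerv"))
  expect_equal(signif(lod_to_pvalue(tab$lod), 3), tab$p_printed)
  expect_equal(lod_to_pvalue(0), 0.5)
  expect_error(lod_to_pvalue(-1), ">= 0")
  # strictly decreasing in LOD
  lods <- seq(0, 5, 0.1)
  expect_true(all(diff(lod_to_pvalue(lods)) < 0))
})

test_that("p to LOD-equivalent inverts the conversion", {
  expect_equal(pvalue_to_lodeq(9.03e-4), 2.114, tolerance = 5e-4)
  x <- c(0.01, 0.5, 1.3, 2.9, 4.2)
  expect_equal(pvalue_to_lodeq(lod_to_pvalue(x)), x, tolerance = 1e-10)
  expect_equal(pvalue_to_lodeq(0.5), 0)
  expect_warning(z <- pvalue_to_lodeq(0.7), "LOD-equivalent 0")
  expect_equal(z, 0)
  expect_error(pvalue_to_lodeq(0), "\\(0, 1\\]")
})

test_that("fully confounded IBD yields an uninformative LOD with warning", {
  d <- local_linkage_data(seed = 92, n_families = 30)
  kin <- d$dat$kin
  fake <- list(pi = 2 * kin$phi, ids = kin$ids, key = kin$key,
               fid = kin$fid, locus = list(chrom = 1, cM = 25))
  class(fake) <- "ibd_matrix"
  expect_warning(
    lf <- fit_linkage_univariate(d$y, d$X, kin, fake),
    "confounded")
  expect_lt(lf$lod, 0.01)
})

test_that("linkage finds signal at the QTL and not at unlinked loci", {
  d <- local_linkage_data(seed = 93, n_families = 104, varfrac = 0.3)
  null_fit <- fit_polygenic(d$y, d$X, d$dat$kin, se = FALSE)
  at_qtl <- fit_linkage_univariate(d$y, d$X, d$dat$kin,
                                   ibd_from_descent(d$dat$descent, 1, 25),
                                   null_fit = null_fit)
  away <- fit_linkage_univariate(d$y, d$X, d$dat$kin,
                                 ibd_from_descent(d$dat$descent, 2, 25),
                                 null_fit = null_fit)
  expect_gt(at_qtl$lod, away$lod)
  expect_gt(at_qtl$lod, 0.5)
  # LOD invariant to affine trait rescaling
  at_qtl2 <- fit_linkage_univariate(3 * d$y - 7, d$X, d$dat$kin,
                                    ibd_from_descent(d$dat$descent, 1, 25))
  expect_equal(at_qtl2$lod, at_qtl$lod, tolerance = 1e-3)
})

test_that("bivariate linkage nests its polygenic null and sees shared QTLs", {
  cfg <- sim_config(n_families = 80, h2 = c(0.4, 0.4), rho_g = 0.7,
                    rho_e = 0.2, seed = 94,
                    map = data.frame(chrom = 1, cM = seq(0, 40, 10)),
                    qtl = list(chrom = 1, cM = 20, varfrac = 0.25, maf = 0.3))
  dat <- sim_dataset(cfg)
  X <- design_from_traits(dat$traits)
  ti <- trait_vector(dat$traits, "trait_i")
  te <- trait_vector(dat$traits, "trait_e")
  nullb <- fit_bivariate(ti, te, X, dat$kin, se = FALSE)
  ibd <- ibd_from_descent(dat$descent, 1, 20)
  bl <- fit_linkage_bivariate(ti, te, X, dat$kin, ibd, null_fit = nullb)
  expect_gte(bl$lambda, 0)
  expect_gt(bl$lodeq, 0.5)
  expect_true(bl$p <= 1 && bl$p > 0)
  # mixture weights must sum to one
  expect_error(fit_linkage_bivariate(ti, te, X, dat$kin, ibd,
                                     mixture = c(0.5, 0.5, 0.5)),
               "mixture")
})

test_that("genome scan refines only around super-threshold coarse points", {
  d <- local_linkage_data(seed = 95, n_families = 104, varfrac = 0.3)
  attr(d$y, "label") <- "trait_i"
  curve <- genome_scan(d$y, d$X, d$dat$kin,
                       ibd_provider_from_descent(d$dat$descent),
                       map = d$dat$config$map,
                       coarse_step = 5, fine_step = 1, refine_above = 0.5)
  expect_s3_class(curve, "lod_curve")
  expect_true(all(curve$lod >= 0))
  # grid strictly increasing within chromosome
  for (ch in unique(curve$chrom))
    expect_true(all(diff(curve$cM[curve$chrom == ch]) > 0))
  # fine positions appear only where the coarse curve cleared the threshold
  fine <- curve[curve$cM %% 5 != 0, ]
  if (nrow(fine)) {
    for (k in seq_len(nrow(fine))) {
      near <- curve$chrom == fine$chrom[k] &
              curve$cM %% 5 == 0 &
              abs(curve$cM - fine$cM[k]) <= 5
      expect_gt(max(curve$lod[near]), 0.5)
    }
  }
  # a flat null scan adds no refinement positions
  cfg0 <- sim_config(n_families = 40, h2 = 0.3, seed = 96,
                     map = data.frame(chrom = 1, cM = seq(0, 30, 5)))
  dat0 <- sim_dataset(cfg0)
  y0 <- trait_vector(dat0$traits, "trait_i")
  X0 <- design_from_traits(dat0$traits)
  curve0 <- genome_scan(y0, X0, dat0$kin,
                        ibd_provider_from_descent(dat0$descent),
                        map = dat0$config$map, refine_above = Inf)
  expect_true(all(curve0$cM %% 5 == 0))
  # provider without fine matrices: fine positions skipped with a warning
  coarse_list <- lapply(seq(0, 30, 5), function(x)
    ibd_from_descent(dat0$descent, 1, x))
  expect_warning(
    curve1 <- genome_scan(y0, X0, dat0$kin,
                          ibd_provider_from_list(coarse_list),
                          map = dat0$config$map, refine_above = -1),
    "skipped")
  expect_true(all(curve1$cM %% 5 == 0))
})

test_that("peak calling applies thresholds and -1-LOD support intervals", {
  curve <- data.frame(chrom = "1", cM = seq(0, 30, 5),
                      lod = c(0, 1, 3, 2.5, 2, 1, 0))
  pk <- call_peaks(curve)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$cM, 10)
  expect_equal(pk$lod, 3)
  expect_equal(pk$status, "significant")       # 3 >= 2.87
  expect_equal(c(pk$ci_lo, pk$ci_hi), c(10, 20))  # lod >= 2 spans 10-20
  expect_equal(pk$p_nominal, lod_to_pvalue(3))

  # the printed significant univariate peak is classified significant
  pk2 <- call_peaks(data.frame(chrom = "17", cM = c(0, 5, 10),
                               lod = c(1, 2.9010, 1)))
  expect_equal(pk2$status, "significant")
  # suggestive band
  pk3 <- call_peaks(data.frame(chrom = "1", cM = c(0, 5, 10),
                               lod = c(0.2, 1.8, 0.2)))
  expect_equal(pk3$status, "suggestive")
  # monotone curve: boundary peak, interval clipped at the chromosome end
  pk4 <- call_peaks(data.frame(chrom = "1", cM = seq(0, 20, 5),
                               lod = c(0.5, 1, 1.5, 2, 2.5)))
  expect_equal(pk4$cM, 20)
  expect_equal(pk4$ci_hi, 20)
  expect_equal(pk4$ci_lo, 10)   # lod >= 1.5
  # sub-threshold curve: nothing called
  expect_equal(nrow(call_peaks(data.frame(chrom = "1", cM = c(0, 5),
                                          lod = c(0.5, 1)))), 0L)
})

test_that("genome-wide threshold solves the upcrossing approximation", {
  thr <- genomewide_threshold(alpha = 0.05, genome_morgans = 35,
                              n_chrom = 23, rho = 0.55)
  expect_gt(thr, 2.6)
  expect_lt(thr, 3.1)
  # monotone: looser alpha lowers the threshold, longer genome raises it
  expect_lt(genomewide_threshold(alpha = 0.2, 35, 23, 0.55), thr)
  expect_gt(genomewide_threshold(alpha = 0.05, 70, 23, 0.55), thr)
  # the solved threshold satisfies the defining equation
  tstar <- 2 * log(10) * thr
  alpha_back <- (23 + 2 * 0.55 * 35 * tstar) *
    0.5 * pchisq(tstar, 1, lower.tail = FALSE)
  expect_equal(alpha_back, 0.05, tolerance = 1e-6)
})

test_that("LOD curves serialize as TSV", {
  curve <- structure(data.frame(chrom = 1, cM = c(0, 5), lod = c(0.1, 0.7)),
                     class = c("lod_curve", "data.frame"))
  attr(curve, "trait_labels") <- c("a", "b")
  tf <- tempfile(fileext = ".tsv")
  write_lod_curve(curve, tf)
  back <- read.delim(tf)
  expect_equal(back$lod, curve$lod)
  expect_equal(unique(back$trait_labels), "a+b")
})
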