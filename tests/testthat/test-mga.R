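local_mga_data <- function(seed = 111, n_families = 80, varfrac = 0.1) {
  cfg <- sim_config(n_families = n_families, h2 = 0.4, seed = seed,
                    map = data.frame(chrom = 1, cM = seq(0, 20, 5)),
                    qtl = if (varfrac > 0)
                      list(chrom = 1, cM = 10, varfrac = varfrac, maf = 0.3))
  dat <- sim_dataset(cfg)
  qd <- attr(dat$traits, "qtl_dosage")
  list(dat = dat, y = trait_vector(dat$traits, "trait_i"),
       X = design_from_traits(dat$traits),
       qd = if (!is.null(qd)) stats::setNames(qd, dat$ped$key))
}

test_that("minor allele frequency folds and flags monomorphic variants", {
  expect_equal(minor_allele_frequency(c(0, 1, 2, 2))$maf, 0.375)
  m <- minor_allele_frequency(c(2, 2, 2, 1))
  expect_equal(m$maf, 0.125)                 # folded from 0.875
  expect_equal(m$minor_allele, "other")
  z <- minor_allele_frequency(c(0, 0, 0))
  expect_true(z$monomorphic)
  expect_equal(z$maf, 0)
  expect_equal(minor_allele_frequency(c(NA, 1, 1))$n_genotyped, 2L)
  expect_error(minor_allele_frequency(c(NA, NA)), "missing")
})

test_that("a causal variant is detected inside the polygenic model", {
  d <- local_mga_data(seed = 112, n_families = 104, varfrac = 0.1)
  res <- fit_mga(d$y, d$X, d$dat$kin, d$qd, snp_id = "causal")
  expect_lt(res$p, 1e-3)
  expect_gt(abs(res$beta), 0)
  # Wald variant available and broadly consistent
  resw <- fit_mga(d$y, d$X, d$dat$kin, d$qd, wald = TRUE)
  expect_lt(resw$p_wald, 1e-2)
  # missing dosages drop individuals from both fits
  qd2 <- d$qd; qd2[1:10] <- NA
  res2 <- fit_mga(d$y, d$X, d$dat$kin, qd2)
  expect_equal(res2$n_genotyped, length(d$qd) - 10L)
})

test_that("monomorphic variants return p = 1 with a flag", {
  d <- local_mga_data(seed = 113, n_families = 20, varfrac = 0)
  dos <- stats::setNames(rep(0, nrow(d$dat$ped)), d$dat$ped$key)
  res <- fit_mga(d$y, d$X, d$dat$kin, dos)
  expect_true(res$monomorphic)
  expect_equal(res$p, 1)
})

test_that("bivariate MGA uses a 2-df dosage test across both trait means", {
  cfg <- sim_config(n_families = 80, h2 = c(0.4, 0.4), rho_g = 0.7,
                    rho_e = 0.2, seed = 114,
                    map = data.frame(chrom = 1, cM = seq(0, 20, 5)),
                    qtl = list(chrom = 1, cM = 10, varfrac = 0.12, maf = 0.3))
  dat <- sim_dataset(cfg)
  qd <- stats::setNames(attr(dat$traits, "qtl_dosage"), dat$ped$key)
  res <- fit_mga(list(trait_vector(dat$traits, "trait_i"),
                      trait_vector(dat$traits, "trait_e")),
                 design_from_traits(dat$traits), dat$kin, qd)
  expect_lt(res$p, 1e-2)
})

test_that("region thresholds follow the reporting convention", {
  expect_equal(region_bonferroni(3500)$threshold, 1e-5)
  expect_equal(signif(region_bonferroni(3500)$exact, 3), 1.43e-5)
  expect_equal(region_bonferroni(9500)$threshold, 5e-6)
  expect_equal(region_bonferroni(9500, threshold_style = "exact")$threshold,
               0.05 / 9500)
  expect_equal(floor_one_sig_fig(c(1.43e-5, 5.26e-6, 0.99)),
               c(1e-5, 5e-6, 0.9))
})

test_that("tier assignment is pure, idempotent, and boundary-consistent", {
  p <- c(1e-6, 1e-5, 5e-5, 1e-4, 5e-4)
  tiers <- assign_tier(p, bonferroni = 1e-5, marginal = 1e-4)
  expect_equal(tiers, c("bonferroni_significant", "marginal", "marginal",
                        "marginal", "none"))
  # a p exactly at the rounded Bonferroni threshold reports as marginal
  expect_equal(assign_tier(1e-5, 1e-5, 1e-4), "marginal")
  expect_equal(assign_tier(1e-5, 1e-5, 1e-4, bonferroni_strict = FALSE),
               "bonferroni_significant")
  # idempotent re-tiering
  expect_equal(assign_tier(p, 1e-5, 1e-4), tiers)
})

test_that("region scans reuse per-SNP fits and report thresholds", {
  d <- local_mga_data(seed = 115, n_families = 60, varfrac = 0.15)
  map <- d$dat$config$map
  snps <- data.frame(snp = sprintf("snp%d", seq_len(nrow(map))),
                     chrom = map$chrom, pos = map$cM)
  dos <- t(d$dat$descent$dosage)
  rownames(dos) <- snps$snp
  dos["snp3", ] <- d$qd           # causal locus at 10 cM
  res <- region_scan(d$y, d$X, d$dat$kin, dos, snps,
                     region = list(chrom = 1, lo = 5, hi = 15))
  expect_equal(nrow(res), 3L)
  expect_equal(attr(res, "n_snps_region"), 3L)
  expect_equal(attr(res, "bonferroni_threshold"),
               floor_one_sig_fig(0.05 / 3))
  # identical to per-SNP fit_mga p-values
  single <- fit_mga(d$y, d$X, d$dat$kin, dos["snp3", ])
  expect_equal(res$p[res$snp_id == "snp3"], single$p, tolerance = 1e-9)
  expect_error(region_scan(d$y, d$X, d$dat$kin, dos, snps,
                           region = list(chrom = 9, lo = 0, hi = 5)),
               "no SNPs")
  # results table writer
  tf <- tempfile(fileext = ".tsv")
  write_mga_table(res, "trait_i", tf)
  expect_equal(nrow(read.delim(tf)), 3L)
})

test_that("an added unrelated singleton leaves other contributions intact", {
  d <- local_mga_data(seed = 116, n_families = 40, varfrac = 0.1)
  res1 <- fit_mga(d$y, d$X, d$dat$kin, d$qd)
  # append one genotyped singleton with trait at the population mean
  ped2 <- pedigree(c(d$dat$ped$fid, "Fx"), c(d$dat$ped$id, "solo"),
                   c(d$dat$ped$father, "0"), c(d$dat$ped$mother, "0"),
                   c(as.character(d$dat$ped$sex), "1"))
  kin2 <- kinship_matrix(ped2)
  key_new <- setdiff(kin2$key, d$dat$kin$key)
  y2 <- c(d$y, stats::setNames(mean(d$y), key_new))
  X2 <- rbind(d$X, matrix(c(1, 0, 0, 0), 1,
                          dimnames = list(key_new, colnames(d$X))))
  qd2 <- c(d$qd, stats::setNames(1, key_new))
  res2 <- fit_mga(y2, X2, kin2, qd2)
  # likelihood additivity: the singleton shifts Lambda only through its own
  # (tiny) contribution, so the p-values stay close
  expect_equal(log10(res2$p), log10(res1$p), tolerance = 0.6)
})
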