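test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_families = 30, seed = 21,
                    qtl = list(chrom = 1, cM = 40, varfrac = 0.1, maf = 0.3))
  d1 <- sim_dataset(cfg)
  d2 <- sim_dataset(cfg)
  expect_identical(d1$ped, d2$ped)
  expect_identical(d1$descent, d2$descent)
  expect_identical(d1$traits, d2$traits)
  # a different seed changes the data
  d3 <- sim_dataset(sim_config(n_families = 30, seed = 22,
                               qtl = cfg$qtl))
  expect_false(identical(d1$traits, d3$traits))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(rho_g = 1.5), "rho_g")
  expect_error(sim_config(maf_spectrum = c(0, 0.1)), "maf")
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(h2 = 0.9,
                          qtl = list(chrom = 1, cM = 0, varfrac = 0.2,
                                     maf = 0.3)),
               "varfrac")
})

test_that("family templates hit the target size distribution", {
  # degenerate mixture: all singletons
  cfg <- sim_config(n_families = 12, seed = 1,
                    template_weights = c(singleton = 1, nuclear = 0,
                                         three_gen = 0, extended = 0))
  expect_equal(nrow(simulate_pedigrees(cfg)), 12L)
  # default mixture: median family size 3 +/- 1, mean near 7, max <= 58
  meds <- means <- numeric(6)
  for (s in 1:6) {
    ped <- simulate_pedigrees(sim_config(n_families = 104, seed = 100 + s))
    sizes <- as.integer(table(ped$fid))
    meds[s] <- stats::median(sizes)
    means[s] <- mean(sizes)
    expect_lte(max(sizes), 58)
  }
  expect_true(all(abs(meds - 3) <= 1))
  expect_true(abs(mean(means) - 7) < 2)
})

test_that("gene dropping is Mendelian with Haldane recombination", {
  # population dosage mean over many founders ~ 2*MAF
  maf <- 0.3
  cfg <- sim_config(n_families = 5000, seed = 77,
                    template_weights = c(singleton = 1, nuclear = 0,
                                         three_gen = 0, extended = 0),
                    map = data.frame(chrom = 1, cM = 0),
                    maf_spectrum = maf)
  ped <- simulate_pedigrees(cfg)
  rec <- gene_drop(ped, cfg)
  se <- sqrt(2 * maf * (1 - maf) / 5000)
  expect_lt(abs(mean(rec$dosage) - 2 * maf), 3 * se)

  # zero map distance: identical descent labels at both loci
  cfg0 <- sim_config(n_families = 20, seed = 3,
                     map = data.frame(chrom = 1, cM = c(10, 10)))
  ped0 <- simulate_pedigrees(cfg0)
  rec0 <- gene_drop(ped0, cfg0)
  expect_identical(rec0$pat[, 1], rec0$pat[, 2])
  expect_identical(rec0$mat[, 1], rec0$mat[, 2])

  # distant loci (same chromosome, 200 cM) recombine nearly freely:
  # transmitted-strand correlation near 0
  cfgd <- sim_config(n_families = 2000, seed = 13,
                     template_weights = c(singleton = 0, nuclear = 1,
                                          three_gen = 0, extended = 0),
                     map = data.frame(chrom = 1, cM = c(0, 200)))
  pedd <- simulate_pedigrees(cfgd)
  recd <- gene_drop(pedd, cfgd)
  kids <- which(!is.na(pedd$father))
  fa <- match(paste(pedd$fid[kids], pedd$father[kids], sep = ":"), pedd$key)
  s1 <- recd$pat[kids, 1] == recd$pat[fa, 1]   # grandpaternal at locus 1
  s2 <- recd$pat[kids, 2] == recd$pat[fa, 2]
  expect_lt(abs(cor(s1, s2)), 0.05)
})

test_that("exact IBD from descent matches its definition", {
  cfg <- sim_config(n_families = 6, seed = 31,
                    map = data.frame(chrom = 1, cM = seq(0, 50, 10)))
  ped <- simulate_pedigrees(cfg)
  rec <- gene_drop(ped, cfg)
  ibd <- ibd_from_descent(rec, 1, 20)
  # parent-offspring share exactly one allele at every locus
  kids <- which(!is.na(ped$father))
  for (k in kids) {
    f <- match(paste(ped$fid[k], ped$father[k], sep = ":"), ped$key)
    expect_equal(unname(ibd$pi[k, f]), 0.5)
  }
  # cross-family pairs share nothing; non-inbred diagonal is 1
  expect_true(all(ibd$pi[outer(ped$fid, ped$fid, "!=")] == 0))
  expect_true(all(diag(ibd$pi) == 1))
  expect_true(isSymmetric(ibd$pi))
  expect_error(ibd_from_descent(rec, 1, 33), "not present")

  # brute-force allele-label oracle on a small family
  small <- ped_half_and_cousins()
  cfg2 <- sim_config(n_families = 1, seed = 4,
                     map = data.frame(chrom = 1, cM = c(0, 25)))
  rec2 <- gene_drop(small, cfg2)
  for (l in 1:2) {
    ib <- ibd_from_descent(rec2, 1, rec2$loci$cM[l])
    expect_equal(unname(ib$pi), oracle_ibd_bruteforce(rec2, l))
  }
})

test_that("sib-pair IBD follows the Mendelian 1/4-1/2-1/4 law across loci", {
  # many independent loci (one per chromosome) for one sib pair
  L <- 4000
  cfg <- sim_config(n_families = 1, seed = 8,
                    map = data.frame(chrom = seq_len(L), cM = 0))
  rec <- gene_drop(ped_nuclear(2), cfg)
  k1 <- 3; k2 <- 4   # the two children (rows are topologically ordered)
  pis <- vapply(seq_len(L), function(l) {
    m <- sum(outer(c(rec$pat[k1, l], rec$mat[k1, l]),
                   c(rec$pat[k2, l], rec$mat[k2, l]), "==")) / 2
    m
  }, numeric(1))
  expect_lt(abs(mean(pis) - 0.5), 3 * stats::sd(pis) / sqrt(L))
  freq <- table(factor(pis, levels = c(0, 0.5, 1))) / L
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.05)
})

test_that("phenotype generator reproduces the configured structure", {
  # rho_g = 1 with equal h2: genetic values perfectly rank-correlated
  cfg <- sim_config(n_families = 40, seed = 12, h2 = c(0.5, 0.5),
                    rho_g = 1, rho_e = 0)
  dat <- sim_dataset(cfg)
  a <- attr(dat$traits, "genetic_values")
  expect_equal(cor(a[, 1], a[, 2], method = "spearman"), 1)

  # sib-pair trait covariance ~ (h2/2) * total variance
  cfgs <- sim_config(n_families = 150, seed = 40, h2 = 0.6,
                     beta = c(age = 0, sex = 0, age_sex = 0),
                     template_weights = c(singleton = 0, nuclear = 1,
                                          three_gen = 0, extended = 0))
  ped <- simulate_pedigrees(cfgs)
  kin <- kinship_matrix(ped)
  covs <- vapply(1:60, function(r) {
    cfgr <- cfgs; cfgr$seed <- cfgr$seed + 1000L * r
    tr <- simulate_phenotypes(ped, kin, cfgr)
    y <- tr$trait_i
    sibs <- which(!is.na(ped$father))
    # all sib pairs across families
    out <- c()
    for (fam in unique(ped$fid)) {
      ks <- sibs[ped$fid[sibs] == fam]
      if (length(ks) >= 2) {
        pr <- t(combn(ks, 2))
        out <- rbind(out, cbind(y[pr[, 1]], y[pr[, 2]]))
      }
    }
    mean(out[, 1] * out[, 2]) - mean(out[, 1]) * mean(out[, 2])
  }, numeric(1))
  expect_lt(abs(mean(covs) - 0.3), 3 * sd(covs) / sqrt(60) + 0.02)
})

test_that("simulated datasets round-trip through the file interfaces", {
  cfg <- sim_config(n_families = 10, seed = 2,
                    map = data.frame(chrom = 1, cM = c(0, 10, 20)))
  dat <- sim_dataset(cfg)
  td <- tempfile(); dir.create(td)

  write_traits(dat$traits, file.path(td, "traits.tsv"))
  tr2 <- read_traits(file.path(td, "traits.tsv"))
  expect_equal(tr2$trait_i, dat$traits$trait_i, tolerance = 1e-12)

  dos <- t(dat$descent$dosage)
  rownames(dos) <- sprintf("snp%d", seq_len(nrow(dos)))
  write_dosages(dos, file.path(td, "dos.tsv"))
  expect_equal(read_dosages(file.path(td, "dos.tsv")), dos)
  # transposed layout auto-detected
  tdos <- data.frame(id = colnames(dos), t(dos), check.names = FALSE)
  write.table(tdos, file.path(td, "dos_t.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_dosages(file.path(td, "dos_t.tsv")), dos)

  ibd <- lapply(c(0, 10), function(x) ibd_from_descent(dat$descent, 1, x))
  write_ibd_long(ibd, file.path(td, "ibd.tsv"))
  ibd2 <- read_ibd_long(file.path(td, "ibd.tsv"), dat$ped)
  got <- ibd2[[which(vapply(ibd2, function(i) i$locus$cM, 1) == 10)]]
  expect_equal(got$pi, ibd[[2]]$pi)
})
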