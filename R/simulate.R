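#' Simulation configuration
#'
#' Bundles the knobs of the synthetic family study: number of families, the
#' family-structure template mixture, the marker map, the minor-allele
#' frequency spectrum, trait variance components and an optional pleiotropic
#' QTL. Defaults emulate a large family study: 104 families with sizes from
#' 1 to a few dozen (median about 3, mean about 7), traits with heritability
#' in the 0.25-0.67 range, a genetic correlation up to 0.85 between an index
#' trait and an endophenotype, and SNP minor-allele frequencies spanning
#' 0.006 to 0.5.
#'
#' @param n_families number of families.
#' @param template_weights named weights over templates `singleton`,
#'   `nuclear`, `three_gen`, `extended`.
#' @param map data frame with columns `chrom`, `cM`: marker/evaluation grid
#'   for gene dropping. Default: two chromosomes of 100 cM at 1 cM steps.
#' @param maf_spectrum allele frequencies recycled across loci.
#' @param h2 heritability per trait (length 1 or 2).
#' @param rho_g,rho_e genetic/environmental cross-trait correlations
#'   (bivariate only).
#' @param qtl optional list `(chrom, cM, varfrac, maf)`: a causal diallelic
#'   locus whose dosage explains `varfrac` of each trait's variance
#'   (`varfrac` length 1 or 2).
#' @param beta fixed effects `c(age, sex, age_sex)` on each trait.
#' @param trait_names names for the simulated traits.
#' @param seed integer seed; the whole simulation is reproducible given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 104,
                       template_weights = c(singleton = 0.30, nuclear = 0.45,
                                            three_gen = 0.17, extended = 0.08),
                       map = default_map(),
                       maf_spectrum = c(0.006, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                       h2 = 0.5, rho_g = 0.85, rho_e = 0.3,
                       qtl = NULL,
                       beta = c(age = 0.02, sex = 0.3, age_sex = 0),
                       trait_names = NULL,
                       seed = 1L) {
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  if (abs(rho_g) > 1 || abs(rho_e) > 1) stop("|rho_g|, |rho_e| must be <= 1")
  if (any(maf_spectrum <= 0 | maf_spectrum > 0.5))
    stop("maf_spectrum must lie in (0, 0.5]")
  if (!is.null(qtl)) {
    vf <- rep_len(qtl$varfrac, length(h2))
    if (any(h2 + vf > 1)) stop("h2 + qtl varfrac must be <= 1 per trait")
    if (qtl$maf <= 0 || qtl$maf > 0.5) stop("qtl maf must lie in (0, 0.5]")
  }
  if (n_families < 1) stop("n_families must be >= 1")
  if (is.null(trait_names))
    trait_names <- if (length(h2) == 2) c("trait_i", "trait_e") else "trait_i"
  structure(list(n_families = n_families,
                 template_weights = template_weights / sum(template_weights),
                 map = map, maf_spectrum = maf_spectrum, h2 = h2,
                 rho_g = rho_g, rho_e = rho_e, qtl = qtl, beta = beta,
                 trait_names = trait_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default two-chromosome 1 cM evaluation map
#' @param n_chrom number of chromosomes.
#' @param length_cM chromosome length in cM.
#' @param step_cM grid step in cM.
#' @export
default_map <- function(n_chrom = 2, length_cM = 100, step_cM = 1) {
  do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    data.frame(chrom = ch, cM = seq(0, length_cM, by = step_cM))
  }))
}

#' Simulate pedigree structures
#'
#' Draws family structures from the configured template mixture:
#' `singleton` (one founder), `nuclear` (couple + 1-4 children),
#' `three_gen` (grandparental couple, their children with in-marrying
#' spouses, and grandchildren) and `extended` (a wide three-generation
#' family, capped at 58 members). Pedigrees are non-inbred by construction.
#'
#' @param config a [sim_config()].
#' @return a [pedigree]; `summary()` reports the size distribution.
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- list()
  templates <- names(config$template_weights)
  draw <- sample(templates, config$n_families, replace = TRUE,
                 prob = config$template_weights)
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%03d", f)
    rows[[f]] <- switch(draw[f],
      singleton = .fam_singleton(fam),
      nuclear = .fam_nuclear(fam, nkids = sample(1:4, 1,
                                                 prob = c(.45, .3, .15, .1))),
      three_gen = .fam_three_gen(fam, nkids = sample(1:3, 1),
                                 gkids = function() sample(1:3, 1)),
      extended = .fam_three_gen(fam, nkids = sample(4:7, 1),
                                gkids = function() sample(3:7, 1),
                                cap = 58))
  }
  tab <- do.call(rbind, rows)
  pedigree(tab$fid, tab$id, tab$father, tab$mother, tab$sex)
}

.fam_singleton <- function(fam) {
  data.frame(fid = fam, id = "I01", father = "0", mother = "0",
             sex = sample(1:2, 1))
}

.fam_nuclear <- function(fam, nkids) {
  id <- sprintf("I%02d", seq_len(2 + nkids))
  data.frame(fid = fam, id = id,
             father = c("0", "0", rep(id[1], nkids)),
             mother = c("0", "0", rep(id[2], nkids)),
             sex = c(1, 2, sample(1:2, nkids, replace = TRUE)))
}

# grandparental couple -> nkids children, each with an in-marrying spouse
# and gkids() grandchildren; total size capped
.fam_three_gen <- function(fam, nkids, gkids, cap = Inf) {
  id <- c("I01", "I02"); father <- c("0", "0"); mother <- c("0", "0")
  sex <- c(1, 2); k <- 2
  for (c_i in seq_len(nkids)) {
    if (k + 2 > cap) break
    child <- sprintf("I%02d", k + 1); spouse <- sprintf("I%02d", k + 2)
    child_sex <- sample(1:2, 1)
    id <- c(id, child, spouse)
    father <- c(father, "I01", "0"); mother <- c(mother, "I02", "0")
    sex <- c(sex, child_sex, 3 - child_sex)
    k <- k + 2
    for (g in seq_len(gkids())) {
      if (k + 1 > cap) break
      gk <- sprintf("I%02d", k + 1)
      id <- c(id, gk)
      if (child_sex == 1) {
        father <- c(father, child); mother <- c(mother, spouse)
      } else {
        father <- c(father, spouse); mother <- c(mother, child)
      }
      sex <- c(sex, sample(1:2, 1))
      k <- k + 1
    }
  }
  data.frame(fid = fam, id = id, father = father, mother = mother, sex = sex)
}

#' Gene dropping through a pedigree
#'
#' Drops founder alleles through the pedigree at every map position.
#' Each founder carries two uniquely labelled alleles; each meiosis draws a
#' grandparental origin at the first locus of each chromosome and switches
#' between loci with the Haldane recombination fraction
#' `theta = (1 - exp(-2 d / 100)) / 2` for `d` cM. Founder allele labels are
#' then assigned allelic states by the per-locus minor-allele frequency,
#' giving 0/1/2 dosages.
#'
#' @param ped a [pedigree] (topologically ordered, as constructed).
#' @param config a [sim_config()]; uses `map`, `maf_spectrum`, and
#'   `seed + 1` for the transmission randomness.
#' @return list of class `descent_record`: `ids`, `key`, `fid`, `loci`
#'   (map data frame), `pat`/`mat` (n x L founder-allele label matrices),
#'   `maf` (per-locus frequency used), `dosage` (n x L minor-allele counts).
#' @export
gene_drop <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  map <- config$map
  L <- nrow(map)
  n <- nrow(ped)
  idx <- .ped_index(ped)

  # per-chromosome switch probabilities between adjacent loci
  newchrom <- c(TRUE, map$chrom[-1] != map$chrom[-L])
  d <- c(0, diff(map$cM)); d[newchrom] <- NA
  theta <- ifelse(newchrom, 0.5, 0.5 * (1 - exp(-2 * d / 100)))

  pat <- matrix(0L, n, L); mat <- matrix(0L, n, L)
  next_label <- 1L
  for (k in seq_len(n)) {
    if (is.na(idx$f[k])) {
      pat[k, ] <- next_label
      mat[k, ] <- next_label + 1L
      next_label <- next_label + 2L
    } else {
      pat[k, ] <- .meiosis(pat[idx$f[k], ], mat[idx$f[k], ], theta, newchrom)
      mat[k, ] <- .meiosis(pat[idx$m[k], ], mat[idx$m[k], ], theta, newchrom)
    }
  }

  maf <- rep_len(config$maf_spectrum, L)
  n_labels <- next_label - 1L
  # allelic state of each founder allele at each locus
  state <- matrix(stats::rbinom(n_labels * L, 1L, rep(maf, each = n_labels)),
                  n_labels, L)
  dosage <- matrix(state[cbind(as.vector(pat), rep(seq_len(L), each = n))],
                   n, L) +
            matrix(state[cbind(as.vector(mat), rep(seq_len(L), each = n))],
                   n, L)
  rownames(dosage) <- ped$key

  structure(list(ids = ped$id, key = ped$key, fid = ped$fid, loci = map,
                 pat = pat, mat = mat, maf = maf, dosage = dosage),
            class = "descent_record")
}

# one gamete: pick grandparental strand per locus with Haldane switching
.meiosis <- function(a1, a2, theta, newchrom) {
  L <- length(a1)
  u <- stats::runif(L)
  switchv <- u < theta
  # strand: cumulative XOR of switches, starting fresh on each chromosome
  strand <- integer(L)
  s <- 0L
  for (l in seq_len(L)) {
    if (newchrom[l]) s <- as.integer(u[l] < 0.5) else if (switchv[l]) s <- 1L - s
    strand[l] <- s
  }
  ifelse(strand == 0L, a1, a2)
}

#' Exact IBD-sharing matrix from descent ground truth
#'
#' For a locus on the gene-drop map, computes the proportion of alleles
#' shared identical-by-descent for every pair:
#' `pi_ij = (# of IBD allele pairs among the 4 cross-comparisons) / 2`,
#' exactly, from the founder-allele labels. Parent-offspring pairs are 1/2
#' at every locus; cross-family pairs are 0; the diagonal is 1 for
#' non-inbred individuals.
#'
#' @param rec a `descent_record` from [gene_drop()].
#' @param chrom,cM locus position; must be on `rec$loci`.
#' @return object of class `ibd_matrix`: list with `pi` (dense symmetric
#'   matrix), `ids`, `key`, `fid`, `locus`.
#' @export
ibd_from_descent <- function(rec, chrom, cM) {
  stopifnot(inherits(rec, "descent_record"))
  l <- which(rec$loci$chrom == chrom & rec$loci$cM == cM)
  if (length(l) != 1L) stop("locus not present in descent record: chrom ",
                            chrom, " at ", cM, " cM")
  p <- rec$pat[, l]; m <- rec$mat[, l]
  pi <- (outer(p, p, "==") + outer(p, m, "==") +
         outer(m, p, "==") + outer(m, m, "==")) / 2
  dimnames(pi) <- list(rec$key, rec$key)
  structure(list(pi = pi, ids = rec$ids, key = rec$key, fid = rec$fid,
                 locus = list(chrom = chrom, cM = cM)),
            class = "ibd_matrix")
}

#' Simulate phenotypes with known variance components
#'
#' Draws `y = X beta + a + q + e` per trait: additive genetic values
#' `a ~ MVN(0, 2 Phi sigma2_g)` family-by-family, an optional QTL
#' contribution `q = b * dosage` at the configured causal locus with `b`
#' scaled so the QTL explains its configured variance fraction, and
#' independent residuals. For two traits, genetic values have cross-trait
#' covariance `rho_g * sg1 * sg2 * 2 Phi` and residuals
#' `rho_e * se1 * se2 * I`. Age (Uniform 18-80) and sex (Bernoulli 1/2)
#' covariates are generated and their effects added according to
#' `config$beta`. Total variance per trait is 1 by construction
#' (before covariate effects).
#'
#' @param ped a [pedigree].
#' @param kin its [kinship_matrix()].
#' @param config a [sim_config()]; uses `seed + 2` for phenotype randomness.
#' @param descent optional `descent_record`, required when `config$qtl` is
#'   set (provides the causal-locus dosage).
#' @return data frame: `id`, `age`, `sex`, one column per trait. The true
#'   genetic values are attached as attribute `genetic_values` and the
#'   causal dosage (if any) as `qtl_dosage`.
#' @export
simulate_phenotypes <- function(ped, kin, config, descent = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(kin, "kinship_matrix"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(ped)
  nt <- length(config$h2)
  h2 <- config$h2
  vf <- if (is.null(config$qtl)) rep(0, nt)
        else rep_len(config$qtl$varfrac, nt)
  s2e <- 1 - h2 - vf
  if (any(s2e < 0)) stop("implied residual variance negative")

  Sg <- diag(sqrt(h2), nt) %*%
        (diag(1 - config$rho_g, nt) + config$rho_g) %*% diag(sqrt(h2), nt)
  Se <- diag(sqrt(s2e), nt) %*%
        (diag(1 - config$rho_e, nt) + config$rho_e) %*% diag(sqrt(s2e), nt)
  if (nt == 1) { Sg <- matrix(h2, 1, 1); Se <- matrix(s2e, 1, 1) }
  for (S in list(Sg, Se)) {
    if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop("implied trait covariance not positive semi-definite")
  }
  Lg <- chol(Sg + diag(1e-12, nt)); Le <- chol(Se + diag(1e-12, nt))

  a <- matrix(0, n, nt)
  for (fam in unique(ped$fid)) {
    rows <- which(ped$fid == fam)
    A <- 2 * kin$phi[rows, rows, drop = FALSE]
    Lf <- chol(A + diag(1e-10, length(rows)))
    Z <- matrix(stats::rnorm(length(rows) * nt), length(rows), nt)
    a[rows, ] <- crossprod(Lf, Z) %*% Lg
  }
  e <- matrix(stats::rnorm(n * nt), n, nt) %*% Le

  q <- matrix(0, n, nt)
  qd <- NULL
  if (!is.null(config$qtl)) {
    if (is.null(descent)) stop("a configured QTL requires a descent record")
    l <- which(descent$loci$chrom == config$qtl$chrom &
               descent$loci$cM == config$qtl$cM)
    if (length(l) != 1L) stop("qtl locus not on the gene-drop map")
    # redraw allelic states at the causal locus at the configured qtl maf
    set.seed(config$seed + 3L)
    labs <- sort(unique(c(descent$pat[, l], descent$mat[, l])))
    st <- stats::rbinom(max(labs), 1L, config$qtl$maf)
    qd <- st[descent$pat[, l]] + st[descent$mat[, l]]
    pq <- config$qtl$maf
    b <- sqrt(vf / (2 * pq * (1 - pq)))
    q <- outer(qd - 2 * pq, b)
  }

  age <- stats::runif(n, 18, 80)
  sex <- stats::rbinom(n, 1, 0.5)
  Xeff <- config$beta["age"] * (age - mean(age)) +
          config$beta["sex"] * sex +
          config$beta["age_sex"] * (age - mean(age)) * sex

  traits <- a + q + e + Xeff
  colnames(traits) <- config$trait_names
  out <- data.frame(id = ped$id, fid = ped$fid, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(traits))
  attr(out, "genetic_values") <- a
  attr(out, "qtl_dosage") <- qd
  out
}

#' One-call synthetic dataset
#'
#' Runs pedigree simulation, kinship, gene dropping and phenotype simulation
#' under one config. Bit-reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list: `ped`, `kin`, `descent`, `traits` plus the `config`.
#' @export
sim_dataset <- function(config) {
  ped <- simulate_pedigrees(config)
  kin <- kinship_matrix(ped)
  descent <- gene_drop(ped, config)
  traits <- simulate_phenotypes(ped, kin, config, descent = descent)
  list(ped = ped, kin = kin, descent = descent, traits = traits,
       config = config)
}

#' Read/write SNP dosage matrices as TSV
#'
#' Canonical layout: one row per SNP, columns `snp` then one per individual
#' id; values 0/1/2 or NA. The transposed layout (first column `id`, one
#' column per SNP) is auto-detected on read.
#'
#' @param dosage numeric matrix, SNPs in rows, individuals in columns.
#' @param path file path.
#' @export
write_dosages <- function(dosage, path) {
  out <- data.frame(snp = rownames(dosage), dosage, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  first <- names(tab)[1]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (tolower(first) == "id") m <- t(m)   # transposed layout
  storage.mode(m) <- "double"
  m
}

#' Read/write locus IBD matrices in long format
#'
#' Long-format TSV with columns `id1`, `id2`, `chrom`, `locus_cM`, `pihat`;
#' only within-family pairs with nonzero sharing (plus the diagonal) are
#' stored. Ids are family-qualified as `fid:id`.
#'
#' @param ibd an `ibd_matrix` or list of them.
#' @param path file path.
#' @export
write_ibd_long <- function(ibd, path) {
  if (inherits(ibd, "ibd_matrix")) ibd <- list(ibd)
  rows <- lapply(ibd, function(im) {
    ut <- which(upper.tri(im$pi, diag = TRUE) & im$pi != 0, arr.ind = TRUE)
    lab <- paste(im$fid, im$ids, sep = ":")
    data.frame(id1 = lab[ut[, 1]], id2 = lab[ut[, 2]],
               chrom = im$locus$chrom, locus_cM = im$locus$cM,
               pihat = im$pi[ut])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibd_long
#' @param ped the [pedigree] the matrices refer to (fixes id order).
#' @export
read_ibd_long <- function(path, ped) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lab <- paste(ped$fid, ped$id, sep = ":")
  out <- list()
  for (grp in split(tab, list(tab$chrom, tab$locus_cM), drop = TRUE)) {
    n <- nrow(ped)
    pi <- matrix(0, n, n, dimnames = list(ped$key, ped$key))
    i <- match(grp$id1, lab); j <- match(grp$id2, lab)
    if (anyNA(i) || anyNA(j)) stop("IBD file refers to unknown individuals")
    pi[cbind(i, j)] <- grp$pihat
    pi[cbind(j, i)] <- grp$pihat
    out[[length(out) + 1L]] <- structure(
      list(pi = pi, ids = ped$id, key = ped$key, fid = ped$fid,
           locus = list(chrom = grp$chrom[1], cM = grp$locus_cM[1])),
      class = "ibd_matrix")
  }
  out
}
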