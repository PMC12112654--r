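#' Compare bivariate and univariate LOD curves position by position
#'
#' Joins curves on their shared (chrom, cM) grid and flags positions where
#' the bivariate LOD-equivalent strictly exceeds both univariate LODs —
#' the operational definition of an improvement in QTL localization from
#' pairing the index trait with an endophenotype. A bivariate peak driven
#' by one trait alone (one univariate LOD at least as high) is not flagged.
#'
#' @param uni_curves list of two univariate `lod_curve`s.
#' @param biv_curve bivariate `lod_curve` (LOD-equivalent scale).
#' @return data frame: `chrom`, `cM`, `lod_biv`, `lod_uni1`, `lod_uni2`,
#'   `improved`.
#' @export
compare_bivariate_gain <- function(uni_curves, biv_curve) {
  stopifnot(length(uni_curves) == 2)
  key <- function(cv) paste(cv$chrom, cv$cM)
  k0 <- key(biv_curve)
  for (u in uni_curves) {
    if (!all(k0 %in% key(u)))
      stop("curves do not share a common (chrom, cM) grid")
  }
  u1 <- uni_curves[[1]][match(k0, key(uni_curves[[1]])), ]
  u2 <- uni_curves[[2]][match(k0, key(uni_curves[[2]])), ]
  data.frame(chrom = biv_curve$chrom, cM = biv_curve$cM,
             lod_biv = biv_curve$lod, lod_uni1 = u1$lod, lod_uni2 = u2$lod,
             improved = biv_curve$lod > u1$lod & biv_curve$lod > u2$lod)
}

#' Default pipeline configuration for a synthetic run
#'
#' A self-contained run configuration: simulate a family study with a
#' pleiotropic QTL affecting the index trait and one endophenotype, then
#' run transforms, heritability fits, ERV ranking, linkage scans and
#' targeted association. All thresholds default to the package-wide
#' conventions (LOD 2.87 / 1.67, marginal p 1e-4, region-wise Bonferroni at
#' family level 0.05, ERV significance floor 0.05).
#'
#' @param out_dir artifact directory.
#' @param seed integer seed driving every stochastic stage.
#' @param n_families,qtl_varfrac,h2,rho_g scale and signal of the simulated
#'   study.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(out_dir = tempfile("famerv_run_"), seed = 1L,
                               n_families = 104, qtl_varfrac = 0.2,
                               h2 = c(0.5, 0.45), rho_g = 0.85) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = list(n_families = n_families, h2 = h2, rho_g = rho_g,
                    rho_e = 0.2,
                    qtl = list(chrom = 1, cM = 40, varfrac = qtl_varfrac,
                               maf = 0.3)),
    index_trait = "trait_i",
    endophenotypes = c(trait_e = "classA"),
    transforms = c(trait_i = "none", trait_e = "none"),
    thresholds = list(significant = 2.87, suggestive = 1.67,
                      alpha_marginal = 1e-4, alpha_family = 0.05,
                      erv_floor = 0.05),
    scan = list(coarse_step = 5, fine_step = 1, refine_above = 0.5)
  ), class = "run_config")
}

#' Run the endophenotype-linkage pipeline end to end
#'
#' Stages, in order: simulate (or load) data; apply trait transforms; fit
#' univariate heritability for every trait; fit bivariate models of the
#' index trait against each candidate endophenotype and rank by ERV; run
#' univariate genome scans for the index trait and each class-winning
#' endophenotype; run bivariate scans for the winners; call peaks; run
#' targeted measured-genotype association over the -1-LOD support interval
#' of every significant or suggestive peak. Stage outputs are written as
#' TSV/JSON analogues of the standard report tables, and a manifest records
#' config hash, stage checksums, timings and warnings. With no
#' endophenotype passing the ERV floor the pipeline completes with
#' univariate outputs only and records an explicit notice.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @return the manifest (list), invisibly; artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("famerv")),
                   config_hash = .hash_obj(config), seed = config$seed,
                   stages = list(), warnings = character(0), notices = character(0))
  note <- function(msg) manifest$notices <<- c(manifest$notices, msg)
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 3))
    val
  }

  # --- data ------------------------------------------------------------
  dat <- stage("data", {
    scfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    sim_dataset(scfg)
  })
  write_pedigree(dat$ped, file.path(config$out_dir, "pedigree.fam"))
  write_traits(dat$traits, file.path(config$out_dir, "traits.tsv"))
  ibd_provider <- ibd_provider_from_descent(dat$descent)
  map <- dat$config$map

  # SNP panel from the gene-drop dosages (1 cM = 1 Mb naming convention);
  # the causal locus dosage replaces the panel column at its position
  snps <- data.frame(snp = sprintf("snp_%d_%g", map$chrom, map$cM),
                     chrom = map$chrom, pos = map$cM)
  dos <- t(dat$descent$dosage)
  rownames(dos) <- snps$snp
  qd <- attr(dat$traits, "qtl_dosage")
  if (!is.null(qd) && !is.null(dat$config$qtl)) {
    causal <- which(snps$chrom == dat$config$qtl$chrom &
                    snps$pos == dat$config$qtl$cM)
    dos[causal, ] <- qd
  }
  write_dosages(dos, file.path(config$out_dir, "dosages.tsv"))

  # --- transforms ------------------------------------------------------
  traits <- stage("transforms", apply_transforms(dat$traits, config$transforms))
  design <- design_from_traits(traits)
  trait_names <- c(config$index_trait, names(config$endophenotypes))

  # --- univariate heritability ----------------------------------------
  fits <- stage("heritability", {
    lapply(stats::setNames(trait_names, trait_names), function(tr) {
      polygenic_heritability(trait_vector(traits, tr), design, dat$kin)
    })
  })
  h2tab <- do.call(rbind, lapply(trait_names, function(tr) {
    f <- fits[[tr]]
    data.frame(trait = tr, n = f$n_used, h2 = f$h2, se = f$se_h2, p = f$p)
  }))
  utils::write.table(h2tab, file.path(config$out_dir, "table1_heritability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- ERV ranking -----------------------------------------------------
  sel <- stage("erv_ranking", {
    records <- do.call(rbind, lapply(names(config$endophenotypes), function(tr) {
      erv_record(trait_vector(traits, config$index_trait),
                 trait_vector(traits, tr), design, dat$kin,
                 endophenotype = tr, class = config$endophenotypes[[tr]])
    }))
    rank_endophenotypes(records, p_floor = config$thresholds$erv_floor)
  })
  write_erv_table(sel$ranking, file.path(config$out_dir, "table2_erv.tsv"))
  if (!nrow(sel$selected))
    note("no endophenotype passed the ERV significance floor; running univariate scans only")

  # --- univariate scans ------------------------------------------------
  scan_traits <- unique(c(config$index_trait, sel$selected$endophenotype))
  uni_curves <- stage("scan_univariate", {
    lapply(stats::setNames(scan_traits, scan_traits), function(tr) {
      tv <- trait_vector(traits, tr); attr(tv, "label") <- tr
      genome_scan(tv, design, dat$kin, ibd_provider, map,
                  coarse_step = config$scan$coarse_step,
                  fine_step = config$scan$fine_step,
                  refine_above = config$scan$refine_above)
    })
  })
  for (tr in names(uni_curves))
    write_lod_curve(uni_curves[[tr]],
                    file.path(config$out_dir, paste0("lod_uni_", tr, ".tsv")))

  # --- bivariate scans for class winners -------------------------------
  biv_curves <- stage("scan_bivariate", {
    lapply(stats::setNames(sel$selected$endophenotype,
                           sel$selected$endophenotype), function(tr) {
      ti <- trait_vector(traits, config$index_trait)
      te <- trait_vector(traits, tr)
      attr(ti, "label") <- config$index_trait; attr(te, "label") <- tr
      genome_scan(list(ti, te), design, dat$kin, ibd_provider, map,
                  coarse_step = config$scan$coarse_step,
                  fine_step = config$scan$fine_step,
                  refine_above = config$scan$refine_above)
    })
  })
  for (tr in names(biv_curves))
    write_lod_curve(biv_curves[[tr]],
                    file.path(config$out_dir, paste0("lod_biv_", tr, ".tsv")))

  # --- peaks + localization gain --------------------------------------
  peaks <- stage("peaks", {
    all <- list()
    for (tr in names(uni_curves)) {
      pk <- call_peaks(uni_curves[[tr]], config$thresholds$significant,
                       config$thresholds$suggestive)
      if (nrow(pk)) { pk$traits <- tr; all[[length(all) + 1]] <- pk }
    }
    for (tr in names(biv_curves)) {
      pk <- call_peaks(biv_curves[[tr]], config$thresholds$significant,
                       config$thresholds$suggestive)
      if (nrow(pk)) {
        pk$traits <- paste(config$index_trait, tr, sep = "+")
        all[[length(all) + 1]] <- pk
      }
    }
    if (length(all)) do.call(rbind, all) else NULL
  })
  if (!is.null(peaks)) {
    jsonlite::write_json(peaks, file.path(config$out_dir, "table34_peaks.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (tr in names(biv_curves)) {
      idx_curve <- uni_curves[[config$index_trait]]
      endo_curve <- uni_curves[[tr]]
      common <- intersect(paste(idx_curve$chrom, idx_curve$cM),
                          paste(endo_curve$chrom, endo_curve$cM))
      bv <- biv_curves[[tr]]
      bv <- bv[paste(bv$chrom, bv$cM) %in% common, ]
      gain <- compare_bivariate_gain(list(idx_curve, endo_curve), bv)
      utils::write.table(gain,
        file.path(config$out_dir, paste0("gain_", tr, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    note("no peaks reached the suggestive threshold; MGA stage skipped")
  }

  # --- targeted MGA under peaks ---------------------------------------
  if (!is.null(peaks) && nrow(peaks)) {
    mga_tabs <- stage("mga", {
      tabs <- list()
      for (k in seq_len(nrow(peaks))) {
        pk <- peaks[k, ]
        region <- list(chrom = pk$chrom, lo = pk$ci_lo, hi = pk$ci_hi)
        prs <- strsplit(pk$traits, "+", fixed = TRUE)[[1]]
        tv <- if (length(prs) == 2) {
          list(trait_vector(traits, prs[1]), trait_vector(traits, prs[2]))
        } else trait_vector(traits, prs)
        res <- region_scan(tv, design, dat$kin, dos, snps, region,
                           alpha_marginal = config$thresholds$alpha_marginal,
                           alpha_family = config$thresholds$alpha_family)
        res$traits <- pk$traits
        res$region <- sprintf("chr%s:%g-%g", pk$chrom, pk$ci_lo, pk$ci_hi)
        tabs[[length(tabs) + 1]] <- res
      }
      tabs
    })
    mga_all <- do.call(rbind, mga_tabs)
    utils::write.table(mga_all, file.path(config$out_dir, "table5_mga.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest$seconds_total <- round(proc.time()[3] - t_all, 3)
  arts <- list.files(config$out_dir, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(sort(arts)))
  names(manifest$checksums) <- basename(sort(arts))
  # timing varies between runs; checksums/config are the identity
  jsonlite::write_json(manifest[c("package_version", "config_hash", "seed",
                                  "checksums", "warnings", "notices")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.hash_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(x[setdiff(names(x), "out_dir")], file = tf)
  unname(tools::md5sum(tf))
}
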