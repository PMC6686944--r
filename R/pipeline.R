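## TSV writer with provenance header (version, seed, config hash)
writeStageTSV <- function(df, path, seed, cfg_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# aquaGS ",
                      as.character(utils::packageVersion("aquaGS"))),
               paste0("# seed ", seed),
               paste0("# config ", cfg_hash)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config, file = tf)
  unname(tools::md5sum(tf))
}

#' Run the genomic-evaluation pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate -> qc -> fit -> gwas -> panel -> impute -> evaluate -> cost`,
#' writing each stage's tables under `out_dir` with a provenance header
#' (package version, seed, config hash) and logging one line per stage.
#' A stage whose output files already exist is skipped and its outputs
#' re-read (logged as cached) unless `overwrite = TRUE`.
#'
#' The configuration is a nested list (or the path of a YAML file with
#' the same structure): `seed`; `out_dir`; `stages` (subset of the above);
#' `simulate` ([simulationConfig()] arguments) or `data` (paths
#' `pedigree`, `ped`, `map`, `phenotypes` of existing files); `qc`
#' (thresholds); `fit` (`trait`, `covariate`, `kinship` = "A" or "H");
#' `gwas` (`n_iterations`, `window_size`); `panel` (`sizes`); `impute`
#' (`panel_size`, `offspring_fraction`); `evaluate` (`n_folds`,
#' `n_replicates`); `cost` (`sizes`, `scenarios`).
#'
#' @param config nested configuration list, or a YAML file path.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stages_all <- c("simulate", "qc", "fit", "gwas", "panel", "impute",
                  "evaluate", "cost")
  stages <- if (is.null(config$stages)) stages_all
            else stages_all[stages_all %in% config$stages]
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  overwrite <- isTRUE(config$overwrite)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  hdr <- c(paste("aquaGS", as.character(utils::packageVersion("aquaGS"))),
           paste("seed", seed), paste("config", hash))
  log1 <- function(stage, msg)
    message(sprintf("[%s] %s (seed %d)", stage, msg, seed))

  ## -- config validation before any work
  if (!"simulate" %in% stages && is.null(config$data) &&
      any(c("qc", "fit", "gwas", "panel", "impute", "evaluate")
          %in% stages))
    stop("config error: analysis stages requested without 'simulate' ",
         "or 'data' inputs")
  if (!is.null(config$data)) {
    need <- c("pedigree", "ped", "map", "phenotypes")
    for (f in need[need %in% names(config$data)])
      if (!file.exists(config$data[[f]]))
        stop("config error: input file not found: ", config$data[[f]])
    if (any(c("qc", "gwas", "panel", "impute") %in% stages) &&
        !all(c("ped", "map") %in% names(config$data)))
      stop("config error: genomic stage requested without genotype files")
  }
  res <- list(seed = seed, config_hash = hash)

  ## -- inputs: simulate or load
  if ("simulate" %in% stages) {
    sim_dir <- file.path(out_dir, "simulate")
    have <- all(file.exists(file.path(sim_dir,
      c("pedigree.csv", "genotypes.ped", "genotypes.map",
        "phenotypes.csv"))))
    if (have && !overwrite) {
      log1("simulate", "cached outputs reused")
      ped <- readPedigree(file.path(sim_dir, "pedigree.csv"))
      geno <- readPlink(file.path(sim_dir, "genotypes.ped"),
                        file.path(sim_dir, "genotypes.map"))
      phen <- readPhenotypes(file.path(sim_dir, "phenotypes.csv"))
      pop <- NULL
    } else {
      cfg <- do.call(simulationConfig,
                     c(config$simulate, list(seed = seed)))
      pop <- simulatePopulation(cfg)
      writeDataset(pop, sim_dir)
      log1("simulate", sprintf("%d animals, %d SNPs written",
                               length(pop@pedigree@id),
                               ncol(pop@genotypes@dosage)))
      ped <- pop@pedigree; geno <- pop@genotypes; phen <- pop@phenotypes
    }
    res$population <- pop
  } else if (!is.null(config$data)) {
    ped <- readPedigree(config$data$pedigree)
    geno <- if (!is.null(config$data$ped))
      readPlink(config$data$ped, config$data$map) else NULL
    phen <- readPhenotypes(config$data$phenotypes)
  }
  res$pedigree <- ped
  res$phenotypes <- phen

  ## genotyped cohort: last-generation offspring plus their parents
  gen_last <- max(ped@generation)
  off_ids <- ped@id[ped@generation == gen_last]
  par_ids <- unique(c(sireOf(ped)[off_ids], damOf(ped)[off_ids]))
  par_ids <- par_ids[par_ids != "0"]
  gids <- intersect(c(par_ids, off_ids), rownames(geno@dosage))

  if ("qc" %in% stages) {
    qc <- do.call(qcFilter, c(list(geno[gids, ]),
                              config$qc[names(config$qc) %in%
                                c("hwe_p_min", "maf_min",
                                  "call_rate_min")]))
    rep_df <- data.frame(filter = c("samples_callrate", "snp_callrate",
                                    "snp_maf", "snp_hwe", "snps_kept",
                                    "samples_kept"),
                         count = c(qc$report@removed,
                                   length(qc$report@kept_snps),
                                   length(qc$report@kept_samples)))
    writeStageTSV(rep_df, file.path(out_dir, "qc_report.tsv"), seed, hash)
    log1("qc", sprintf("%d SNPs, %d samples retained",
                       length(qc$report@kept_snps),
                       length(qc$report@kept_samples)))
    geno_qc <- qc$genotypes
    res$qc <- qc
  } else geno_qc <- if (!is.null(geno)) geno[gids, ] else NULL

  fit_cfg <- config$fit
  trait <- if (is.null(fit_cfg$trait)) "fy" else fit_cfg$trait
  covariate <- fit_cfg$covariate
  if ("fit" %in% stages || "gwas" %in% stages || "evaluate" %in% stages)
    Ainv <- makeAInverse(ped)

  if ("fit" %in% stages) {
    design <- mmeDesign(phen, trait, ped, covariate = covariate)
    kin <- if (is.null(fit_cfg$kinship)) "A" else fit_cfg$kinship
    if (kin == "H") {
      A22 <- makeA(ped, subset = rownames(geno_qc@dosage))
      G <- makeG(geno_qc, A22 = A22)
      Kinv <- makeHInverse(Ainv, solve(G), solve(A22))
      klab <- "H-inverse"
    } else {
      Kinv <- Ainv; klab <- "A-inverse"
    }
    vc <- remlVC(design, Kinv)
    fit <- solveMME(design, Kinv, vc, kinship = klab)
    writeStageTSV(data.frame(component = c("sigma2_a", "sigma2_c",
                                           "sigma2_e", "h2"),
                             estimate = c(vc@sigma2, heritability(vc)$h2),
                             se = c(vc@se, vc@h2_se)),
                  file.path(out_dir, "variance_components.tsv"),
                  seed, hash)
    writeStageTSV(data.frame(animal = names(fit@u), ebv = unname(fit@u)),
                  file.path(out_dir, paste0("ebv_", trait, ".tsv")),
                  seed, hash)
    log1("fit", sprintf("%s h2 = %.3f", trait, heritability(vc)$h2))
    res$vc <- vc; res$fit <- fit
  }

  if ("gwas" %in% stages) {
    gw <- runWssGBLUP(ped, geno_qc, phen, trait, covariate = covariate,
                      vc = res$vc,
                      n_iterations = if (is.null(config$gwas$n_iterations))
                        2L else config$gwas$n_iterations,
                      window_size = if (is.null(config$gwas$window_size))
                        20L else config$gwas$window_size)
    rep_it <- Find(function(x) x$reporting, gw)
    writeStageTSV(data.frame(snp = names(rep_it$snp_effects),
                             effect = unname(rep_it$snp_effects)),
                  file.path(out_dir, "snp_effects.tsv"), seed, hash)
    writeStageTSV(rep_it$windows, file.path(out_dir, "windows.tsv"),
                  seed, hash)
    log1("gwas", sprintf("top window %.2f%% of genetic variance",
                         max(rep_it$windows$pct_var)))
    res$gwas <- gw
  }

  if ("panel" %in% stages) {
    sizes <- if (is.null(config$panel$sizes)) c(500, 1000, 3000)
             else config$panel$sizes
    panels <- lapply(sizes, function(sz) selectLDPanel(geno_qc, sz))
    names(panels) <- paste0("LD", sizes)
    for (nm in names(panels))
      writeLines(panels[[nm]]$snps,
                 file.path(out_dir, paste0("panel_", nm, ".txt")))
    log1("panel", paste("achieved:",
                        paste(vapply(panels, `[[`, 0, "achieved"),
                              collapse = ", ")))
    res$panels <- panels
  }

  if ("impute" %in% stages) {
    psz <- if (is.null(config$impute$panel_size)) 500
           else config$impute$panel_size
    frac <- if (is.null(config$impute$offspring_fraction)) 0.20
            else config$impute$offspring_fraction
    panel <- if (!is.null(res$panels))
      res$panels[[paste0("LD", psz)]] else selectLDPanel(geno_qc, psz)
    g_off <- intersect(off_ids, rownames(geno_qc@dosage))
    g_par <- intersect(par_ids, rownames(geno_qc@dosage))
    sp <- splitReference(g_par, g_off, frac, seed = seed)
    imp <- imputeGenotypes(geno_qc[sp$reference, ],
                           geno_qc[sp$validation, panel$snps], ped)
    masked <- setdiff(colnames(geno_qc@dosage), panel$snps)
    acc <- imputationAccuracy(geno_qc[sp$validation, ], imp, masked)
    writePlink(imp, file.path(out_dir, "imputed"), header = hdr)
    writeStageTSV(acc$per_snp, file.path(out_dir, "imputation_accuracy.tsv"),
                  seed, hash)
    log1("impute", sprintf("mean per-SNP r = %.3f", acc$mean_r))
    res$imputation <- acc
  }

  if ("evaluate" %in% stages) {
    ev_cfg <- config$evaluate
    nf <- if (is.null(ev_cfg$n_folds)) 5L else ev_cfg$n_folds
    nr <- if (is.null(ev_cfg$n_replicates)) 5L else ev_cfg$n_replicates
    pool <- intersect(rownames(geno_qc@dosage),
                      phen$animal[!is.na(phen[[trait]])])
    pool <- intersect(pool, off_ids)
    folds <- makeCVFolds(pool, nf, nr, seed = seed)
    vc_ped <- res$vc
    if (is.null(vc_ped) || !identical(res$fit@kinship, "A-inverse")) {
      design <- mmeDesign(phen, trait, ped, covariate = covariate)
      vc_ped <- remlVC(design, Ainv)
    }
    h2p <- heritability(vc_ped)$h2
    pblup <- crossValidate(ped, phen, trait, folds, Ainv, vc = vc_ped,
                           h2_ped = h2p, covariate = covariate,
                           label = "PBLUP")
    A22 <- makeA(ped, subset = rownames(geno_qc@dosage))
    G <- makeG(geno_qc, A22 = A22)
    Hinv <- makeHInverse(Ainv, solve(G), solve(A22))
    ssg <- crossValidate(ped, phen, trait, folds, Hinv, vc = vc_ped,
                         h2_ped = h2p, covariate = covariate,
                         label = "ssGBLUP")
    tab <- data.frame(method = c("PBLUP", "ssGBLUP"),
                      mean_accuracy = c(pblup$mean_accuracy,
                                        ssg$mean_accuracy),
                      sd_accuracy = c(pblup$sd_accuracy, ssg$sd_accuracy),
                      relative_increase_pct = c(0,
                        relativeIncrease(ssg, pblup)))
    writeStageTSV(tab, file.path(out_dir, "prediction_accuracy.tsv"),
                  seed, hash)
    log1("evaluate", sprintf("PBLUP %.3f vs ssGBLUP %.3f",
                             pblup$mean_accuracy, ssg$mean_accuracy))
    res$evaluation <- list(pblup = pblup, ssgblup = ssg)
  }

  if ("cost" %in% stages) {
    sizes <- if (is.null(config$cost$sizes)) seq(4150, 10150, by = 1000)
             else config$cost$sizes
    scen <- if (is.null(config$cost$scenarios)) c("B", "C", "D")
            else setdiff(config$cost$scenarios, "A")
    tab <- costTable(sizes, scen)
    writeStageTSV(tab, file.path(out_dir, "cost_scenarios.tsv"), seed, hash)
    log1("cost", sprintf("scenario D reduction %.1f%% at n=%d",
                         max(tab$reduction_pct[tab$scenario == "D"],
                             -Inf),
                         min(sizes)))
    res$cost <- tab
  }
  invisible(res)
}
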