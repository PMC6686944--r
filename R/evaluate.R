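#' Cross-validation fold assignments
#'
#' Disjoint, exhaustive folds (sizes differing by at most one), replicated
#' with fresh random assignments; all methods compared on the same folds
#' share one scheme object.
#'
#' @param ids animals to fold (genotyped and phenotyped validation pool).
#' @param n_folds folds per replicate (default 5).
#' @param n_replicates replicates (default 5).
#' @param seed integer seed.
#' @return list of replicates, each a named integer vector mapping id ->
#'   fold.
#' @export
makeCVFolds <- function(ids, n_folds = 5L, n_replicates = 5L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_replicates), function(r) {
    f <- rep(seq_len(n_folds), length.out = length(ids))
    setNames(f[sample.int(length(ids))], ids)
  })
}

#' Cross-validated prediction accuracy
#'
#' For each fold the validation animals' phenotype records are removed,
#' the animal model is refit on the training records (non-genotyped
#' phenotyped animals always stay in training - the single-step property),
#' and the accuracy is `r((G)EBV, y) / h`, the correlation between the
#' predicted breeding values and the masked phenotypes divided by the
#' square root of the pedigree-based heritability.
#'
#' @param ped full [Pedigree-class].
#' @param phenotypes phenotype table (see [mmeDesign()]).
#' @param trait response column.
#' @param folds from [makeCVFolds()]; its ids define the validation pool.
#' @param Kinv relationship inverse for the evaluation ([makeAInverse()]
#'   for PBLUP, [makeHInverse()] for ssGBLUP).
#' @param vc variance components used in the mixed-model equations;
#'   estimated once on the full data by [remlVC()] with `Kinv` when
#'   `NULL`.
#' @param h2_ped pedigree-based heritability for the accuracy denominator;
#'   when `NULL` it is taken from `vc` (supply the pedigree-model value
#'   when evaluating genomic methods, so all methods share one `h`).
#' @param cg,covariate,common_env model structure, as in [mmeDesign()].
#' @param label method label stored in the result.
#' @return list with `label`, `h2_ped`, `per_fold` (data.frame: replicate,
#'   fold, n, r, accuracy), `mean_accuracy`, `sd_accuracy`, `mean_r`.
#' @export
crossValidate <- function(ped, phenotypes, trait, folds, Kinv, vc = NULL,
                          h2_ped = NULL, cg = "cg", covariate = NULL,
                          common_env = TRUE, label = "model") {
  phen <- phenotypes[!is.na(phenotypes[[trait]]), , drop = FALSE]
  pool <- names(folds[[1L]])
  if (!all(pool %in% phen$animal))
    stop("every fold animal needs a ", trait, " phenotype")
  if (is.null(vc)) {
    design_all <- mmeDesign(phen, trait, ped, cg = cg,
                            covariate = covariate, common_env = common_env)
    vc <- remlVC(design_all, Kinv)
  }
  if (is.null(h2_ped))
    h2_ped <- if (is(vc, "VarianceComponents")) heritability(vc)$h2
              else heritability(vc)$h2
  h <- sqrt(h2_ped)
  res <- list()
  for (r in seq_along(folds)) {
    fa <- folds[[r]]
    for (f in sort(unique(fa))) {
      val_ids <- names(fa)[fa == f]
      train <- phen[!(phen$animal %in% val_ids), , drop = FALSE]
      design <- mmeDesign(train, trait, ped, cg = cg,
                          covariate = covariate, common_env = common_env)
      fit <- solveMME(design, Kinv, vc, kinship = label)
      yv <- phen[[trait]][match(val_ids, phen$animal)]
      if (sd(yv) == 0) stop("zero phenotype variance in a fold")
      rr <- cor(fit@u[val_ids], yv)
      res[[length(res) + 1L]] <-
        data.frame(replicate = r, fold = f, n = length(val_ids),
                   r = rr, accuracy = rr / h)
    }
  }
  per_fold <- do.call(rbind, res)
  list(label = label, h2_ped = h2_ped, per_fold = per_fold,
       mean_accuracy = mean(per_fold$accuracy),
       sd_accuracy = sd(per_fold$accuracy),
       mean_r = mean(per_fold$r))
}

#' Relative increase in accuracy over PBLUP
#'
#' `100 * (acc_genomic - acc_pblup) / acc_pblup`.
#'
#' @param genomic,pblup accuracy results from [crossValidate()] (their
#'   `mean_accuracy` is used) or plain numbers.
#' @return percent increase (negative = decrease).
#' @examples
#' relativeIncrease(0.621, 0.539)  # ~ +15.2
#' @export
relativeIncrease <- function(genomic, pblup) {
  a <- if (is.list(genomic)) genomic$mean_accuracy else genomic
  b <- if (is.list(pblup)) pblup$mean_accuracy else pblup
  if (b == 0) stop("zero reference accuracy")
  100 * (a - b) / b
}

#' Genotyping price schedule
#'
#' Per-sample base prices for the high-density chip and the 3K/1K/0.5K
#' low-density panels, plus the high-density volume discount: the HD price
#' drops by `discount_rate` for each full `discount_step` samples beyond
#' `base_volume`.
#'
#' @param hd,ld3k,ld1k,ld05k per-sample prices (currency units).
#' @param discount_rate multiplicative discount per step (default 10%).
#' @param discount_step samples per discount step (default 1,000).
#' @param base_volume volume at which the base HD price applies
#'   (default 4,150).
#' @return a named list.
#' @export
priceSchedule <- function(hd = 50, ld3k = 25, ld1k = 20, ld05k = 10,
                          discount_rate = 0.10, discount_step = 1000,
                          base_volume = 4150) {
  if (any(c(hd, ld3k, ld1k, ld05k) <= 0)) stop("prices must be positive")
  list(hd = hd, ld3k = ld3k, ld1k = ld1k, ld05k = ld05k,
       discount_rate = discount_rate, discount_step = discount_step,
       base_volume = base_volume)
}

#' Volume-discounted high-density price per sample
#'
#' `hd * (1 - rate)^floor((n - base_volume)/step)` for `n` above the base
#' volume, else the base price.
#'
#' @param n_hd_samples HD samples counted toward the discount.
#' @param schedule a [priceSchedule()].
#' @return price per sample.
#' @examples
#' hdPrice(4150)   # 50
#' hdPrice(10150)  # 50 * 0.9^6 = 26.57
#' @export
hdPrice <- function(n_hd_samples, schedule = priceSchedule()) {
  if (n_hd_samples < 0) stop("negative sample count")
  if (n_hd_samples <= schedule$base_volume) return(schedule$hd)
  steps <- floor((n_hd_samples - schedule$base_volume) /
                   schedule$discount_step)
  schedule$hd * (1 - schedule$discount_rate)^steps
}

#' Cost of a genotyping scenario
#'
#' Scenario A genotypes parents, reference population (RP) and selection
#' candidates (SC) all at high density; scenarios B, C and D genotype all
#' parents plus 20% of RP at high density and the remaining animals with
#' the 3K, 1K or 0.5K panel respectively. The population splits evenly
#' into RP and SC; the parents (default 150: 100 females + 50 males) are
#' additional. The HD volume discount is keyed on the non-parent HD count
#' (the RP+SC volume convention); low-density prices are flat.
#'
#' @param scenario `"A"`, `"B"`, `"C"` or `"D"`.
#' @param total RP + SC animals (parents not included).
#' @param schedule a [priceSchedule()].
#' @param n_parents breeding parents, genotyped HD in every scenario.
#' @param hd_rp_fraction fraction of RP genotyped HD in scenarios B-D.
#' @return list: `scenario`, `total_cost`, `breakdown` (data.frame:
#'   stratum, n, price_per_sample, cost).
#' @examples
#' scenarioCost("A", 4150)$total_cost  # 4300 * 50 = 215000
#' @export
scenarioCost <- function(scenario, total, schedule = priceSchedule(),
                         n_parents = 150, hd_rp_fraction = 0.20) {
  scenario <- match.arg(scenario, c("A", "B", "C", "D"))
  if (total < 0 || n_parents < 0) stop("negative counts")
  rp <- total / 2
  if (scenario == "A") {
    price <- hdPrice(total, schedule)
    breakdown <- data.frame(stratum = "HD (P + RP + SC)",
                            n = n_parents + total,
                            price_per_sample = price,
                            cost = (n_parents + total) * price)
  } else {
    n_hd_off <- hd_rp_fraction * rp
    n_hd <- n_parents + n_hd_off
    n_ld <- total - n_hd_off
    hd_p <- hdPrice(n_hd_off, schedule)
    ld_p <- switch(scenario, B = schedule$ld3k, C = schedule$ld1k,
                   D = schedule$ld05k)
    breakdown <- data.frame(
      stratum = c("HD (P + 20% RP)", paste0("LD (", scenario, " panel)")),
      n = c(n_hd, n_ld),
      price_per_sample = c(hd_p, ld_p),
      cost = c(n_hd * hd_p, n_ld * ld_p))
  }
  list(scenario = scenario, total_cost = sum(breakdown$cost),
       breakdown = breakdown)
}

#' Cost reduction of a scenario relative to scenario A
#'
#' `100 * (cost_A - cost_X) / cost_A`; negative values mean the
#' low-density strategy costs more than genotyping everything at high
#' density.
#'
#' @param scenario_x,scenario_a results from [scenarioCost()] (or plain
#'   costs), computed on the same population size.
#' @return percent reduction.
#' @export
costReduction <- function(scenario_x, scenario_a) {
  cx <- if (is.list(scenario_x)) scenario_x$total_cost else scenario_x
  ca <- if (is.list(scenario_a)) scenario_a$total_cost else scenario_a
  if (ca == 0) stop("zero scenario-A cost")
  100 * (ca - cx) / ca
}

#' Cost-reduction table over population sizes
#'
#' @param sizes RP + SC totals (default the 4,150-10,150 range by 1,000).
#' @param scenarios scenario labels to evaluate against A.
#' @param schedule a [priceSchedule()].
#' @param ... passed to [scenarioCost()].
#' @return data.frame: size, scenario, total_cost, cost_A, reduction_pct.
#' @export
costTable <- function(sizes = seq(4150, 10150, by = 1000),
                      scenarios = c("B", "C", "D"),
                      schedule = priceSchedule(), ...) {
  do.call(rbind, lapply(sizes, function(sz) {
    a <- scenarioCost("A", sz, schedule, ...)
    do.call(rbind, lapply(scenarios, function(sc) {
      x <- scenarioCost(sc, sz, schedule, ...)
      data.frame(size = sz, scenario = sc, total_cost = x$total_cost,
                 cost_A = a$total_cost,
                 reduction_pct = costReduction(x, a))
    }))
  }))
}
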