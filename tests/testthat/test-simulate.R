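test_that("simulationConfig enforces the mating-design invariants", {
  expect_error(simulationConfig(n_sires = 50, n_dams = 80),
               "2 \\* n_sires")
  expect_error(simulationConfig(n_families = 101), "not enough matings")
  expect_error(simulationConfig(h2_target = c(fy = 0.6, hw = 0.36),
                                c2_target = c(fy = 0.5, hw = 0.068)),
               "h2_target \\+ c2_target")
  expect_error(simulationConfig(n_qtl = 6000), "n_qtl")
  expect_error(simulationConfig(
    offspring_per_family = list(mean = 3, sd = 1, min = 5, max = 49)),
    "min <= mean <= max")
  expect_error(simulationConfig(n_snps = 10, n_qtl = 5),
               "per chromosome")
})

test_that("the nested mating design uses 2 dams per sire", {
  cfg <- simulationConfig(n_generations = 1, seed = 21,
                          n_snps = 44, n_qtl = 10)
  ped <- simulatePedigree(cfg)
  off <- ped@id[ped@generation == 1]
  sires <- unique(sireOf(ped)[off])
  dams <- unique(damOf(ped)[off])
  expect_length(sires, 40)   # 80 families / 2 dams per sire
  expect_length(dams, 80)
  ## every sire mated to exactly two dams
  pairs <- unique(paste(sireOf(ped)[off], damOf(ped)[off]))
  expect_length(pairs, 80)
  per_sire <- table(sub(" .*", "", pairs))
  expect_true(all(per_sire == 2))
})

test_that("family sizes respect the truncated-normal bounds", {
  cfg <- simulationConfig(n_generations = 1, n_families = 74, seed = 5,
                          n_snps = 44, n_qtl = 10)
  ped <- simulatePedigree(cfg)
  off <- ped@id[ped@generation == 1]
  sizes <- table(paste(sireOf(ped)[off], damOf(ped)[off]))
  expect_length(sizes, 74)
  expect_true(all(sizes >= 5 & sizes <= 49))
  expect_equal(mean(sizes), 18, tolerance = 0.15)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- simulationConfig(n_generations = 1, n_sires = 4, n_dams = 8,
                          n_families = 6, n_snps = 60, n_qtl = 12,
                          n_chromosomes = 2,
                          chromosome_lengths_bp = c(3e7, 2e7),
                          burnin_generations = 10, base_size = 30,
                          seed = 77)
  p1 <- simulatePopulation(cfg)
  p2 <- simulatePopulation(cfg)
  expect_identical(animalIds(p1@pedigree), animalIds(p2@pedigree))
  expect_identical(dosages(p1@genotypes), dosages(p2@genotypes))
  expect_identical(p1@phenotypes, p2@phenotypes)
})

test_that("gene dropping is Mendelian-consistent", {
  pop <- small_pop()
  ped <- pop@pedigree
  D <- dosages(pop@genotypes)
  off <- ped@id[ped@generation == 1]
  S <- D[sireOf(ped)[off], , drop = FALSE]
  M <- D[damOf(ped)[off], , drop = FALSE]
  O <- D[off, , drop = FALSE]
  ## parents both 0 force offspring 0; both 2 force 2
  expect_true(all(O[S == 0 & M == 0] == 0))
  expect_true(all(O[S == 2 & M == 2] == 2))
  ## a parent's minimum possible contribution is respected
  expect_true(all(O >= (S == 2) + (M == 2)))
  expect_true(all(O <= 2 - (S == 0) - (M == 0)))
})

test_that("offspring dosage regresses on the parent with slope one half", {
  ## each parent transmits one of its two alleles per locus, so the
  ## regression of offspring dosage on parent dosage has slope 1/2
  pop <- mid_pop()
  ped <- pop@pedigree
  D <- dosages(pop@genotypes)
  off <- ped@id[ped@generation == 1]
  s <- sireOf(ped)[off]
  sl <- vapply(seq_len(ncol(D)), function(j) {
    x <- D[s, j]; y <- D[off, j]
    if (sd(x) == 0) return(NA_real_)
    cov(x, y) / var(x)
  }, numeric(1))
  expect_equal(mean(sl, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("burn-in generates LD that decays with distance", {
  pop <- small_pop()
  map <- snpMap(pop@genotypes)
  D <- dosages(pop@genotypes)
  r2_adj <- c(); r2_far <- c()
  for (cc in unique(map$chr)) {
    j <- which(map$chr == cc)
    poly <- j[apply(D[, j, drop = FALSE], 2, sd) > 0]
    for (k in seq_len(length(poly) - 1L)) {
      r2 <- cor(D[, poly[k]], D[, poly[k + 1L]])^2
      r2_adj <- c(r2_adj, r2)
    }
    far <- which(outer(map$pos[poly], map$pos[poly], function(a, b)
      abs(a - b)) > 1e7, arr.ind = TRUE)
    far <- far[far[, 1] < far[, 2], , drop = FALSE]
    if (nrow(far) > 50) far <- far[seq(1, nrow(far), length.out = 50), ]
    for (r in seq_len(nrow(far)))
      r2_far <- c(r2_far, cor(D[, poly[far[r, 1]]],
                              D[, poly[far[r, 2]]])^2)
  }
  expect_gt(mean(r2_adj), mean(r2_far))
})

test_that("phenotype variance budget matches the configured targets", {
  pop <- small_pop()
  for (tr in c("fy", "hw")) {
    real <- pop@params$realized[[tr]]
    tgt <- pop@config$h2_target[[tr]]
    ## the additive variance is rescaled to its target exactly; the ratio
    ## then moves only through the sampled c and e draws (8 families in
    ## this fixture, so the c share is noisy)
    expect_equal(real$var_a, real$sigma2[["a"]], tolerance = 1e-8)
    expect_lt(abs(real$h2 - tgt), 0.08)
    expect_equal(real$var_a + real$var_c + real$var_e,
                 pop@config$trait_sds[[tr]]^2, tolerance = 0.35)
  }
  ## full sibs share one common-environment value by construction:
  ## phenotype minus fixed, additive and residual parts is constant per
  ## family; verified through the realized c variance being positive
  expect_gt(pop@params$realized$hw$var_c, 0)
})

test_that("founders fixed for an allele force descendant dosage", {
  ## all founder haplotypes carry allele 1 at a SNP -> every animal is 2
  pop <- small_pop()
  ped <- pop@pedigree
  D <- dosages(pop@genotypes)
  founders <- ped@id[ped@generation == 0]
  fixed <- which(apply(D[founders, , drop = FALSE], 2,
                       function(x) all(x == 2)))
  if (length(fixed))
    expect_true(all(D[, fixed] == 2))
  ## and the haplotype bookkeeping matches the dosage matrix
  hap <- attr(pop@genotypes, "haplotypes")
  expect_equal(hap$paternal + hap$maternal, D, ignore_attr = TRUE)
})
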