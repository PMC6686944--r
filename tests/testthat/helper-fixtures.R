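## Shared fixtures, built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

## textbook 5-animal pedigree: founders 1,2; full sibs 3,4; 5 = 3 x 4
toy_ped <- function() {
  pedigree(id = c("1", "2", "3", "4", "5"),
           sire = c("0", "0", "1", "1", "3"),
           dam = c("0", "0", "2", "2", "4"))
}

## random non-inbred-free pedigree for inverse checks
random_ped <- function(n = 80, n_founders = 20, seed = 42) {
  set.seed(seed)
  id <- as.character(seq_len(n))
  sire <- dam <- rep("0", n)
  for (k in (n_founders + 1):n) {
    pr <- sample(seq_len(k - 1L), 2L)
    sire[k] <- id[pr[1L]]
    dam[k] <- id[pr[2L]]
  }
  pedigree(id, sire, dam)
}

## small simulated population: 1 offspring generation, 8 families,
## 200 SNPs on 4 chromosomes (fast; shared by many tests)
small_pop <- function() {
  memo_fixture("small_pop", function() {
    cfg <- simulationConfig(
      n_generations = 1, n_sires = 5, n_dams = 10, n_families = 8,
      offspring_per_family = list(mean = 14, sd = 4, min = 6, max = 25),
      n_snps = 200, n_qtl = 60, n_chromosomes = 4,
      chromosome_lengths_bp = c(5e7, 4e7, 3e7, 2e7),
      burnin_generations = 25, base_size = 50, seed = 3)
    simulatePopulation(cfg, keep_haplotypes = TRUE)
  })
}

## genotyped cohort of the small population (offspring + parents), QC'd
small_geno <- function() {
  memo_fixture("small_geno", function() {
    pop <- small_pop()
    qcFilter(pop@genotypes, maf_min = 0.05)$genotypes
  })
}

## mid-size population for REML / CV / imputation property tests:
## 2 generations, 30 families x ~12 offspring
mid_pop <- function() {
  memo_fixture("mid_pop", function() {
    cfg <- simulationConfig(
      n_generations = 2, n_sires = 20, n_dams = 40, n_families = 30,
      offspring_per_family = list(mean = 12, sd = 4, min = 5, max = 25),
      n_snps = 600, n_qtl = 200, n_chromosomes = 6,
      chromosome_lengths_bp = rep(4e7, 6),
      burnin_generations = 40, base_size = 80, seed = 11)
    simulatePopulation(cfg)
  })
}
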