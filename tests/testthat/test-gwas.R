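test_that("SNP effects are a linear map of the breeding values", {
  pop <- small_pop()
  ped <- pop@pedigree
  gids <- ped@id[ped@generation == 1]
  g <- small_geno()[gids, ]
  A22 <- makeA(ped, subset = gids)
  zero <- setNames(rep(0, length(gids)), gids)
  expect_true(all(backsolveSnpEffects(zero, g, A22 = A22) == 0))
  set.seed(4)
  a <- setNames(rnorm(length(gids)), gids)
  u1 <- backsolveSnpEffects(a, g, A22 = A22)
  u2 <- backsolveSnpEffects(2 * a, g, A22 = A22)
  expect_equal(u2, 2 * u1, tolerance = 1e-10)
})

test_that("unit-weight back-solving matches the dense ridge identity", {
  ## without blending the effects satisfy M u = a exactly for breeding
  ## values in the row space of the genomic matrix
  pop <- small_pop()
  ped <- pop@pedigree
  gids <- ped@id[ped@generation == 1]
  g <- small_geno()[gids, ]
  D <- dosages(g)
  p <- colMeans(D) / 2
  Z <- sweep(D, 2, 2 * p)
  set.seed(14)
  a <- setNames(drop(Z %*% rnorm(ncol(Z))), gids)
  u <- backsolveSnpEffects(a, g, blend = 0)
  expect_lt(max(abs(drop(Z %*% u) - a)), 1e-8)
})

test_that("weight updates follow the marker-variance rule", {
  set.seed(6)
  u <- rnorm(50)
  p <- runif(50, 0.05, 0.95)
  w <- updateSnpWeights(u, p)
  expect_equal(sum(w), 50)
  expect_equal(order(w), order(u^2 * 2 * p * (1 - p)))
  ## zero effects give zero weight before normalization
  u0 <- u; u0[7] <- 0
  expect_equal(unname(updateSnpWeights(u0, p)[7]), 0)
  ## symmetric inputs give unit weights
  expect_equal(unname(updateSnpWeights(rep(2, 10), rep(0.3, 10))),
               rep(1, 10))
  expect_warning(updateSnpWeights(rep(0, 5), rep(0.5, 5)), "zero")
  expect_error(updateSnpWeights(u, p - 1), "frequencies")
})

test_that("windows partition each chromosome with a short tail", {
  ## 105 SNPs on one chromosome, window 20 -> 6 windows, last of size 5
  d <- matrix(rbinom(12 * 105, 2, 0.5), 12, 105,
              dimnames = list(paste0("a", 1:12), paste0("s", 1:105)))
  g <- genotypeData(d, data.frame(snp = paste0("s", 1:105), chr = "1",
                                  pos = seq_len(105) * 1e4))
  set.seed(2)
  u <- rnorm(105)
  win <- windowVariance(u, g, window_size = 20)
  expect_equal(nrow(win), 6)
  expect_equal(win$n_snps, c(rep(20, 5), 5))
  ## one window holding everything explains 100%
  w1 <- windowVariance(u, g, window_size = 200)
  expect_equal(w1$pct_var, 100)
  ## percentages are invariant to rescaling the effects
  win2 <- windowVariance(10 * u, g, window_size = 20)
  expect_equal(win2$pct_var, win$pct_var, tolerance = 1e-10)
})

test_that("window percentages sum to about 100 under linkage equilibrium", {
  set.seed(31)
  n <- 400; m <- 120
  d <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.8), each = n)), n, m,
              dimnames = list(paste0("a", 1:n), paste0("s", 1:m)))
  g <- genotypeData(d, data.frame(snp = paste0("s", 1:m),
                                  chr = rep(c("1", "2"), each = m / 2),
                                  pos = rep(seq_len(m / 2) * 1e5, 2)))
  u <- rnorm(m)
  win <- windowVariance(u, g, window_size = 20)
  expect_equal(sum(win$pct_var), 100, tolerance = 8)
  ## the independent-SNP variant sums to 100 even more tightly here
  win2 <- windowVariance(u, g, window_size = 20, method = "sum")
  expect_equal(sum(win2$pct_var), 100, tolerance = 8)
})

test_that("iteration one of wssGBLUP is plain ssGBLUP", {
  pop <- small_pop()
  ped <- pop@pedigree
  gids <- ped@id[ped@generation == 1]
  g <- small_geno()[gids, ]
  phen <- pop@phenotypes
  vc <- c(a = 1, c = 0.2, e = 3.3)
  gw <- runWssGBLUP(ped, g, phen, "fy", covariate = "fy_cov", vc = vc,
                    n_iterations = 2)
  expect_true(all(gw[[1]]$weights == 1))
  A22 <- makeA(ped, subset = gids)
  G <- makeG(g, A22 = A22)
  Hinv <- makeHInverse(makeAInverse(ped), solve(G), solve(A22), gids)
  design <- mmeDesign(phen, "fy", ped, covariate = "fy_cov")
  fit <- solveMME(design, Hinv, vc, kinship = "H-inverse")
  expect_equal(gw[[1]]$fit@u, fit@u, tolerance = 1e-9)
  ## a single iteration returns the ssGBLUP result and reports it
  gw1 <- runWssGBLUP(ped, g, phen, "fy", covariate = "fy_cov", vc = vc,
                     n_iterations = 1)
  expect_equal(gw1[[1]]$fit@u, fit@u, tolerance = 1e-9)
  expect_true(gw1[[1]]$reporting)
  ## iteration 2 is the reporting default with updated weights
  expect_true(gw[[2]]$reporting)
  expect_equal(sum(gw[[2]]$weights), ncol(dosages(g)))
  ## windows and effects exist per iteration
  expect_equal(nrow(gw[[2]]$windows),
               sum(ceiling(table(snpMap(g)$chr) / 20)))
})

test_that("top windows are ordered by percent then genomic position", {
  win <- data.frame(chr = c("2", "1", "1"), first_bp = c(5, 9, 1),
                    last_bp = c(6, 10, 2), n_snps = 2, length_bp = 1,
                    pct_var = c(5, 5, 7),
                    first_snp = "x", last_snp = "y")
  top <- topWindows(win, 2)
  expect_equal(top$pct_var, c(7, 5))
  ## tie at 5: genomic order prefers chromosome 2 listed first in the map
  expect_equal(top$chr[2], "2")
})
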