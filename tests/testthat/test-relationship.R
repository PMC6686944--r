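test_that("makeG with unit weights matches the dense VanRaden formula", {
  set.seed(8)
  d <- matrix(rbinom(10 * 20, 2, runif(20, 0.2, 0.8)), 10, 20,
              byrow = TRUE,
              dimnames = list(paste0("a", 1:10), paste0("s", 1:20)))
  g <- genotypeData(d, data.frame(snp = paste0("s", 1:20), chr = "1",
                                  pos = 1:20 * 1000))
  G <- makeG(g)   # no A22: raw VanRaden
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  G_or <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  expect_lt(max(abs(G - G_or)), 1e-10)
})

test_that("identical genotypes give off-diagonal equal to the diagonal", {
  set.seed(9)
  d <- matrix(rbinom(6 * 30, 2, 0.5), 6, 30,
              dimnames = list(paste0("a", 1:6), paste0("s", 1:30)))
  d[2, ] <- d[1, ]
  g <- genotypeData(d, data.frame(snp = paste0("s", 1:30), chr = "1",
                                  pos = 1:30 * 500))
  G <- makeG(g)
  expect_equal(G["a1", "a2"], G["a1", "a1"])
  expect_equal(G["a1", "a2"], G["a2", "a2"])
})

test_that("tuning matches G means to A22 and blending keeps them", {
  pop <- small_pop()
  ped <- pop@pedigree
  gids <- ped@id[ped@generation == 1][1:50]
  g <- small_geno()[gids, ]
  A22 <- makeA(ped, subset = gids)
  G <- makeG(g, A22 = A22)
  expect_equal(mean(diag(G)), mean(diag(A22)), tolerance = 1e-6)
  off <- !diag(length(gids))
  expect_equal(mean(G[off]), mean(A22[off]), tolerance = 1e-6)
  ## blend weight 0 with tune off reproduces the raw VanRaden matrix
  G_raw <- makeG(g)
  G0 <- makeG(g, A22 = A22, blend = 0, tune = FALSE)
  expect_equal(G0, G_raw, ignore_attr = TRUE)
  ## blended G is positive definite (invertible)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("an all-monomorphic panel is rejected", {
  d <- matrix(2, 4, 3, dimnames = list(paste0("a", 1:4), paste0("s", 1:3)))
  g <- genotypeData(d, data.frame(snp = paste0("s", 1:3), chr = "1",
                                  pos = 1:3 * 100))
  expect_error(makeG(g), "monomorphic")
})

test_that("H inverse collapses to A inverse in the degenerate cases", {
  pop <- small_pop()
  ped <- pop@pedigree
  Ainv <- makeAInverse(ped)
  ## no genotyped animals
  H0 <- makeHInverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0), character(0))
  expect_equal(as.matrix(H0), as.matrix(Ainv), ignore_attr = TRUE)
  ## G identical to A22: the correction cancels exactly
  gids <- ped@id[ped@generation == 1][1:30]
  A22 <- makeA(ped, subset = gids)
  H1 <- makeHInverse(Ainv, solve(A22), solve(A22), gids)
  expect_lt(max(abs(as.matrix(H1) - as.matrix(Ainv))), 1e-10)
  ## dimension mismatch is caught
  expect_error(makeHInverse(Ainv, solve(A22), diag(3), gids), "mismatch")
})

test_that("ssGBLUP with every animal genotyped equals GBLUP", {
  ## when all pedigree animals are genotyped, A = A22 so H^-1 = G^-1
  pop <- small_pop()
  ped <- pop@pedigree
  g <- small_geno()
  A <- makeA(ped)
  Ainv <- makeAInverse(ped)
  G <- makeG(g[animalIds(ped), ], A22 = A)
  Hinv <- makeHInverse(Ainv, solve(G), solve(A), animalIds(ped))
  design <- mmeDesign(pop@phenotypes, "fy", ped, covariate = "fy_cov")
  vc <- c(a = 1, c = 0.2, e = 3.3)
  fit_h <- solveMME(design, Hinv, vc, kinship = "H-inverse")
  fit_g <- solveMME(design, solve(G), vc, kinship = "G-inverse")
  expect_equal(fit_h@u, fit_g@u, tolerance = 1e-6)
  expect_equal(fit_h@beta, fit_g@beta, tolerance = 1e-6)
})
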