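test_that("design matrices have the documented structure", {
  pop <- small_pop()
  ped <- pop@pedigree
  phen <- pop@phenotypes
  design <- mmeDesign(phen, "fy", ped, covariate = "fy_cov")
  n <- nrow(phen)
  ## intercept + (levels - 1) CG dummies + 1 centered covariate
  n_cg <- length(unique(phen$cg))
  expect_equal(ncol(design$X), n_cg + 1)
  expect_equal(qr(design$X)$rank, ncol(design$X))
  expect_equal(abs(sum(design$X[, ncol(design$X)])), 0, tolerance = 1e-9)
  ## Z carries every pedigree animal; founders have empty columns
  expect_equal(dim(design$Z), c(n, length(animalIds(ped))))
  founders <- ped@id[ped@generation == 0]
  expect_true(all(Matrix::colSums(design$Z[, founders]) == 0))
  ## full sibs share a W column
  fam <- phen$family
  two_sibs <- which(fam == fam[1])[1:2]
  expect_equal(design$W[two_sibs[1], ], design$W[two_sibs[2], ])
  ## unknown animals are rejected
  bad <- phen; bad$animal[1] <- "ghost"
  expect_error(mmeDesign(bad, "fy", ped), "unknown animal")
})

test_that("a single record shrinks by heritability", {
  ## one animal, no fixed effects, no family effect: a_hat = h2 * y
  ped <- pedigree("a1", "0", "0")
  y <- 2.5
  design <- list(y = y,
                 X = matrix(numeric(0), 1, 0),
                 Z = Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                          dims = c(1, 1),
                                          dimnames = list(NULL, "a1")),
                 W = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                          x = numeric(0), dims = c(1, 0)),
                 record_animal = "a1", animal_ids = "a1",
                 family_ids = character(0))
  Kinv <- diag(1); dimnames(Kinv) <- list("a1", "a1")
  for (h2 in c(0.2, 0.36, 0.9)) {
    fit <- solveMME(design, Kinv, c(a = h2, e = 1 - h2))
    expect_equal(unname(fit@u["a1"]), h2 * y, tolerance = 1e-10)
  }
  ## vanishing additive variance drives every EBV to zero
  fit0 <- solveMME(design, Kinv, c(a = 1e-10, e = 1))
  expect_lt(abs(fit0@u["a1"]), 1e-8)
})

test_that("solveMME matches the dense generalized-least-squares oracle", {
  pop <- small_pop()
  ped <- pop@pedigree
  phen <- head(pop@phenotypes, 40)
  design <- mmeDesign(phen, "fy", ped, covariate = "fy_cov")
  A <- makeA(ped)
  Ainv <- makeAInverse(ped)
  vc <- c(a = 1.0, c = 0.2, e = 3.4)
  fit <- solveMME(design, Ainv, vc)
  expect_lt(fit@residual_norm, 1e-8)
  X <- design$X
  Z <- as.matrix(design$Z)
  W <- as.matrix(design$W)
  V <- vc["a"] * Z %*% A %*% t(Z) + vc["c"] * tcrossprod(W) +
    vc["e"] * diag(length(design$y))
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% design$y)
  resid <- design$y - X %*% bhat
  expect_equal(unname(fit@beta), unname(drop(bhat)), tolerance = 1e-8)
  expect_equal(unname(fit@u),
               unname(drop(vc["a"] * A %*% t(Z) %*% Vi %*% resid)),
               tolerance = 1e-8)
  expect_equal(unname(fit@cfam),
               unname(drop(vc["c"] * t(W) %*% Vi %*% resid)),
               tolerance = 1e-8)
})

test_that("REML score and likelihood match a dense projection oracle", {
  pop <- small_pop()
  ped <- pop@pedigree
  phen <- head(pop@phenotypes, 35)
  design <- mmeDesign(phen, "fy", ped, covariate = "fy_cov")
  A <- makeA(ped)
  Ainv <- makeAInverse(ped)
  Kg <- as(as(Ainv, "generalMatrix"), "CsparseMatrix")
  ldet <- as.numeric(Matrix::determinant(Ainv, TRUE)$modulus)
  X <- design$X; Z <- as.matrix(design$Z); W <- as.matrix(design$W)
  y <- design$y
  dense_ll <- function(s2a, s2c, s2e) {
    V <- s2a * Z %*% A %*% t(Z) + s2c * tcrossprod(W) +
      s2e * diag(length(y))
    Vi <- solve(V)
    XVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
    as.numeric(-0.5 * (determinant(V)$modulus +
                         determinant(XVX)$modulus + t(y) %*% P %*% y))
  }
  st <- aquaGS:::remlStep(design, Kg, ldet, 1.1, 0.25, 3.2)
  expect_equal(st$loglik, dense_ll(1.1, 0.25, 3.2), tolerance = 1e-8)
  eps <- 1e-5
  num <- c(a = (dense_ll(1.1 + eps, 0.25, 3.2) -
                  dense_ll(1.1 - eps, 0.25, 3.2)) / (2 * eps),
           c = (dense_ll(1.1, 0.25 + eps, 3.2) -
                  dense_ll(1.1, 0.25 - eps, 3.2)) / (2 * eps),
           e = (dense_ll(1.1, 0.25, 3.2 + eps) -
                  dense_ll(1.1, 0.25, 3.2 - eps)) / (2 * eps))
  expect_equal(st$score, num, tolerance = 1e-5)
})

test_that("REML converges on the small population", {
  pop <- small_pop()
  design <- mmeDesign(pop@phenotypes, "fy", pop@pedigree,
                      covariate = "fy_cov")
  Ainv <- makeAInverse(pop@pedigree)
  vc <- remlVC(design, Ainv)
  expect_true(vc@converged)
  expect_true(all(varComp(vc) > 0))
  ## the tiny common-environment component may sit on the boundary in a
  ## fixture this small; additive and residual must be well determined
  expect_true(all(is.finite(vc@se[c("a", "e")])))
  h <- heritability(vc)
  expect_gt(h$h2, 0); expect_lt(h$h2, 1)
  expect_true(is.finite(h$se))
})

test_that("heritability reproduces the printed Eq.-3 arithmetic", {
  ## fillet yield, pedigree model
  expect_equal(round(heritability(c(a = 0.972, c = 0.174, e = 3.498))$h2,
                     3), 0.209)
  ## harvest weight, genomic model
  expect_equal(round(heritability(c(a = 23161, c = 3823, e = 37345))$h2,
                     3), 0.360)
  ## all variance additive
  expect_equal(heritability(c(a = 1, c = 0, e = 0))$h2, 1)
  ## a ratio is scale invariant
  expect_equal(heritability(c(a = 2 * 0.972, c = 2 * 0.174,
                              e = 2 * 3.498))$h2,
               heritability(c(a = 0.972, c = 0.174, e = 3.498))$h2)
  expect_error(heritability(c(a = 0, c = 0, e = 0)), "zero total")
})

test_that("PBLUP and ssGBLUP coincide when nothing is genotyped", {
  pop <- small_pop()
  ped <- pop@pedigree
  Ainv <- makeAInverse(ped)
  Hinv <- makeHInverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0),
                       character(0))
  design <- mmeDesign(pop@phenotypes, "hw", ped, covariate = "hw_cov")
  vc <- c(a = 20000, c = 4000, e = 40000)
  fa <- solveMME(design, Ainv, vc)
  fh <- solveMME(design, Hinv, vc)
  expect_equal(fa@u, fh@u, tolerance = 1e-10)
})
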