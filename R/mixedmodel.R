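#' Build the animal-model design structures
#'
#' Assembles `y`, `X`, `Z`, `W` for the animal model
#' `y = Xb + Za + Wc + e`: `X` holds the contemporary-group factor
#' (intercept + treatment contrasts, i.e. a drop-first-level constraint)
#' and a centered covariate column; `Z` maps records to pedigree animals,
#' carrying non-phenotyped animals as extra columns (their equations enter
#' through the kinship inverse); `W` maps records to full-sib families so
#' full sibs share one common-environment level.
#'
#' @param phenotypes data.frame with columns `animal`, the trait, and the
#'   factor/covariate columns named below. Records with a missing trait
#'   value are dropped.
#' @param trait response column name.
#' @param ped a [Pedigree-class]; every record's animal must appear in it.
#' @param cg contemporary-group column name, or `NULL` for an
#'   intercept-only fixed part.
#' @param covariate covariate column name (centered before fitting), or
#'   `NULL`.
#' @param common_env fit the full-sib common-environment effect
#'   (column `family`, or derived from the pedigree when absent).
#' @return list with `y`, `X` (dense), `Z`, `W` (sparse), `record_animal`,
#'   `animal_ids`, `family_ids`.
#' @export
mmeDesign <- function(phenotypes, trait, ped, cg = "cg",
                      covariate = NULL, common_env = TRUE) {
  phen <- phenotypes[!is.na(phenotypes[[trait]]), , drop = FALSE]
  if (!nrow(phen)) stop("no records with a ", trait, " phenotype")
  if (!all(phen$animal %in% ped@id))
    stop("unknown animal id(s) in phenotype table: ",
         paste(head(setdiff(phen$animal, ped@id)), collapse = ", "))
  y <- phen[[trait]]
  n <- length(y)
  if (!is.null(cg)) {
    f <- factor(phen[[cg]])
    if (any(table(f) == 0L)) stop("empty contemporary-group level")
    X <- model.matrix(~f)
    colnames(X) <- sub("^f", paste0(cg, ":"), colnames(X))
  } else {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (!is.null(covariate)) {
    z <- phen[[covariate]]
    X <- cbind(X, matrix(z - mean(z), dimnames = list(NULL, covariate)))
  }
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(phen$animal, ped@id),
                            x = 1, dims = c(n, length(ped@id)),
                            dimnames = list(NULL, ped@id))
  if (common_env) {
    fam <- if ("family" %in% names(phen)) phen$family
           else unname(fullSibFamily(ped)[phen$animal])
    if (anyNA(fam)) stop("phenotyped animal without a full-sib family")
    fam_ids <- unique(fam)
    W <- Matrix::sparseMatrix(i = seq_len(n), j = match(fam, fam_ids),
                              x = 1, dims = c(n, length(fam_ids)),
                              dimnames = list(NULL, fam_ids))
  } else {
    fam_ids <- character(0)
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, 0L))
  }
  list(y = y, X = X, Z = Z, W = W, record_animal = phen$animal,
       animal_ids = ped@id, family_ids = fam_ids)
}

## Assemble the lambda-form MME coefficient matrix and right-hand side.
## Kinv must cover design$animal_ids (reordered by dimnames when present).
assembleMME <- function(design, Kinv, lambda_a, lambda_c) {
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Z <- design$Z; W <- design$W
  Kinv <- as(as(Kinv, "generalMatrix"), "CsparseMatrix")
  if (!is.null(rownames(Kinv)))
    Kinv <- Kinv[design$animal_ids, design$animal_ids]
  q_c <- ncol(W)
  top <- cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z),
               Matrix::crossprod(X, W))
  mid <- cbind(Matrix::crossprod(Z, X),
               Matrix::crossprod(Z) + lambda_a * Kinv,
               Matrix::crossprod(Z, W))
  C <- rbind(top, mid)
  if (q_c > 0L) {
    bot <- cbind(Matrix::crossprod(W, X), Matrix::crossprod(W, Z),
                 Matrix::crossprod(W) +
                   lambda_c * Matrix::Diagonal(q_c))
    C <- rbind(C, bot)
  }
  rhs <- c(as.numeric(Matrix::crossprod(X, design$y)),
           as.numeric(Matrix::crossprod(Z, design$y)),
           if (q_c > 0L) as.numeric(Matrix::crossprod(W, design$y)))
  list(C = Matrix::forceSymmetric(C), rhs = rhs,
       p = ncol(X), q_a = ncol(Z), q_c = q_c)
}

#' Solve Henderson's mixed-model equations
#'
#' Solves the animal model at fixed variance components, with variance
#' ratios `lambda_a = s2e/s2a` on the kinship-inverse block and
#' `lambda_c = s2e/s2c` on the family block. A sparse Cholesky
#' factorization is used; the relative residual of the solved system is
#' returned as a diagnostic (and must be below `1e-8`).
#'
#' @param design from [mmeDesign()].
#' @param Kinv relationship inverse over the pedigree animals
#'   ([makeAInverse()] for PBLUP, [makeHInverse()] for ssGBLUP), with id
#'   dimnames.
#' @param vc a [VarianceComponents-class] or named vector `c(a=, c=, e=)`
#'   of strictly positive variances (component `c` ignored when the design
#'   has no family block).
#' @param kinship label stored in the fit (`"A-inverse"`, `"H-inverse"`,
#'   ...).
#' @return a [MixedModelFit-class].
#' @export
solveMME <- function(design, Kinv, vc, kinship = "A-inverse") {
  s2 <- if (is(vc, "VarianceComponents")) vc@sigma2
        else c(a = vc[["a"]],
               c = if ("c" %in% names(vc)) vc[["c"]] else NA_real_,
               e = vc[["e"]])
  if (s2[["a"]] <= 0 || s2[["e"]] <= 0)
    stop("additive and residual variances must be strictly positive")
  q_c <- ncol(design$W)
  if (q_c > 0L && (is.na(s2[["c"]]) || s2[["c"]] <= 0))
    stop("common-environment variance must be strictly positive")
  lambda_a <- s2[["e"]] / s2[["a"]]
  lambda_c <- if (q_c > 0L) s2[["e"]] / s2[["c"]] else 0
  sys <- assembleMME(design, Kinv, lambda_a, lambda_c)
  sol <- tryCatch(as.numeric(Matrix::solve(sys$C, sys$rhs)),
                  error = function(e)
                    stop("singular mixed-model equations: ",
                         conditionMessage(e)))
  res <- as.numeric(sys$C %*% sol) - sys$rhs
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(sys$rhs^2)), 1e-300)
  p <- sys$p
  vcobj <- if (is(vc, "VarianceComponents")) vc else
    new("VarianceComponents",
        sigma2 = c(a = s2[["a"]],
                   c = if (q_c > 0L) s2[["c"]] else 0, e = s2[["e"]]),
        se = c(a = NA_real_, c = NA_real_, e = NA_real_),
        h2 = NA_real_, h2_se = NA_real_, converged = NA, n_iter = 0L,
        loglik = NA_real_, ai = matrix(numeric(0), 0, 0))
  new("MixedModelFit",
      beta = setNames(sol[seq_len(p)], colnames(design$X)),
      u = setNames(sol[p + seq_len(sys$q_a)], design$animal_ids),
      cfam = if (q_c > 0L)
        setNames(sol[p + sys$q_a + seq_len(q_c)], design$family_ids)
        else setNames(numeric(0), character(0)),
      kinship = kinship, vc = vcobj, residual_norm = rel)
}

## score, AI matrix and REML log-likelihood at the current components.
## Dense C inverse: intended for desk-scale systems.
remlStep <- function(design, Kinv_g, ldet_Kinv, s2a, s2c, s2e) {
  y <- design$y; n <- length(y)
  with_c <- ncol(design$W) > 0L
  sys <- assembleMME(design, Kinv_g, s2e / s2a,
                     if (with_c) s2e / s2c else 0)
  Cd <- as.matrix(sys$C)
  R <- chol(Cd)
  Cinv <- chol2inv(R)
  sol <- drop(Cinv %*% sys$rhs)
  p <- sys$p; q_a <- sys$q_a; q_c <- sys$q_c
  aidx <- p + seq_len(q_a)
  cidx <- p + q_a + seq_len(q_c)
  ahat <- sol[aidx]
  chat <- if (with_c) sol[cidx] else numeric(0)
  e <- y - drop(design$X %*% sol[seq_len(p)]) -
    as.numeric(design$Z %*% ahat) -
    (if (with_c) as.numeric(design$W %*% chat) else 0)
  Kt <- as(Kinv_g, "TsparseMatrix")
  Taa <- sum(Kt@x * Cinv[cbind(aidx[Kt@i + 1L], aidx[Kt@j + 1L])])
  Tcc <- if (with_c) sum(diag(Cinv)[cidx]) else 0
  aKa <- sum(ahat * as.numeric(Kinv_g %*% ahat))
  ## REML scores (first derivatives of log-likelihood)
  la <- s2e / s2a; lc <- if (with_c) s2e / s2c else 0
  sc_a <- -0.5 * ((q_a - la * Taa) / s2a - aKa / s2a^2)
  sc_c <- if (with_c)
    -0.5 * ((q_c - lc * Tcc) / s2c - sum(chat^2) / s2c^2) else NA_real_
  trP <- (n - p - q_a - q_c + la * Taa + lc * Tcc) / s2e
  sc_e <- -0.5 * (trP - sum(e^2) / s2e^2)
  ## average information via working variates f_i = dV/dtheta_i %*% Py
  f <- cbind(as.numeric(design$Z %*% ahat) / s2a,
             if (with_c) as.numeric(design$W %*% chat) / s2c,
             e / s2e)
  rhs_f <- rbind(crossprod(design$X, f),
                 as.matrix(Matrix::crossprod(design$Z, f)),
                 if (with_c) as.matrix(Matrix::crossprod(design$W, f)))
  sol_f <- Cinv %*% rhs_f
  fit_f <- design$X %*% sol_f[seq_len(p), , drop = FALSE] +
    as.matrix(design$Z %*% sol_f[aidx, , drop = FALSE]) +
    (if (with_c) as.matrix(design$W %*% sol_f[cidx, , drop = FALSE]) else 0)
  AI <- crossprod(f, f - as.matrix(fit_f)) / (2 * s2e)
  AI <- (AI + t(AI)) / 2
  comp <- if (with_c) c("a", "c", "e") else c("a", "e")
  dimnames(AI) <- list(comp, comp)
  yPy <- (sum(y^2) - sum(sol * sys$rhs)) / s2e
  ldetC <- 2 * sum(log(diag(R)))
  m2l <- ldetC - (p + q_a + q_c) * log(s2e) + n * log(s2e) +
    q_a * log(s2a) + (if (with_c) q_c * log(s2c) else 0) -
    ldet_Kinv + yPy
  ## EM updates (always positive; used as safeguarded fallback)
  em <- c(a = (aKa + s2e * Taa) / q_a,
          c = if (with_c) (sum(chat^2) + s2e * Tcc) / q_c else NA_real_,
          e = yPy * s2e / (n - p))
  list(score = c(a = sc_a, c = sc_c, e = sc_e), AI = AI, loglik = -0.5 * m2l,
       em = em, sol = sol, p = p, q_a = q_a, q_c = q_c)
}

#' REML variance components by average information
#'
#' Estimates the additive, common-environment and residual variances of
#' the animal model by AI-REML, with EM fallback steps whenever the AI
#' proposal leaves the parameter space. Standard errors come from the
#' inverse AI matrix at convergence; `h2 = s2a/(s2a+s2c+s2e)` and its
#' delta-method standard error are filled in. Convergence is declared when
#' the largest relative parameter change drops below `tol`.
#'
#' @param design from [mmeDesign()] (`>= 2` fixed-effect levels and
#'   families of size `>= 2` are needed for identifiability with the
#'   common-environment effect).
#' @param Kinv relationship inverse over the pedigree animals.
#' @param start optional named vector `c(a=, c=, e=)` of starting values;
#'   default splits the phenotypic variance 0.3/0.1/0.6.
#' @param max_iter,tol iteration cap (default 200) and relative-change
#'   tolerance (default `1e-8`).
#' @param verbose print the trajectory.
#' @return a [VarianceComponents-class] (with `converged = FALSE` and a
#'   warning if the cap is hit).
#' @export
remlVC <- function(design, Kinv, start = NULL, max_iter = 200L,
                   tol = 1e-8, verbose = FALSE) {
  with_c <- ncol(design$W) > 0L
  s2p <- var(design$y)
  th <- if (is.null(start)) c(a = 0.3, c = if (with_c) 0.1 else NA, e = 0.6) * s2p
        else c(a = start[["a"]], c = if (with_c) start[["c"]] else NA,
               e = start[["e"]])
  lower <- 1e-8 * s2p
  Kinv_g <- as(as(Kinv, "generalMatrix"), "CsparseMatrix")
  if (!is.null(rownames(Kinv_g)))
    Kinv_g <- Kinv_g[design$animal_ids, design$animal_ids]
  ldet_Kinv <- as.numeric(Matrix::determinant(Kinv_g, logarithm = TRUE)$modulus)
  act <- if (with_c) c("a", "c", "e") else c("a", "e")
  last_ll <- -Inf
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- remlStep(design, Kinv_g, ldet_Kinv, th[["a"]],
                   if (with_c) th[["c"]] else NA, th[["e"]])
    if (verbose)
      message(sprintf("it %d  logL %.6f  a %.5g c %.5g e %.5g", it,
                      st$loglik, th[["a"]],
                      if (with_c) th[["c"]] else NA, th[["e"]]))
    step <- tryCatch(solve(st$AI[act, act], st$score[act]),
                     error = function(e) NULL)
    prop <- NULL
    if (!is.null(step) && all(is.finite(step))) {
      ## damp the AI step (step-halving) while it leaves the parameter
      ## space; only fall back to EM when no damped step is admissible
      fac <- 1
      for (h in 1:12) {
        cand <- th
        cand[act] <- th[act] + fac * step
        if (all(cand[act] > lower)) { prop <- cand; break }
        fac <- fac / 2
      }
    }
    if (is.null(prop)) {
      prop <- th
      prop[act] <- pmax(st$em[act], lower)
    }
    ## boundary handling: a variance pushed to (near) zero with a
    ## negative score is pinned there and dropped from the update set
    pin <- act[act != "e" & prop[act] <= 1e-3 * s2p &
                 st$score[act] < 0]
    if (length(pin)) {
      prop[pin] <- lower
      act <- setdiff(act, pin)
    }
    delta <- max(abs(prop[act] - th[act]) / pmax(abs(th[act]), lower))
    th <- prop
    last_ll <- st$loglik
    if (delta < tol) break
  }
  converged <- delta < tol
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")
  ## SEs at the final iterate
  st <- remlStep(design, Kinv_g, ldet_Kinv, th[["a"]],
                 if (with_c) th[["c"]] else NA, th[["e"]])
  covm <- tryCatch(solve(st$AI[act, act]), error = function(e)
    matrix(NA_real_, length(act), length(act),
           dimnames = list(act, act)))
  se <- c(a = NA_real_, c = NA_real_, e = NA_real_)
  se[act] <- sqrt(pmax(diag(covm), 0))
  sigma2 <- c(a = th[["a"]], c = if (with_c) th[["c"]] else 0, e = th[["e"]])
  ai3 <- matrix(NA_real_, 3, 3, dimnames = list(c("a", "c", "e"),
                                                c("a", "c", "e")))
  ai3[act, act] <- st$AI[act, act]
  h <- heritabilityFromComponents(sigma2, covm, act)
  new("VarianceComponents", sigma2 = sigma2, se = se,
      h2 = h$h2, h2_se = h$se, converged = converged, n_iter = it,
      loglik = st$loglik, ai = ai3)
}

## delta-method h2 and SE from a component covariance over `act`
heritabilityFromComponents <- function(sigma2, covm = NULL, act = NULL) {
  tot <- sum(sigma2)
  if (tot <= 0) stop("zero total variance")
  h2 <- sigma2[["a"]] / tot
  se <- NA_real_
  if (!is.null(covm) && all(is.finite(covm))) {
    grad <- c(a = (tot - sigma2[["a"]]) / tot^2,
              c = -sigma2[["a"]] / tot^2,
              e = -sigma2[["a"]] / tot^2)[act]
    se <- sqrt(max(drop(t(grad) %*% covm %*% grad), 0))
  }
  list(h2 = unname(h2), se = unname(se))
}

#' Heritability from variance components
#'
#' `h2 = s2a / (s2a + s2c + s2e)`. For a [VarianceComponents-class] with
#' an AI matrix the delta-method standard error is propagated from the
#' inverse-AI covariance; for a plain named vector only the ratio is
#' returned.
#'
#' @param vc a [VarianceComponents-class] or named numeric vector with
#'   components `a`, `c`, `e` (all `>= 0`, positive sum).
#' @return list with `h2` and `se` (`NA` when no covariance is available).
#' @examples
#' heritability(c(a = 0.972, c = 0.174, e = 3.498))$h2  # 0.209...
#' @export
heritability <- function(vc) {
  if (is(vc, "VarianceComponents")) {
    if (any(vc@sigma2 < 0)) stop("negative variance component")
    act <- names(which(!is.na(vc@se)))
    if (length(act) && length(vc@ai) &&
        all(is.finite(vc@ai[act, act])))
      return(heritabilityFromComponents(vc@sigma2,
                                        solve(vc@ai[act, act]), act))
    return(heritabilityFromComponents(vc@sigma2))
  }
  s <- c(a = vc[["a"]], c = if ("c" %in% names(vc)) vc[["c"]] else 0,
         e = vc[["e"]])
  if (any(s < 0)) stop("negative variance component")
  heritabilityFromComponents(s)
}
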