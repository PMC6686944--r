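#' Construct a Pedigree from id/sire/dam vectors
#'
#' Records are topologically sorted (parents before offspring) before the
#' object is built. Parents that appear as sire or dam but have no record of
#' their own are added as founders with a warning. Unknown parents are `"0"`
#' (or `NA`, which is recoded).
#'
#' @param id,sire,dam vectors of animal/parent identifiers.
#' @param generation optional integer generation codes; inferred from
#'   pedigree depth when missing.
#' @return a [Pedigree-class].
#' @examples
#' ped <- pedigree(id = c("o1", "s", "d"), sire = c("s", "0", "0"),
#'                 dam = c("d", "0", "0"))
#' animalIds(ped)  # founders first
#' @export
pedigree <- function(id, sire, dam, generation = NULL) {
  id <- as.character(id)
  sire <- as.character(sire); sire[is.na(sire)] <- "0"
  dam <- as.character(dam); dam[is.na(dam)] <- "0"
  if (anyDuplicated(id))
    stop("duplicate animal ids: ", paste(unique(id[duplicated(id)]),
                                         collapse = ", "))
  if (any(sire == id) || any(dam == id))
    stop("animal listed as its own parent")
  miss <- setdiff(c(sire, dam), c(id, "0"))
  if (length(miss)) {
    warning(length(miss), " parent(s) without a record added as founders")
    id <- c(miss, id)
    sire <- c(rep("0", length(miss)), sire)
    dam <- c(rep("0", length(miss)), dam)
    if (!is.null(generation)) generation <- c(rep(0L, length(miss)),
                                              as.integer(generation))
  }
  ord <- pedigreeOrder(id, sire, dam)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  if (is.null(generation)) {
    gen <- integer(length(id)); names(gen) <- id
    for (k in seq_along(id)) {
      ps <- c(sire[k], dam[k])
      ps <- ps[ps != "0"]
      gen[k] <- if (length(ps)) max(gen[ps]) + 1L else 0L
    }
    generation <- unname(gen)
  } else {
    generation <- as.integer(generation)[ord]
  }
  new("Pedigree", id = id, sire = sire, dam = dam, generation = generation)
}

## Kahn topological sort; stops on cycles. An input that is already
## topologically ordered is returned unchanged, so sorted pedigrees
## round-trip through files without reordering.
pedigreeOrder <- function(id, sire, dam) {
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  si <- ifelse(sire == "0", 0L, pos[sire])
  di <- ifelse(dam == "0", 0L, pos[dam])
  if (all(si < pos) && all(di < pos)) return(pos)
  indeg <- integer(n)
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(si[k], di[k])) if (p > 0L) {
      indeg[k] <- indeg[k] + 1L
      children[[p]] <- c(children[[p]], k)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    k <- queue[1L]; queue <- queue[-1L]
    out <- c(out, k)
    for (ch in children[[k]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n)
    stop("cycle detected in pedigree (an animal is its own ancestor)")
  out
}

#' Read / write a pedigree CSV
#'
#' The file has columns `animal, sire, dam[, generation]`; `0` codes an
#' unknown parent. Rows may be in any order; the result is topologically
#' sorted. Comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return [readPedigree()] returns a [Pedigree-class];
#'   [writePedigree()] returns `path`, invisibly.
#' @export
readPedigree <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                  colClasses = "character")
  names(d) <- tolower(names(d))
  if (!all(c("animal", "sire", "dam") %in% names(d)))
    stop("pedigree file needs columns animal, sire, dam")
  gen <- if ("generation" %in% names(d)) as.integer(d$generation) else NULL
  pedigree(d$animal, d$sire, d$dam, generation = gen)
}

#' @rdname readPedigree
#' @param ped a [Pedigree-class].
#' @param header optional character vector of comment lines (each written
#'   prefixed with `#`).
#' @export
writePedigree <- function(ped, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("animal,sire,dam,generation", con)
  writeLines(paste(ped@id, ped@sire, ped@dam, ped@generation, sep = ","), con)
  invisible(path)
}

#' Inbreeding coefficients by recursive kinship
#'
#' `F_i` is the kinship of the parents, computed by the standard recursion
#' on the topologically ordered pedigree with memoisation of ancestor
#' kinships, so no dense relationship matrix is formed.
#'
#' @param ped a [Pedigree-class].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  n <- length(ped@id)
  pos <- seq_len(n); names(pos) <- ped@id
  si <- ifelse(ped@sire == "0", 0L, pos[ped@sire])
  di <- ifelse(ped@dam == "0", 0L, pos[ped@dam])
  Fcoef <- numeric(n)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  kin <- function(a, b) {
    if (a == 0L || b == 0L) return(0)
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste0(a, ":", b)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (a == b) 0.5 * (1 + Fcoef[a])
         else 0.5 * (kin(a, si[b]) + kin(a, di[b]))
    memo[[key]] <- v
    v
  }
  for (k in seq_len(n))
    Fcoef[k] <- if (si[k] > 0L && di[k] > 0L) kin(si[k], di[k]) else 0
  setNames(Fcoef, ped@id)
}

#' Numerator relationship matrix A (tabular method)
#'
#' Builds the additive relationship matrix over the whole pedigree by the
#' tabular recursion, with inbreeding on the diagonal
#' (`A[i,i] = 1 + F_i`), then returns the requested sub-block. Memory is
#' quadratic in pedigree size; intended for desk-scale pedigrees.
#'
#' @param ped a [Pedigree-class].
#' @param subset animal ids to keep (default: all, in pedigree order).
#' @return dense symmetric matrix with animal-id dimnames.
#' @examples
#' ped <- pedigree(c("1", "2", "3", "4"), c("0", "0", "1", "1"),
#'                 c("0", "0", "2", "2"))
#' makeA(ped)["3", "4"]  # full sibs: 0.5
#' @export
makeA <- function(ped, subset = NULL) {
  n <- length(ped@id)
  pos <- seq_len(n); names(pos) <- ped@id
  si <- ifelse(ped@sire == "0", 0L, pos[ped@sire])
  di <- ifelse(ped@dam == "0", 0L, pos[ped@dam])
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (k in seq_len(n)) {
    s <- si[k]; d <- di[k]
    if (k > 1L) {
      j <- seq_len(k - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[j, k] <- v
      A[k, j] <- v
    }
    A[k, k] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  if (!is.null(subset)) A <- A[subset, subset, drop = FALSE]
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding from [inbreeding()]: for each animal
#' the Mendelian-sampling variance is
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (terms dropped for unknown parents,
#' `d_i = 1` for founders), and `1/d_i` contributions are scattered over the
#' animal/parent equations. Never forms A itself.
#'
#' @param ped a [Pedigree-class].
#' @return sparse symmetric `Matrix::dsCMatrix` with animal-id dimnames.
#' @export
makeAInverse <- function(ped) {
  n <- length(ped@id)
  pos <- seq_len(n); names(pos) <- ped@id
  si <- ifelse(ped@sire == "0", 0L, pos[ped@sire])
  di <- ifelse(ped@dam == "0", 0L, pos[ped@dam])
  Fc <- unname(inbreeding(ped))
  Fs <- ifelse(si > 0L, Fc[pmax(si, 1L)], NA_real_)
  Fd <- ifelse(di > 0L, Fc[pmax(di, 1L)], NA_real_)
  dvec <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (Fs + Fd),
          ifelse(si > 0L, 0.75 - 0.25 * Fs,
          ifelse(di > 0L, 0.75 - 0.25 * Fd, 1)))
  alpha <- 1 / dvec
  ## vectorized triplet assembly
  k <- seq_len(n)
  ii <- k; jj <- k; xx <- alpha
  for (p in list(si, di)) {
    has <- p > 0L
    ii <- c(ii, k[has], p[has])
    jj <- c(jj, p[has], k[has])
    xx <- c(xx, rep(-alpha[has] / 2, 2))
  }
  hs <- si > 0L; hd <- di > 0L
  ii <- c(ii, si[hs], di[hd])
  jj <- c(jj, si[hs], di[hd])
  xx <- c(xx, alpha[hs] / 4, alpha[hd] / 4)
  both <- hs & hd
  ii <- c(ii, si[both], di[both])
  jj <- c(jj, di[both], si[both])
  xx <- c(xx, rep(alpha[both] / 4, 2))
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(Ainv)
}

#' Full-sib family labels
#'
#' Labels each non-founder by its `sire:dam` pair; founders get `NA`.
#' Used to build the common-environment incidence matrix.
#'
#' @param ped a [Pedigree-class].
#' @return named character vector, `NA` for animals with an unknown parent.
#' @export
fullSibFamily <- function(ped) {
  fam <- ifelse(ped@sire != "0" & ped@dam != "0",
                paste(ped@sire, ped@dam, sep = ":"), NA_character_)
  setNames(fam, ped@id)
}
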