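#' Design a low-density panel by LD pruning
#'
#' Allocates a per-chromosome quota proportional to chromosome length,
#' then finds by bisection the pairwise-r2 pruning threshold (greedy
#' chromosome-wide sliding prune, step 1 SNP) whose survivor count best
#' matches the quota; survivors beyond the quota are thinned evenly. The
#' result is a subset of markers approximately proportional to chromosome
#' size, evenly spread and in low mutual linkage disequilibrium.
#'
#' @param geno HD [GenotypeData-class].
#' @param target_size desired SNP count (`>=` number of chromosomes).
#' @param bisection_iter bisection refinement steps (default 20).
#' @return list with `snps` (selected ids, map order), `achieved`,
#'   `target`, and `per_chromosome` (data.frame: chr, quota, achieved,
#'   r2 threshold used).
#' @export
selectLDPanel <- function(geno, target_size, bisection_iter = 20L) {
  map <- geno@map
  chrs <- unique(map$chr)
  if (target_size < length(chrs))
    stop("target_size smaller than the number of chromosomes")
  if (target_size > nrow(map))
    stop("target_size exceeds the HD SNP count")
  span <- vapply(chrs, function(cc) {
    p <- map$pos[map$chr == cc]
    max(p) - min(p) + 1
  }, numeric(1))
  chr_n <- vapply(chrs, function(cc) sum(map$chr == cc), integer(1))
  quota <- pmin(chr_n, pmax(1L, round(target_size * span / sum(span))))
  while (sum(quota) != target_size) {
    if (sum(quota) > target_size) {
      k <- which.max(quota)
      quota[k] <- quota[k] - 1L
    } else {
      ## grow the least-filled chromosome that still has room
      room <- which(quota < chr_n)
      k <- room[which.min((quota / span)[room])]
      quota[k] <- quota[k] + 1L
    }
  }
  d <- geno@dosage
  if (anyNA(d)) {
    mu <- rep(colMeans(d, na.rm = TRUE), each = nrow(d))
    d[is.na(d)] <- mu[is.na(d)]
  }
  sel <- character(0)
  per_chr <- data.frame(chr = chrs, quota = quota, achieved = 0L,
                        r2_threshold = NA_real_)
  for (ci in seq_along(chrs)) {
    j <- which(map$chr == chrs[ci])
    S <- scale(d[, j, drop = FALSE])
    S[, attr(S, "scaled:scale") == 0] <- 0
    q <- quota[ci]
    if (q >= length(j)) {
      keep <- seq_along(j)
      thr <- 1
    } else {
      lo <- 0; hi <- 1
      best <- NULL; best_gap <- Inf; thr <- 1
      for (b in seq_len(bisection_iter)) {
        t0 <- (lo + hi) / 2
        keep0 <- prune_chr(S, t0)
        gap <- length(keep0) - q
        if (abs(gap) < best_gap ||
            (abs(gap) == best_gap && gap >= 0)) {
          best <- keep0; best_gap <- abs(gap); thr <- t0
        }
        if (gap == 0L) break
        if (gap > 0L) hi <- t0 else lo <- t0
      }
      keep <- best
      if (length(keep) > q)  # thin evenly to the quota
        keep <- keep[unique(round(seq(1, length(keep), length.out = q)))]
    }
    per_chr$achieved[ci] <- length(keep)
    per_chr$r2_threshold[ci] <- thr
    sel <- c(sel, map$snp[j][keep])
  }
  list(snps = sel, achieved = length(sel), target = target_size,
       per_chromosome = per_chr)
}

## Greedy chromosome-wide prune on standardized dosages: drop any SNP
## whose squared correlation with an already-kept SNP exceeds `t`.
prune_chr <- function(S, t) {
  n <- nrow(S)
  m <- ncol(S)
  keep <- 1L
  if (m < 2L) return(keep)
  for (j in 2:m) {
    r <- crossprod(S[, keep, drop = FALSE], S[, j]) / (n - 1)
    if (all(r^2 <= t)) keep <- c(keep, j)
  }
  keep
}

#' Split genotyped animals into reference and validation sets
#'
#' Mirrors the study design: the reference (kept at high density) is all
#' genotyped parents plus a seeded random fraction of the offspring; the
#' remaining offspring form the validation set (reduced to the low-density
#' panel before imputation).
#'
#' @param parents,offspring genotyped parent and offspring ids (disjoint).
#' @param offspring_fraction fraction of offspring put in the reference
#'   (default 0.20).
#' @param seed integer seed for the random assignment.
#' @return list with `reference` and `validation` id vectors.
#' @export
splitReference <- function(parents, offspring, offspring_fraction = 0.20,
                           seed = 1L) {
  if (offspring_fraction < 0 || offspring_fraction >= 1)
    stop("offspring_fraction must lie in [0, 1)")
  if (length(intersect(parents, offspring)))
    stop("parents and offspring overlap")
  if (!length(parents))
    warning("no genotyped parents: population-only imputation")
  set.seed(seed)
  n_ref <- round(offspring_fraction * length(offspring))
  ref_off <- if (n_ref > 0) sort(sample(offspring, n_ref)) else character(0)
  list(reference = c(parents, ref_off),
       validation = setdiff(offspring, ref_off))
}
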