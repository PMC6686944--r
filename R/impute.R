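## Allele transmitted by `par` to a child, deduced by Mendelian rules.
## All arguments are dosage vectors over the same loci (NA = unknown);
## returns 0/1/NA per locus.
transmittedAllele <- function(child, par, mate) {
  t <- rep(NA_real_, length(child))
  t[!is.na(child) & child == 0] <- 0
  t[!is.na(child) & child == 2] <- 1
  het <- !is.na(child) & child == 1
  if (!is.null(par)) {
    t[het & !is.na(par) & par == 0] <- 0
    t[het & !is.na(par) & par == 2] <- 1
  }
  if (!is.null(mate)) {
    open <- het & is.na(t)
    t[open & !is.na(mate) & mate == 0] <- 1
    t[open & !is.na(mate) & mate == 2] <- 0
  }
  t
}

## Partition the HD loci of one chromosome into spans, one per block of
## `w` consecutive LD markers; returns list of (hd index range, ld indices).
ldWindows <- function(ld_in_chr, n_hd, w) {
  nb <- ceiling(length(ld_in_chr) / w)
  blocks <- split(ld_in_chr, ceiling(seq_along(ld_in_chr) / w))
  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    first <- if (b == 1L) 1L
      else floor((max(blocks[[b - 1L]]) + min(blocks[[b]])) / 2) + 1L
    last <- if (b == nb) n_hd
      else floor((max(blocks[[b]]) + min(blocks[[b + 1L]])) / 2)
    out[[b]] <- list(span = first:last, ld = blocks[[b]])
  }
  out
}

## Per-chromosome window structures for every schedule length, indexed by
## global HD locus; computed once per imputation run.
chromosomeWindows <- function(chr_of, ld_idx, schedule) {
  lapply(unique(chr_of), function(cc) {
    hd_in <- which(chr_of == cc)
    ld_in <- which(chr_of[ld_idx] == cc)
    ld_local <- match(ld_idx[ld_in], hd_in)
    wins <- lapply(schedule, function(w) {
      if (!length(ld_local)) return(list())
      lapply(ldWindows(ld_local, length(hd_in), w), function(win)
        list(span = hd_in[win$span], cons = hd_in[win$ld]))
    })
    list(hd = hd_in, wins = wins)
  })
}

## Fill the still-missing entries of gamete `t_full` by matching its
## constraints against a library of candidate gametes (rows of `lib`),
## within the precomputed windows, longest first. A candidate matches a
## window when it agrees with every constraint locus where both are
## observed and at least `min_compare` loci are comparable; the missing
## loci of the window take the majority vote over all matching candidates
## (ties resolved by the earliest candidate in library order).
matchFill <- function(t_full, lib, chr_wins, min_compare = 1L) {
  if (is.null(lib) || !nrow(lib)) return(t_full)
  for (chr in chr_wins) {
    if (!anyNA(t_full[chr$hd])) next
    for (wins in chr$wins) {
      if (!anyNA(t_full[chr$hd])) break
      for (win in wins) {
        span <- win$span
        gap <- span[is.na(t_full[span])]
        if (!length(gap)) next
        cons <- t_full[win$cons]
        known <- which(!is.na(cons))
        if (length(known) < min_compare) next
        L <- lib[, win$cons[known], drop = FALSE]
        cmp <- !is.na(L)
        n_cmp <- rowSums(cmp)
        n_ok <- rowSums(cmp & L == rep(cons[known], each = nrow(L)),
                        na.rm = TRUE)
        hits <- which(n_cmp >= min(min_compare, length(known)) &
                        n_ok == n_cmp)
        if (!length(hits)) next
        votes <- lib[hits, gap, drop = FALSE]
        m <- colMeans(votes, na.rm = TRUE)
        fill <- ifelse(m > 0.5, 1, ifelse(m < 0.5, 0, NA))
        ## ties (and single-candidate NaN columns): earliest informative
        ## candidate decides
        tie <- which(is.na(fill) & !is.nan(m) | m == 0.5)
        for (k in tie) {
          val <- votes[, k]
          val <- val[!is.na(val)]
          if (length(val)) fill[k] <- val[1L]
        }
        ok <- !is.na(fill)
        t_full[gap[ok]] <- fill[ok]
      }
    }
  }
  t_full
}

#' Family-plus-population genotype imputation
#'
#' Imputes low-density-genotyped validation animals up to the reference
#' high-density panel, following the family-first design of
#' pedigree-aware imputation software:
#'
#' 1. *Family phase.* For each reference parent, the gametes it
#'    transmitted to its HD reference offspring are deduced locus-by-locus
#'    by Mendelian rules (the mate's genotype resolves heterozygous
#'    children). For a validation animal, the gamete received from each
#'    parent is deduced the same way at the low-density loci and matched,
#'    within sliding windows of shrinking length (default 64, 32, 16, 8
#'    low-density markers; agreement required at every mutually observed
#'    constraint locus), against that parent's deduced gametes; the
#'    matching gametes vote on the untyped loci of the window. Loci where
#'    a parent is homozygous are always filled directly, and each resolved
#'    parental side sharpens the other through the Mendelian complement at
#'    the observed low-density loci.
#' 2. *Population fallback.* Gamete segments still unresolved are matched
#'    the same way against the haplotype library pooled over all deduced
#'    reference gametes (a stricter minimum overlap guards against chance
#'    matches).
#' 3. *Frequency fallback.* Anything left takes the parent-expected
#'    contribution (0.5 per heterozygous parent) or the reference allele
#'    frequency, so every locus receives a call.
#'
#' Observed low-density dosages always override imputed values. The
#' procedure is deterministic: ties are broken by reference order.
#'
#' @param reference_hd [GenotypeData-class] of the reference animals at
#'   the full HD panel (parents and HD offspring).
#' @param validation_ld [GenotypeData-class] of the validation animals at
#'   the low-density panel; its SNPs must be a subset of the HD panel.
#' @param ped a [Pedigree-class] linking validation animals to their
#'   parents.
#' @param window_schedule LD-marker window lengths, long to short.
#' @param pop_min_compare minimum mutually observed loci for a
#'   population-tier match (default 4).
#' @return [GenotypeData-class] of the validation animals at the HD panel;
#'   dosages may be fractional where only expected values are available.
#' @export
imputeGenotypes <- function(reference_hd, validation_ld, ped,
                            window_schedule = c(64L, 32L, 16L, 8L),
                            pop_min_compare = 4L) {
  hd_map <- reference_hd@map
  ld_snps <- colnames(validation_ld@dosage)
  ld_idx <- match(ld_snps, hd_map$snp)
  if (anyNA(ld_idx))
    stop("validation SNPs must be a subset of the reference HD panel")
  if (is.unsorted(ld_idx)) {
    o <- order(ld_idx)
    validation_ld <- validation_ld[, o]
    ld_idx <- ld_idx[o]
  }
  R <- reference_hd@dosage
  V <- validation_ld@dosage
  nsnp <- ncol(R)
  ref_ids <- rownames(R)
  val_ids <- rownames(V)
  p_ref <- colMeans(R, na.rm = TRUE) / 2
  sire <- sireOf(ped); dam <- damOf(ped)

  ## deduced transmitted gametes per reference parent, from HD offspring
  lib <- list()
  ref_par <- intersect(unique(c(sire[val_ids], dam[val_ids],
                                sire[ref_ids], dam[ref_ids])), ref_ids)
  for (pid in ref_par) {
    kids <- ref_ids[!is.na(sire[ref_ids]) &
                      (sire[ref_ids] == pid | dam[ref_ids] == pid)]
    gam <- lapply(kids, function(k) {
      mate <- if (sire[k] == pid) dam[k] else sire[k]
      mrow <- if (!is.na(mate) && mate %in% ref_ids) R[mate, ] else NULL
      transmittedAllele(R[k, ], R[pid, ], mrow)
    })
    if (length(gam)) {
      M <- matrix(unlist(gam), nrow = length(gam), byrow = TRUE)
      ## each deduced gamete also implies its Mendelian complement
      ## (the parent's other haplotype, locally), doubling the library
      comp <- sweep(-M, 2L, R[pid, ], "+")
      comp[comp < 0 | comp > 1] <- NA
      lib[[pid]] <- rbind(M, comp)
    }
  }
  pool <- do.call(rbind, unname(lib))

  chrs <- unique(hd_map$chr)
  chr_of <- match(hd_map$chr, chrs)
  chr_wins <- chromosomeWindows(chr_of, ld_idx, window_schedule)
  out <- matrix(NA_real_, length(val_ids), nsnp,
                dimnames = list(val_ids, hd_map$snp))
  for (v in val_ids) {
    s <- sire[[v]]; d <- dam[[v]]
    srow <- if (s %in% ref_ids) R[s, ] else NULL
    drow <- if (d %in% ref_ids) R[d, ] else NULL
    vld <- V[v, ]
    ## per-side gamete skeletons: LD-deduced constraints + homozygous loci
    ts <- startGamete(vld, srow, drow, ld_idx, nsnp)
    td <- startGamete(vld, drow, srow, ld_idx, nsnp)
    ## family tier per side
    ts <- matchFill(ts, lib[[s]], chr_wins, min_compare = 1L)
    td <- matchFill(td, lib[[d]], chr_wins, min_compare = 1L)
    ## Mendelian complement at observed LD loci sharpens the weak side,
    ## then a second family pass and the population tier mop up
    upd <- complementSides(ts, td, vld, ld_idx)
    if (upd$changed) {
      ts <- matchFill(upd$ts, lib[[s]], chr_wins, min_compare = 1L)
      td <- matchFill(upd$td, lib[[d]], chr_wins, min_compare = 1L)
    }
    if (anyNA(ts))
      ts <- matchFill(ts, pool, chr_wins, min_compare = pop_min_compare)
    if (anyNA(td))
      td <- matchFill(td, pool, chr_wins, min_compare = pop_min_compare)
    ## frequency fallback per haplotype side
    es <- expectedContribution(srow, p_ref)
    ed <- expectedContribution(drow, p_ref)
    g <- ifelse(is.na(ts), es, ts) + ifelse(is.na(td), ed, td)
    ## observed LD dosages always win
    g[ld_idx] <- vld
    out[v, ] <- g
  }
  genotypeData(out, hd_map)
}

## initial gamete for one parental side: Mendelian deductions at the LD
## loci plus direct fills where the parent is homozygous
startGamete <- function(vld, par, mate, ld_idx, nsnp) {
  t_full <- rep(NA_real_, nsnp)
  if (!is.null(par)) {
    hom <- !is.na(par) & (par == 0 | par == 2)
    t_full[hom] <- par[hom] / 2
  }
  t_ld <- transmittedAllele(vld,
                            if (is.null(par)) NULL else par[ld_idx],
                            if (is.null(mate)) NULL else mate[ld_idx])
  keep <- !is.na(t_ld)
  t_full[ld_idx[keep]] <- t_ld[keep]
  t_full
}

## dosage arithmetic at the observed LD loci: a resolved allele on one
## side determines the other side's allele there
complementSides <- function(ts, td, vld, ld_idx) {
  changed <- FALSE
  open_d <- which(is.na(td[ld_idx]) & !is.na(ts[ld_idx]) & !is.na(vld))
  if (length(open_d)) {
    val <- vld[open_d] - ts[ld_idx[open_d]]
    ok <- val %in% c(0, 1)
    td[ld_idx[open_d[ok]]] <- val[ok]
    changed <- changed || any(ok)
  }
  open_s <- which(is.na(ts[ld_idx]) & !is.na(td[ld_idx]) & !is.na(vld))
  if (length(open_s)) {
    val <- vld[open_s] - td[ld_idx[open_s]]
    ok <- val %in% c(0, 1)
    ts[ld_idx[open_s[ok]]] <- val[ok]
    changed <- changed || any(ok)
  }
  list(ts = ts, td = td, changed = changed)
}

## expected per-gamete contribution from a parent genotype (or frequency)
expectedContribution <- function(par, p_ref) {
  if (is.null(par)) return(p_ref)
  e <- par / 2
  e[is.na(e)] <- p_ref[is.na(e)]
  e
}

#' Imputation accuracy
#'
#' Per-SNP Pearson correlation between true and imputed dosages across the
#' validation animals at the masked loci; the overall accuracy is the mean
#' over SNPs with a defined correlation (SNPs monomorphic in the truth are
#' excluded and counted). The genotype concordance rate (imputed dosages
#' rounded) and a secondary per-animal correlation summary are also
#' reported.
#'
#' @param truth true dosages over the validation animals
#'   ([GenotypeData-class] or matrix).
#' @param imputed imputed dosages from [imputeGenotypes()].
#' @param masked_snps ids of the SNPs that were masked (default: every
#'   imputed column).
#' @return list: `per_snp` (data.frame snp, r, concordance), `mean_r`,
#'   `concordance`, `n_excluded`, `per_animal_mean_r`.
#' @export
imputationAccuracy <- function(truth, imputed, masked_snps = NULL) {
  Tm <- if (is(truth, "GenotypeData")) truth@dosage else as.matrix(truth)
  Im <- if (is(imputed, "GenotypeData")) imputed@dosage else
    as.matrix(imputed)
  if (is.null(masked_snps)) masked_snps <- colnames(Im)
  if (!length(masked_snps)) stop("no masked SNPs to score")
  ids <- rownames(Im)
  Tm <- Tm[ids, masked_snps, drop = FALSE]
  Im <- Im[ids, masked_snps, drop = FALSE]
  sdT <- apply(Tm, 2L, sd)
  sdI <- apply(Im, 2L, sd)
  r <- rep(NA_real_, length(masked_snps))
  ok <- sdT > 0 & sdI > 0
  for (j in which(ok)) r[j] <- cor(Tm[, j], Im[, j])
  conc <- colMeans(round(Im) == Tm)
  ra <- vapply(seq_len(nrow(Tm)), function(i) {
    if (sd(Tm[i, ]) == 0 || sd(Im[i, ]) == 0) return(NA_real_)
    cor(Tm[i, ], Im[i, ])
  }, numeric(1))
  list(per_snp = data.frame(snp = masked_snps, r = r, concordance = conc,
                            stringsAsFactors = FALSE),
       mean_r = mean(r, na.rm = TRUE),
       concordance = mean(conc),
       n_excluded = sum(sdT == 0),
       per_animal_mean_r = mean(ra, na.rm = TRUE))
}
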