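#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix (animals x SNPs) of 0/1/2 dosages, `NA`
#'   allowed; rownames are animal ids.
#' @param map data.frame with columns `snp`, `chr`, `pos` and optionally
#'   `a1`, `a2` (allele labels; `a2` is the counted allele). Defaults
#'   `a1 = "A"`, `a2 = "B"` are filled in when absent.
#' @return a [GenotypeData-class].
#' @export
genotypeData <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  map <- as.data.frame(map)
  map$snp <- as.character(map$snp)
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp
  new("GenotypeData", dosage = dosage, map = map)
}

#' Read genotypes from PLINK-style PED/MAP text files
#'
#' The MAP file has columns `chr snp cM bp` and, in the dialect this
#' package writes, two extra allele columns `a1 a2`; `a2` is the counted
#' allele (dosage = number of `a2` copies). When the allele columns are
#' absent the counted allele is the lexicographically larger of the two
#' alleles observed at the SNP, a fixed documented convention. The PED file
#' is `fid iid pat mat sex pheno` followed by two alleles per SNP; `0 0`
#' codes a missing genotype.
#'
#' @param ped_path,map_path file paths.
#' @return a [GenotypeData-class].
#' @export
readPlink <- function(ped_path, map_path) {
  mp <- read.table(map_path, header = FALSE, colClasses = "character",
                   comment.char = "#")
  if (!ncol(mp) %in% c(4L, 6L))
    stop("MAP file must have 4 or 6 columns")
  map <- data.frame(snp = mp[[2L]], chr = mp[[1L]],
                    pos = as.numeric(mp[[4L]]), stringsAsFactors = FALSE)
  nsnp <- nrow(map)
  toks <- scan(ped_path, what = character(), quiet = TRUE,
               comment.char = "#")
  ncol_ped <- 6L + 2L * nsnp
  if (length(toks) %% ncol_ped != 0L)
    stop("PED column count does not match MAP (",
         length(toks), " tokens, expected a multiple of ", ncol_ped, ")")
  m <- matrix(toks, ncol = ncol_ped, byrow = TRUE)
  ids <- m[, 2L]
  al <- m[, -(1:6), drop = FALSE]
  a_first <- al[, seq(1L, 2L * nsnp, by = 2L), drop = FALSE]
  a_second <- al[, seq(2L, 2L * nsnp, by = 2L), drop = FALSE]
  if (ncol(mp) == 6L) {
    map$a1 <- mp[[5L]]; map$a2 <- mp[[6L]]
  } else {
    map$a1 <- NA_character_; map$a2 <- NA_character_
    for (j in seq_len(nsnp)) {
      obs <- unique(c(a_first[, j], a_second[, j]))
      obs <- sort(obs[obs != "0"])
      if (length(obs) > 2L)
        stop("non-biallelic SNP ", map$snp[j])
      if (length(obs) == 0L) obs <- c("A", "B")
      if (length(obs) == 1L) obs <- c(obs, obs)
      map$a1[j] <- obs[1L]; map$a2[j] <- obs[2L]
    }
  }
  counted <- matrix(rep(map$a2, each = nrow(m)), nrow = nrow(m))
  dos <- (a_first == counted) + (a_second == counted)
  dos[a_first == "0" | a_second == "0"] <- NA
  dimnames(dos) <- list(ids, map$snp)
  bad <- !(a_first == "0" | a_first == map$a1[col(a_first)] |
             a_first == counted) |
         !(a_second == "0" | a_second == map$a1[col(a_second)] |
             a_second == counted)
  if (any(bad))
    stop("allele not matching the MAP alleles at SNP(s): ",
         paste(unique(map$snp[unique(col(bad)[bad])]), collapse = ", "))
  genotypeData(dos, map)
}

#' Write genotypes as PLINK-style PED/MAP text files
#'
#' Inverse of [readPlink()]: emits a 6-column MAP (`chr snp 0 bp a1 a2`)
#' and a PED with two alleles per SNP (`0 0` for missing). Non-integer
#' dosages are rounded to the nearest of 0/1/2.
#'
#' @param geno a [GenotypeData-class].
#' @param prefix output path prefix; writes `<prefix>.ped`, `<prefix>.map`.
#' @param header optional comment lines written (with `#`) atop both files.
#' @return the two paths, invisibly.
#' @export
writePlink <- function(geno, prefix, header = NULL) {
  map <- geno@map
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  con <- file(map_path, "w")
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(map$chr, map$snp, 0, format(map$pos, scientific = FALSE,
                                               trim = TRUE),
                   map$a1, map$a2), con)
  close(con)
  d <- round(geno@dosage)
  n <- nrow(d); nsnp <- ncol(d)
  first <- matrix(rep(map$a1, each = n), n)
  second <- matrix(rep(map$a1, each = n), n)
  a2rep <- rep(map$a2, each = n)
  i1 <- which(d >= 1); i2 <- which(d == 2)
  second[i1] <- a2rep[i1]
  first[i2] <- a2rep[i2]
  first[is.na(d)] <- "0"; second[is.na(d)] <- "0"
  alleles <- matrix("", n, 2L * nsnp)
  alleles[, seq(1L, 2L * nsnp, 2L)] <- first
  alleles[, seq(2L, 2L * nsnp, 2L)] <- second
  lines <- paste(0, rownames(d), 0, 0, 0, -9,
                 apply(alleles, 1L, paste, collapse = " "))
  con <- file(ped_path, "w")
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(lines, con)
  close(con)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read / write a phenotype CSV
#'
#' Columns: `animal`, trait columns, `cg` (contemporary group), covariate
#' columns, `family`, `generation`; extra columns pass through.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readPhenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                  stringsAsFactors = FALSE)
  d$animal <- as.character(d$animal)
  d
}

#' @rdname readPhenotypes
#' @param phen data.frame of phenotypes.
#' @param header optional comment lines.
#' @export
writePhenotypes <- function(phen, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(phen, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a relationship matrix in triplet text form
#'
#' Writes `row_id<TAB>col_id<TAB>value` for the lower triangle (including
#' the diagonal) of a symmetric relationship matrix.
#'
#' @param mat symmetric matrix with id dimnames (dense or `Matrix`).
#' @param path output path.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
writeTriplets <- function(mat, path, header = NULL) {
  mat <- as.matrix(mat)
  idx <- which(lower.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(rownames(mat)[idx[, 1L]], colnames(mat)[idx[, 2L]],
                   format(mat[idx], digits = 10), sep = "\t"), con)
  invisible(path)
}
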