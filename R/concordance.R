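# Genotype concordance between the variation catalogue and an external
# genotype panel (HapMap-style homozygous genotypes).

#' Read a tabular concordance panel
#'
#' Tab-separated columns `chrom`, `pos`, `strain`, `genotype` with a header
#' line. Genotypes are single bases (`A`) or allele pairs (`A/A`, `AA`);
#' entries with a missing genotype (`NA`, `.`, `N`, empty) are removed on
#' load, as in the upstream resource.
#'
#' @param path File path.
#' @param provenance Free-text provenance label stored as an attribute.
#' @return `data.table` with `chrom`, `pos`, `strain`, `allele1`, `allele2`.
#' @export
read_concordance_panel <- function(path, provenance = basename(path)) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = "genotype"))
  data.table::setnames(dt, tolower(names(dt)))
  stopifnot(all(c("chrom", "pos", "strain", "genotype") %in% names(dt)))
  g <- normalize_genotype(dt$genotype)
  keep <- !is.na(g$allele1) & !is.na(g$allele2)
  out <- data.table::data.table(chrom = as.character(dt$chrom),
                                pos = as.integer(dt$pos),
                                strain = as.character(dt$strain),
                                allele1 = g$allele1, allele2 = g$allele2)[keep]
  data.table::setattr(out, "provenance", provenance)
  out[]
}

normalize_genotype <- function(x) {
  x <- toupper(gsub("[/|]", "", as.character(x)))
  x[x %in% c("", ".", "NA", "N", "..", "NN")] <- NA_character_
  a1 <- substr(x, 1L, 1L)
  a2 <- ifelse(nchar(x) >= 2L, substr(x, 2L, 2L), a1)
  bad <- !is.na(x) & !(a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T"))
  a1[bad | is.na(x)] <- NA_character_
  a2[bad | is.na(x)] <- NA_character_
  list(allele1 = a1, allele2 = a2)
}

#' Genotype concordance for one strain against a panel
#'
#' For every panel entry of the strain, the called genotype at the position
#' is derived from the strain matrix: a high-quality homozygous-alternate
#' call gives the alternate allele pair, a high-quality homozygous-reference
#' call gives the reference pair (counted as comparable evidence by
#' default), a heterozygous call gives the ref/alt pair. Low-quality or
#' missing calls, and positions with no reference-genotype evidence, are
#' uncallable and excluded from the denominator.
#'
#' @param mat A [strain_matrix()].
#' @param panel Panel `data.table` from [read_concordance_panel()].
#' @param strain Strain name (must be in the matrix panel).
#' @param include_homref Count high-quality homozygous-reference calls as
#'   comparable (default `TRUE`); when `FALSE`, only variant calls enter
#'   the denominator.
#' @return List with `n_compared`, `n_concordant`, `rate` (percent; `NA`
#'   when nothing is comparable).
#' @export
genotype_concordance <- function(mat, panel, strain, include_homref = TRUE) {
  if (!strain %in% mat$strains) stop("strain absent from calls: ", strain)
  keep_rows <- which(panel[["strain"]] == strain)
  p <- panel[keep_rows]
  if (nrow(p) == 0L) {
    return(list(n_compared = 0L, n_concordant = 0L, rate = NA_real_))
  }
  sites <- mat$sites
  idx <- match(paste(p$chrom, p$pos), paste(sites$chrom, sites$pos))
  gt <- mat$gt[, strain]
  n_compared <- 0L
  n_concordant <- 0L
  for (i in seq_len(nrow(p))) {
    j <- idx[i]
    if (is.na(j)) next                      # position not genotyped: uncallable
    cls <- gt[j]
    if (cls %in% c(GT_LOWQUAL, GT_MISSING)) next
    if (cls == GT_HOM_REF && !include_homref) next
    called <- switch(cls,
                     c(sites$ref[j], sites$ref[j]),        # HOM_REF_HQ
                     c(sites$alt[j], sites$alt[j]),        # HOM_ALT_HQ
                     c(sites$ref[j], sites$alt[j]))        # HET_HQ
    n_compared <- n_compared + 1L
    exp_gt <- sort(c(p$allele1[i], p$allele2[i]))
    if (identical(sort(called), exp_gt)) n_concordant <- n_concordant + 1L
  }
  list(n_compared = n_compared, n_concordant = n_concordant,
       rate = if (n_compared > 0L) 100 * n_concordant / n_compared else NA_real_)
}

#' Concordance report over all panel strains
#'
#' @inheritParams genotype_concordance
#' @return `data.table` with `strain`, `n_genotypes`, `n_concordant`,
#'   `rate`.
#' @export
concordance_report <- function(mat, panel, include_homref = TRUE) {
  strains <- intersect(mat$strains, unique(panel$strain))
  data.table::rbindlist(lapply(strains, function(s) {
    r <- genotype_concordance(mat, panel, s, include_homref)
    data.table::data.table(strain = s, n_genotypes = r$n_compared,
                           n_concordant = r$n_concordant, rate = r$rate)
  }))
}
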