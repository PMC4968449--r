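# The strains x sites genotype catalogue and the private/shared-variant
# rules applied to it.

#' Construct a strain genotype matrix
#'
#' The central container of the package: an ordered strain panel, a site
#' table (one row per decomposed alternate allele, keyed by
#' `chrom:pos:ref:alt`) and an integer matrix of genotype-class codes (see
#' [GT_CLASSES]) with one column per strain. Optional slots carry raw GT
#' strings, genotype qualities, site-level filter status and consequence
#' annotations.
#'
#' @param strains Ordered character vector of strain identifiers.
#' @param sites `data.frame` with `chrom`, `pos`, `ref`, `alt` (one row per
#'   alternate allele; multi-allelic rows must already be decomposed).
#' @param gt Integer matrix, `nrow(sites)` x `length(strains)`, of class
#'   codes in `1:5`.
#' @param gq Optional numeric matrix of genotype qualities.
#' @param raw Optional character matrix of raw GT strings.
#' @param pass Optional logical vector: site passed soft filters.
#' @param annotations Optional annotation `data.table` (see
#'   [read_multistrain_vcf()] for columns).
#' @param config The [quality_config()] used for classification.
#' @return An object of class `strain_matrix`.
#' @export
strain_matrix <- function(strains, sites, gt, gq = NULL, raw = NULL,
                          pass = NULL, annotations = NULL,
                          config = quality_config()) {
  strains <- as.character(strains)
  if (length(strains) < 1L) stop("panel needs at least one strain")
  sites <- data.table::as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!"vclass" %in% names(sites)) sites[, vclass := variant_class(ref, alt)]
  if (!"key" %in% names(sites)) sites[, key := site_key(chrom, pos, ref, alt)]
  if (anyDuplicated(sites$key)) {
    stop("duplicate site keys: ", paste(head(sites$key[duplicated(sites$key)], 3), collapse = ", "))
  }
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (nrow(gt) != nrow(sites) || ncol(gt) != length(strains)) {
    stop("gt matrix must be n_sites x n_strains")
  }
  if (nrow(gt) > 0L && (min(gt) < 1L || max(gt) > 5L)) {
    stop("gt codes must be in 1..5")
  }
  colnames(gt) <- strains
  if (is.null(raw)) {
    raw <- matrix(c("0/0", "1/1", "0/1", "0/0", "./.")[gt],
                  nrow = nrow(gt), dimnames = list(NULL, strains))
  }
  if (is.null(gq)) {
    # classification-consistent defaults: HQ calls well above, LQ below min_gq
    gq <- matrix(ifelse(gt == GT_LOWQUAL, max(0, config$min_gq - 10),
                        ifelse(gt == GT_MISSING, NA_real_, 99)),
                 nrow = nrow(gt), dimnames = list(NULL, strains))
  }
  if (is.null(pass)) pass <- rep(TRUE, nrow(sites))
  if (is.null(annotations)) annotations <- empty_annotations()
  structure(list(strains = strains, sites = sites, gt = gt, gq = gq,
                 raw = raw, pass = pass,
                 annotations = data.table::as.data.table(annotations),
                 config = config),
            class = "strain_matrix")
}

#' @export
print.strain_matrix <- function(x, ...) {
  cat("strain_matrix:", nrow(x$sites), "sites x", length(x$strains), "strains\n")
  cat("  classes:", paste(GT_CLASSES, tabulate(x$gt, 5L), collapse = ", "), "\n")
  if (nrow(x$annotations) > 0L) {
    cat("  annotations:", nrow(x$annotations), "rows on",
        length(unique(x$annotations$key)), "sites\n")
  }
  invisible(x)
}

subset_sites <- function(mat, idx) {
  keys <- mat$sites$key[idx]
  strain_matrix(mat$strains, mat$sites[idx, !"key"][, !"vclass"],
                mat$gt[idx, , drop = FALSE],
                gq = mat$gq[idx, , drop = FALSE],
                raw = mat$raw[idx, , drop = FALSE],
                pass = mat$pass[idx],
                annotations = mat$annotations[key %in% keys],
                config = mat$config)
}

vclass_index <- function(mat, vclass_filter) {
  if (is.null(vclass_filter)) return(rep(TRUE, nrow(mat$sites)))
  vf <- match.arg(vclass_filter, c("SNP", "INS", "DEL", "INDEL"))
  if (vf == "INDEL") mat$sites$vclass %in% c("INS", "DEL") else mat$sites$vclass == vf
}

#' Privacy rule for private-variant identification
#'
#' A variant site is *private* to a strain when that strain is the only
#' high-quality homozygous-alternate call, all other confidently called
#' strains are high-quality homozygous reference and number at least
#' `min_homref_others`, and at most `max_missing_lq` of the other strains
#' have a low-quality or missing genotype. Any high-quality heterozygous
#' call (or a second homozygous-alternate) among the others disqualifies
#' the site.
#'
#' With the defaults on a 36-strain panel this is the "at least 30
#' high-quality homozygous reference, at most 5 missing or low quality"
#' rule; for a general panel of `S` strains leave `min_homref_others = NULL`
#' to get `S - 1 - max_missing_lq`.
#'
#' @param min_homref_others Minimum number of other strains that must be
#'   `HOM_REF_HQ`, or `NULL` to derive from panel size.
#' @param max_missing_lq Maximum number of other strains allowed a
#'   `LOW_QUALITY` or `MISSING` call. Default 5.
#' @return A `privacy_rule` list.
#' @export
privacy_rule <- function(min_homref_others = 30L, max_missing_lq = 5L) {
  stopifnot(max_missing_lq >= 0L)
  if (!is.null(min_homref_others)) stopifnot(min_homref_others >= 0L)
  structure(list(min_homref_others = min_homref_others,
                 max_missing_lq = as.integer(max_missing_lq)),
            class = "privacy_rule")
}

resolve_rule <- function(rule, S) {
  mh <- rule$min_homref_others
  if (is.null(mh)) mh <- S - 1L - rule$max_missing_lq
  mh <- as.integer(mh)
  if (mh + rule$max_missing_lq + 1L > S) {
    stop("privacy rule incompatible with panel of ", S, " strains: ",
         "min_homref_others + max_missing_lq + 1 must be <= S")
  }
  list(min_homref_others = mh, max_missing_lq = rule$max_missing_lq)
}

#' Identify variants private to each strain
#'
#' Applies a [privacy_rule()] to every site of the matrix and returns, per
#' strain, the keys of sites private to it, sorted by `(chrom, pos)`.
#'
#' @param mat A [strain_matrix()].
#' @param rule A [privacy_rule()].
#' @param vclass_filter Optional `"SNP"`, `"INS"`, `"DEL"` or `"INDEL"` to
#'   restrict to one variant class.
#' @return Named list (one element per panel strain) of character vectors of
#'   site keys.
#' @export
identify_private_variants <- function(mat, rule = privacy_rule(),
                                      vclass_filter = NULL) {
  stopifnot(inherits(mat, "strain_matrix"), inherits(rule, "privacy_rule"))
  S <- length(mat$strains)
  r <- resolve_rule(rule, S)
  keep <- vclass_index(mat, vclass_filter)
  gt <- mat$gt[keep, , drop = FALSE]
  sites <- mat$sites[keep]
  n_alt <- rowSums(gt == GT_HOM_ALT)
  n_het <- rowSums(gt == GT_HET)
  n_ml  <- rowSums(gt == GT_LOWQUAL | gt == GT_MISSING)
  n_ref <- rowSums(gt == GT_HOM_REF)
  ok <- n_alt == 1L & n_het == 0L & n_ml <= r$max_missing_lq &
    n_ref >= r$min_homref_others
  out <- setNames(vector("list", S), mat$strains)
  ord <- order(sites$chrom, sites$pos)
  for (j in seq_len(S)) {
    idx <- ord[ok[ord] & gt[ord, j] == GT_HOM_ALT]
    out[[j]] <- sites$key[idx]
  }
  out
}

#' Fraction of one strain's variants shared with another
#'
#' The denominator is the number of sites where `strain_a` is a high-quality
#' homozygous-alternate call (optionally restricted by variant class); the
#' numerator is the subset where `strain_b` is homozygous for the same
#' alternate allele.
#'
#' @inheritParams identify_private_variants
#' @param strain_a,strain_b Panel strain names.
#' @return List with `fraction` (`NA` when the denominator is 0, with
#'   `defined = FALSE`), `numerator`, `denominator`, `defined`.
#' @export
shared_fraction <- function(mat, strain_a, strain_b, vclass_filter = NULL) {
  stopifnot(inherits(mat, "strain_matrix"))
  for (s in c(strain_a, strain_b)) {
    if (!s %in% mat$strains) stop("unknown strain: ", s)
  }
  keep <- vclass_index(mat, vclass_filter)
  a <- mat$gt[keep, strain_a] == GT_HOM_ALT
  b <- mat$gt[keep, strain_b] == GT_HOM_ALT
  den <- sum(a)
  num <- sum(a & b)
  list(fraction = if (den > 0L) num / den else NA_real_,
       numerator = num, denominator = den, defined = den > 0L)
}

#' Pairwise shared-variant counts across the panel
#'
#' Symmetric S x S matrix of the number of sites at which both strains of a
#' pair are high-quality homozygous alternate for the same allele; the
#' diagonal holds per-strain totals.
#'
#' @inheritParams identify_private_variants
#' @return Integer matrix with strain dimnames.
#' @export
pairwise_sharing_table <- function(mat, vclass_filter = NULL) {
  stopifnot(inherits(mat, "strain_matrix"))
  keep <- vclass_index(mat, vclass_filter)
  alt <- mat$gt[keep, , drop = FALSE] == GT_HOM_ALT
  out <- crossprod(alt)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(mat$strains, mat$strains)
  out
}

#' Per-strain variant and private-variant summary
#'
#' One row per strain with SNP/indel totals (high-quality hom-alt sites) and
#' private counts under the supplied rule.
#'
#' @inheritParams identify_private_variants
#' @return `data.table` with columns `strain`, `n_snps`, `n_private_snps`,
#'   `n_indels`, `n_private_indels`.
#' @export
catalog_summary <- function(mat, rule = privacy_rule()) {
  snp <- vclass_index(mat, "SNP")
  priv_snp <- identify_private_variants(mat, rule, "SNP")
  priv_indel <- identify_private_variants(mat, rule, "INDEL")
  data.table::data.table(
    strain = mat$strains,
    n_snps = colSums(mat$gt[snp, , drop = FALSE] == GT_HOM_ALT),
    n_private_snps = lengths(priv_snp),
    n_indels = colSums(mat$gt[!snp, , drop = FALSE] == GT_HOM_ALT),
    n_private_indels = lengths(priv_indel)
  )
}
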