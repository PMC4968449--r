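# Candidate-gene discovery: (A) genes with a missense variant private to a
# focal strain; (B) strain-subtraction with damage filtering (target minus
# strains sharing the allele, then missense + SIFT-deleterious).

new_candidate_set <- function(focal, comparators, snp_keys, genes, filter_spec) {
  structure(list(focal_strain = focal, comparator_strains = comparators,
                 snp_keys = snp_keys, genes = genes, filter_spec = filter_spec),
            class = "candidate_gene_set")
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat("candidate_gene_set:", x$focal_strain,
      if (length(x$comparator_strains)) paste0("(minus ", paste(x$comparator_strains, collapse = ", "), ")"),
      "\n  ", length(x$snp_keys), "SNPs in", length(x$genes), "genes\n")
  invisible(x)
}

#' Genes carrying a missense variant private to a strain
#'
#' Identifies SNPs private to `strain` under the privacy rule, keeps those
#' with a missense annotation, and returns the union of annotated genes.
#'
#' @param mat A [strain_matrix()] with annotations attached.
#' @param strain Focal strain name.
#' @param rule A [privacy_rule()].
#' @return A `candidate_gene_set` with `snp_keys` (private missense SNPs)
#'   and `genes`.
#' @export
private_missense_gene_set <- function(mat, strain, rule = privacy_rule()) {
  if (!strain %in% mat$strains) stop("strain absent from panel: ", strain)
  priv <- identify_private_variants(mat, rule, vclass_filter = "SNP")[[strain]]
  ann <- filter_by_consequence(mat, "missense_variant")
  ann <- ann[key %in% priv]
  new_candidate_set(strain, character(), sort(unique(ann$key)),
                    sort(unique(ann$gene_id)),
                    list(method = "private_missense", rule = rule))
}

#' Strain-subtraction candidate gene set
#'
#' Starts from all high-quality homozygous-alternate SNPs of the target
#' strain, removes every site at which any exclude strain carries a
#' high-quality homozygous call for the same alternate allele (a
#' low-quality or missing genotype in an exclude strain does *not* remove
#' the site), then optionally retains only sites with at least one missense
#' annotation classified SIFT-deleterious. Genes are the union over the
#' retained missense annotations.
#'
#' @param mat A [strain_matrix()] with annotations.
#' @param target Target strain.
#' @param exclude_strains Strains whose shared alleles are subtracted.
#' @param require_deleterious Keep only SIFT-deleterious missense sites
#'   (default `TRUE`).
#' @param sift_threshold SIFT cutoff passed to [classify_sift()].
#' @return A `candidate_gene_set`.
#' @export
subtraction_candidate_set <- function(mat, target, exclude_strains,
                                      require_deleterious = TRUE,
                                      sift_threshold = 0.05) {
  if (target %in% exclude_strains) stop("target cannot be among exclude_strains")
  for (s in c(target, exclude_strains)) {
    if (!s %in% mat$strains) stop("strain absent from panel: ", s)
  }
  snp <- vclass_index(mat, "SNP")
  is_target <- mat$gt[, target] == GT_HOM_ALT & snp
  shared <- rep(FALSE, nrow(mat$sites))
  for (s in exclude_strains) shared <- shared | mat$gt[, s] == GT_HOM_ALT
  keep_keys <- mat$sites$key[is_target & !shared]
  ann <- score_annotations(filter_by_consequence(mat, "missense_variant"),
                           sift_threshold = sift_threshold)
  ann <- ann[key %in% keep_keys]
  if (require_deleterious) ann <- ann[sift_class == "deleterious"]
  new_candidate_set(target, exclude_strains, sort(unique(ann$key)),
                    sort(unique(ann$gene_id)),
                    list(method = "subtraction",
                         require_deleterious = require_deleterious,
                         sift_threshold = sift_threshold))
}

#' Write a candidate set as TSV plus a plain gene list
#'
#' @param cs A `candidate_gene_set`.
#' @param mat The matrix the set was derived from (for annotation columns).
#' @param tsv_path,genes_path Output paths (`NULL` to skip one of them).
#' @return Invisibly, the annotation table written.
#' @export
write_candidate_set <- function(cs, mat, tsv_path = NULL, genes_path = NULL) {
  ann <- score_annotations(mat$annotations[key %in% cs$snp_keys])
  data.table::setorder(ann, key, gene_id, transcript_id)
  if (!is.null(tsv_path)) {
    data.table::fwrite(ann, tsv_path, sep = "\t")
  }
  if (!is.null(genes_path)) {
    writeLines(cs$genes, genes_path)
  }
  invisible(ann)
}
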