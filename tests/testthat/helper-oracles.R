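# Independent brute-force oracles used across the suite. These re-state
# each rule in the most literal form available and must stay independent
# of the package implementation paths they check.

# Literal per-site evaluation of the privacy rule: exactly one strain is a
# high-quality homozygous alternate; no high-quality het among the others;
# at most max_ml of the others low-quality or missing; at least min_homref
# of the others high-quality homozygous reference.
oracle_private_variants <- function(gt, strains, min_homref, max_ml,
                                    keys = NULL, sites = NULL) {
  out <- stats::setNames(rep(list(character()), length(strains)), strains)
  if (is.null(keys)) keys <- as.character(seq_len(nrow(gt)))
  hits <- stats::setNames(rep(list(integer()), length(strains)), strains)
  for (i in seq_len(nrow(gt))) {
    cls <- gt[i, ]
    carrier <- which(cls == 2L)
    if (length(carrier) != 1L) next
    others <- cls[-carrier]
    if (any(others == 3L)) next
    if (sum(others == 4L | others == 5L) > max_ml) next
    if (sum(others == 1L) < min_homref) next
    s <- strains[carrier]
    hits[[s]] <- c(hits[[s]], i)
  }
  for (s in strains) {
    idx <- hits[[s]]
    if (!is.null(sites)) idx <- idx[order(sites$chrom[idx], sites$pos[idx])]
    out[[s]] <- keys[idx]
  }
  out
}

# O(n^2) reciprocal-overlap transitive closure via repeated BFS.
oracle_del_clusters <- function(svs, threshold = 0.9) {
  n <- nrow(svs)
  if (n == 0L) return(integer())
  adj <- matrix(FALSE, n, n)
  len <- svs$end - svs$start + 1L
  for (i in seq_len(n)) {
    # full row at a time: O(n^2) overall, no index structures
    ov <- pmin(svs$end[i], svs$end) - pmax(svs$start[i], svs$start) + 1L
    ro <- pmin(ov / len[i], ov / len)
    ro[ov <= 0L | svs$chrom != svs$chrom[i]] <- 0
    adj[i, ] <- ro > threshold
    adj[i, i] <- FALSE
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# canonical form of a clustering: sorted list of sorted member index sets
cluster_partition <- function(comp) {
  unname(lapply(split(seq_along(comp), comp), sort))
}
canonical_partition <- function(parts) {
  parts[order(vapply(parts, min, 0L))]
}

# exact upper-tail hypergeometric by enumerating all C(N, n) candidate
# draws from universe 1..N with the pathway being genes 1..K
oracle_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0L) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlap <- matrixStats_colSums(draws <= K)
  sum(overlap >= k) / ncol(draws)
}
matrixStats_colSums <- function(x) {
  if (is.matrix(x)) colSums(x) else sum(x)
}

# brute-force subtraction pipeline: literal set algebra over key sets
oracle_subtraction <- function(mat, target, excludes, require_deleterious,
                               sift_threshold = 0.05) {
  snp <- mat$sites$vclass == "SNP"
  target_keys <- mat$sites$key[snp & mat$gt[, target] == 2L]
  for (s in excludes) {
    shared <- mat$sites$key[mat$gt[, s] == 2L]
    target_keys <- setdiff(target_keys, shared)
  }
  ann <- mat$annotations
  is_mis <- vapply(strsplit(ann$consequence, "&", fixed = TRUE),
                   function(tt) "missense_variant" %in% tt, TRUE)
  ann <- ann[is_mis & ann$key %in% target_keys]
  if (require_deleterious) {
    del <- ifelse(!is.na(ann$sift_call), ann$sift_call == "deleterious",
                  !is.na(ann$sift_score) & ann$sift_score <= sift_threshold)
    ann <- ann[del]
  }
  list(keys = sort(unique(ann$key)), genes = sort(unique(ann$gene_id)))
}

# compact builder for hand-laid genotype matrices: rows of class codes
make_matrix <- function(gt_rows, strains = NULL, vclass = "SNP") {
  gt <- do.call(rbind, gt_rows)
  S <- ncol(gt)
  if (is.null(strains)) strains <- sprintf("S%02d", seq_len(S))
  n <- nrow(gt)
  ref <- rep("A", n)
  alt <- rep(if (vclass == "SNP") "T" else "TT", n)
  if (vclass == "DEL") { ref <- rep("AT", n); alt <- rep("A", n) }
  sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                      ref = ref, alt = alt)
  strain_matrix(strains, sites, gt)
}

# shorthand class codes
HR <- 1L; HA <- 2L; HE <- 3L; LQ <- 4L; MI <- 5L

write_temp_vcf <- function(lines) {
  path <- withr_local_tempfile()
  writeLines(lines, path)
  path
}
withr_local_tempfile <- function() tempfile(fileext = ".vcf")

minimal_vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FILTER=<ID=LowQual,Description=\"low quality\">",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations. Format: Gene|Feature|Consequence|Amino_acids|Protein_position|SIFT\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
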