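# Domain types and readers/writers for the external formats the pipeline
# consumes: multi-sample VCF with VEP-style CSQ annotations, GFF3/GTF/BED
# gene models, GMT pathway collections and tabular genotype panels.
#
# Genotype calls are held in a compact matrix representation (one integer
# code per strain per site) rather than one object per call; see
# strain_matrix() in genotype_catalog.R.

#' Genotype call classes
#'
#' Integer-coded classification of a per-strain genotype call at a variant
#' site. `HOM_REF_HQ` / `HOM_ALT_HQ` / `HET_HQ` are high-quality calls
#' (site passed all soft filters and genotype quality is at or above the
#' configured minimum). A call with a genotype present but failing quality
#' is `LOW_QUALITY`; an absent genotype (`./.`) is `MISSING`.
#'
#' @format Character vector of the five class labels, in code order.
#' @export
GT_CLASSES <- c("HOM_REF_HQ", "HOM_ALT_HQ", "HET_HQ", "LOW_QUALITY", "MISSING")

GT_HOM_REF <- 1L
GT_HOM_ALT <- 2L
GT_HET     <- 3L
GT_LOWQUAL <- 4L
GT_MISSING <- 5L

#' Quality configuration for genotype classification
#'
#' @param min_gq Minimum genotype quality (phred-like) for a call to count
#'   as high quality. Default 20.
#' @param require_pass If `TRUE` (default) the site-level FILTER column must
#'   be `PASS` (or `.`) for any call at the site to be high quality; soft
#'   filter failures downgrade calls to `LOW_QUALITY`.
#' @return A `quality_config` list.
#' @export
quality_config <- function(min_gq = 20, require_pass = TRUE) {
  stopifnot(is.numeric(min_gq), length(min_gq) == 1L, min_gq >= 0)
  structure(list(min_gq = as.numeric(min_gq), require_pass = isTRUE(require_pass)),
            class = "quality_config")
}

#' Classify one genotype string against one alternate allele
#'
#' Maps a raw VCF GT string (possibly referring to several alternate alleles
#' of the same row) to a class code with respect to a single alternate
#' allele index. A genotype homozygous for a *different* alternate allele of
#' the same row is treated as `HET_HQ`-equivalent: it is positive evidence
#' of segregation but neither reference evidence nor evidence for this
#' allele, which is the conservative choice for privacy calling.
#'
#' @param gt Character vector of GT strings (`"0/0"`, `"1/1"`, `"1|2"`, `"./."`).
#' @param allele_index Integer index (1-based among ALT alleles) of the
#'   alternate allele the site record represents.
#' @param pass Logical vector (recycled): site passed soft filters.
#' @param gq Numeric vector (recycled): genotype quality; `NA` treated as
#'   passing when GQ is absent from the file.
#' @param config A [quality_config()].
#' @return Integer vector of class codes (see [GT_CLASSES]).
#' @export
classify_gt <- function(gt, allele_index, pass = TRUE, gq = NA_real_,
                        config = quality_config()) {
  n <- length(gt)
  pass <- rep_len(pass, n)
  gq <- rep_len(gq, n)
  allele_index <- rep_len(as.integer(allele_index), n)
  out <- integer(n)
  alleles <- strsplit(gt, "[/|]")
  for (i in seq_len(n)) {
    a <- alleles[[i]]
    if (length(a) == 0L || any(a == ".") || any(is.na(a))) {
      out[i] <- GT_MISSING
      next
    }
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai)) {
      out[i] <- GT_MISSING
      next
    }
    lowq <- (config$require_pass && !pass[i]) ||
      (!is.na(gq[i]) && gq[i] < config$min_gq)
    if (lowq) {
      out[i] <- GT_LOWQUAL
    } else if (all(ai == 0L)) {
      out[i] <- GT_HOM_REF
    } else if (all(ai == allele_index[i])) {
      out[i] <- GT_HOM_ALT
    } else {
      # het for this allele, or any configuration involving another
      # alternate allele of the same row
      out[i] <- GT_HET
    }
  }
  out
}

variant_class <- function(ref, alt) {
  data.table::fifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNP",
    data.table::fifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
}

site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# ---------------------------------------------------------------------------
# VCF reading

default_csq_fields <- c("Gene", "Feature", "Consequence", "Amino_acids",
                        "Protein_position", "SIFT")

parse_csq_header <- function(hdr) {
  info <- VariantAnnotation::info(hdr)
  if (!"CSQ" %in% rownames(info)) return(default_csq_fields)
  desc <- info["CSQ", "Description"]
  m <- regmatches(desc, regexpr("Format: .*$", desc))
  if (length(m) == 0L) return(default_csq_fields)
  strsplit(sub("^Format: ", "", m), "|", fixed = TRUE)[[1]]
}

parse_sift_field <- function(x) {
  # VEP writes e.g. "deleterious(0.01)" or "tolerated(0.2)"; bare numbers
  # and bare calls are also accepted.
  call <- rep(NA_character_, length(x))
  score <- rep(NA_real_, length(x))
  has <- !is.na(x) & nzchar(x)
  m <- regmatches(x[has], regexec("^([a-z_]+)?\\(?([0-9.]+)?\\)?$", x[has]))
  call[has] <- vapply(m, function(g) if (length(g) >= 2 && nzchar(g[2])) g[2] else NA_character_, "")
  score[has] <- vapply(m, function(g) if (length(g) >= 3 && nzchar(g[3])) as.numeric(g[3]) else NA_real_, 0)
  call <- sub("_low_confidence$", "", call)
  list(call = call, score = score)
}

parse_csq_strings <- function(csq, keys, fields = default_csq_fields) {
  # csq: list parallel to keys, each element a character vector of CSQ
  # entries (one per transcript). Returns the annotation data.table.
  nper <- lengths(csq)
  if (sum(nper) == 0L) return(empty_annotations())
  flat <- unlist(csq, use.names = FALSE)
  key <- rep(keys, nper)
  parts <- data.table::tstrsplit(flat, "|", fixed = TRUE)
  get_field <- function(name) {
    i <- match(name, fields)
    if (is.na(i) || i > length(parts)) rep(NA_character_, length(flat)) else parts[[i]]
  }
  aa <- get_field("Amino_acids")
  aa2 <- data.table::tstrsplit(ifelse(is.na(aa), "", aa), "/", fixed = TRUE)
  aa_ref <- if (length(aa2) >= 1) aa2[[1]] else rep("", length(flat))
  aa_alt <- if (length(aa2) >= 2) aa2[[2]] else rep(NA_character_, length(flat))
  sift <- parse_sift_field(get_field("SIFT"))
  ann <- data.table::data.table(
    gene_id = get_field("Gene"),
    transcript_id = get_field("Feature"),
    consequence = get_field("Consequence"),
    aa_ref = ifelse(is.na(aa_ref), "", aa_ref),
    aa_pos = suppressWarnings(as.integer(get_field("Protein_position"))),
    aa_alt = ifelse(is.na(aa_alt), "", aa_alt),
    sift_score = sift$score,
    sift_call = sift$call
  )
  data.table::set(ann, j = "key", value = key)
  data.table::setcolorder(ann, "key")
  ann[]
}

empty_annotations <- function() {
  ann <- data.table::data.table(
    gene_id = character(), transcript_id = character(),
    consequence = character(), aa_ref = character(), aa_pos = integer(),
    aa_alt = character(), sift_score = numeric(), sift_call = character()
  )
  data.table::set(ann, j = "key", value = character())
  data.table::setcolorder(ann, "key")
  ann[]
}

#' Read a multi-sample VCF into a strain genotype matrix
#'
#' Reads SNP and indel records for a panel of strains, decomposes
#' multi-allelic rows into one record per alternate allele, and classifies
#' every genotype into one of the five classes of [GT_CLASSES] under the
#' supplied quality configuration. VEP-style `CSQ` INFO annotations, when
#' present, are parsed into the annotation table.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param panel Character vector of strain (sample) names, in the desired
#'   order. All must be present in the VCF; default is the file's samples.
#' @param config A [quality_config()].
#' @return A [strain_matrix()] object.
#' @export
read_multistrain_vcf <- function(path, panel = NULL, config = quality_config()) {
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (is.null(panel)) panel <- samples
  missing <- setdiff(panel, samples)
  if (length(missing) > 0L) {
    stop("panel strain(s) absent from VCF: ", paste(missing, collapse = ", "))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt_chr <- methods::as(altl, "CharacterList")
  n_alt <- lengths(alt_chr)
  filt <- VariantAnnotation::filt(vcf)
  pass <- filt %in% c("PASS", ".") | is.na(filt)
  gt_mat <- VariantAnnotation::geno(vcf)$GT
  gq_mat <- if ("GQ" %in% names(VariantAnnotation::geno(vcf))) {
    gqm <- VariantAnnotation::geno(vcf)$GQ
    storage.mode(gqm) <- "double"
    gqm
  } else {
    matrix(NA_real_, nrow = nrow(gt_mat), ncol = ncol(gt_mat),
           dimnames = dimnames(gt_mat))
  }
  csq <- if ("CSQ" %in% names(VariantAnnotation::info(vcf))) {
    as.list(VariantAnnotation::info(vcf)$CSQ)
  } else {
    rep(list(character()), length(rr))
  }
  csq_fields <- parse_csq_header(VariantAnnotation::header(vcf))

  # decompose: one output record per (row, alt allele)
  row_idx <- rep(seq_along(n_alt), n_alt)
  allele_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  alt <- unlist(alt_chr, use.names = FALSE)
  if (length(row_idx) == 0L) {
    return(strain_matrix(panel, sites = data.table::data.table(
      chrom = character(), pos = integer(), ref = character(), alt = character()),
      gt = matrix(integer(), 0, length(panel), dimnames = list(NULL, panel))))
  }
  out_chrom <- chrom[row_idx]
  out_pos <- pos[row_idx]
  out_ref <- ref[row_idx]
  keys <- site_key(out_chrom, out_pos, out_ref, alt)

  S <- length(panel)
  gt <- matrix(GT_MISSING, nrow = length(row_idx), ncol = S,
               dimnames = list(NULL, panel))
  raw <- matrix("./.", nrow = length(row_idx), ncol = S,
                dimnames = list(NULL, panel))
  gq <- matrix(NA_real_, nrow = length(row_idx), ncol = S,
               dimnames = list(NULL, panel))
  for (s in panel) {
    raw[, s] <- gt_mat[row_idx, s]
    gq[, s] <- gq_mat[row_idx, s]
    gt[, s] <- classify_gt(raw[, s], allele_idx, pass = pass[row_idx],
                           gq = gq[, s], config = config)
  }
  ann <- parse_csq_strings(csq[row_idx], keys, fields = csq_fields)
  sites <- data.table::data.table(chrom = out_chrom, pos = as.integer(out_pos),
                                  ref = out_ref, alt = alt)
  strain_matrix(panel, sites = sites, gt = gt, gq = gq, raw = raw,
                pass = pass[row_idx], annotations = ann, config = config)
}

#' Write a strain genotype matrix as a multi-sample VCF
#'
#' Emits a VCF 4.2 file carrying GT and GQ per strain, site-level FILTER
#' status and, when annotations are attached, a VEP-style `CSQ` INFO field.
#' Reading the file back with [read_multistrain_vcf()] under the same
#' quality configuration reproduces the genotype classifications exactly.
#'
#' @param mat A [strain_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multistrain_vcf <- function(mat, path) {
  stopifnot(inherits(mat, "strain_matrix"))
  sites <- mat$sites
  n <- nrow(sites)
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=LowQual,Description=\"Failed soft filters\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: ", paste(default_csq_fields, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", mat$strains), collapse = "\t")
  )
  writeLines(hdr, con)
  if (n == 0L) return(invisible(path))
  ann <- mat$annotations
  info <- rep(".", n)
  if (!is.null(ann) && nrow(ann) > 0L) {
    fmt_sift <- ifelse(is.na(ann$sift_call) & is.na(ann$sift_score), "",
      ifelse(is.na(ann$sift_score), ann$sift_call,
        paste0(ifelse(is.na(ann$sift_call), "", ann$sift_call),
               "(", format(ann$sift_score, trim = TRUE, scientific = FALSE), ")")))
    aa <- ifelse(nzchar(ann$aa_ref) | nzchar(ann$aa_alt),
                 paste0(ann$aa_ref, "/", ann$aa_alt), "")
    ent <- paste(ann$gene_id, ann$transcript_id, ann$consequence, aa,
                 ifelse(is.na(ann$aa_pos), "", ann$aa_pos), fmt_sift, sep = "|")
    by_key <- split(ent, factor(ann$key, levels = sites$key))
    has <- lengths(by_key) > 0L
    info[has] <- paste0("CSQ=", vapply(by_key[has], paste, "", collapse = ","))
  }
  filt <- if (!is.null(mat$pass)) ifelse(mat$pass, "PASS", "LowQual") else "PASS"
  gqm <- mat$gq
  sample_cols <- vapply(seq_len(n), function(i) {
    gqs <- ifelse(is.na(gqm[i, ]), ".", as.character(as.integer(gqm[i, ])))
    paste(paste0(mat$raw[i, ], ":", gqs), collapse = "\t")
  }, "")
  lines <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                 filt, info, "GT:GQ", sample_cols, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models

#' Read gene models (CDS intervals) from GFF3/GTF or BED
#'
#' CDS intervals are grouped per gene, sorted and merged (abutting or
#' overlapping intervals become one). BED input (0-based half-open) is
#' converted to the package's 1-based inclusive convention; the BED name
#' column supplies the gene identifier. GFF3/GTF `CDS` features use the
#' `gene_id` attribute, falling back to `Parent`/`ID`; CDS features without
#' any gene attribution are skipped with a warning.
#'
#' @param path Path to a `.gff3`/`.gff`/`.gtf` or `.bed` file.
#' @return A `data.table` with columns `gene_id`, `chrom`, `start`, `end`
#'   (one row per normalized CDS interval).
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "bed") {
    n_fields <- max(utils::count.fields(path, sep = "\t"), 0L)
    if (is.infinite(n_fields) || n_fields == 0L) {
      warning("no gene models in ", path)
      return(empty_gene_models())
    }
    bed <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(bed) < 4L) stop("BED gene models need a name (gene_id) column")
    dt <- data.table::data.table(gene_id = as.character(bed[[4]]),
                                 chrom = as.character(bed[[1]]),
                                 start = bed[[2]] + 1L, end = bed[[3]])
  } else {
    gr <- rtracklayer::import(path)
    gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
    meta <- S4Vectors::mcols(gr)
    gid <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id) else rep(NA_character_, length(gr))
    if ("Parent" %in% names(meta)) {
      par <- vapply(as.list(meta$Parent), function(p) if (length(p)) as.character(p[[1]]) else NA_character_, "")
      gid <- ifelse(is.na(gid) | !nzchar(gid), par, gid)
    }
    if ("ID" %in% names(meta)) {
      gid <- ifelse(is.na(gid) | !nzchar(gid), as.character(meta$ID), gid)
    }
    drop <- is.na(gid) | !nzchar(gid)
    if (any(drop)) warning(sum(drop), " CDS feature(s) without gene attribution skipped")
    gr <- gr[!drop]
    gid <- gid[!drop]
    dt <- data.table::data.table(gene_id = gid,
                                 chrom = as.character(GenomicRanges::seqnames(gr)),
                                 start = GenomicRanges::start(gr),
                                 end = GenomicRanges::end(gr))
  }
  if (nrow(dt) == 0L) {
    warning("no gene models in ", path)
    return(empty_gene_models())
  }
  normalize_gene_models(dt)
}

empty_gene_models <- function() {
  data.table::data.table(gene_id = character(), chrom = character(),
                         start = integer(), end = integer())
}

#' Normalize gene-model CDS intervals
#'
#' Sorts and merges per-gene CDS intervals; abutting intervals coalesce.
#'
#' @param dt `data.table` with `gene_id`, `chrom`, `start`, `end`.
#' @return Normalized `data.table`, same columns.
#' @export
normalize_gene_models <- function(dt) {
  dt <- data.table::as.data.table(dt)
  out <- dt[, {
    ir <- IRanges::reduce(IRanges::IRanges(start, end))
    list(start = IRanges::start(ir), end = IRanges::end(ir))
  }, by = .(gene_id, chrom)]
  data.table::setcolorder(out, c("gene_id", "chrom", "start", "end"))
  data.table::setorder(out, gene_id, chrom, start)
  out[]
}

# ---------------------------------------------------------------------------
# GMT pathways

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated `name`, `description`,
#' then gene identifiers. Duplicate genes within a line are deduplicated.
#' The database label is parsed from a `KEGG:` / `REACTOME:` prefix on the
#' pathway name when present, else `"other"`.
#'
#' @param path Path to a `.gmt` file.
#' @return A list of `pathway_set` lists with elements `pathway_id`, `name`,
#'   `database`, `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line ", i, ": fewer than 3 fields (need name, description, >=1 gene)")
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("GMT line ", i, ": empty gene list")
    db <- "other"
    nm <- f[1]
    if (grepl("^(KEGG|REACTOME):", nm)) {
      db <- sub(":.*$", "", nm)
      nm <- sub("^[A-Z]+:", "", nm)
    }
    out[[i]] <- structure(list(pathway_id = f[1], name = nm, database = db,
                               genes = genes), class = "pathway_set")
  }
  ids <- vapply(out, `[[`, "", "pathway_id")
  if (anyDuplicated(ids)) stop("duplicate pathway ids in GMT: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

#' Write pathway gene sets to GMT
#'
#' @param pathways List of `pathway_set` objects (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p) {
    paste(c(p$pathway_id, if (is.null(p$name)) "" else p$name, p$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
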