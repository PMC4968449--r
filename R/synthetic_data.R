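# Seeded generators for every input the pipeline consumes, each with a
# planted-truth sidecar: a strain panel with shared ancestral blocks and
# planted private variants, consequence annotations, jittered multi-caller
# SV call sets, pathway databases with one enriched pathway, and a
# concordance panel with a known discordance count.
#
# Each generator calls set.seed() on entry, so a fixed seed reproduces its
# output exactly (byte-identical once written). One global seed can be
# fanned out with fanout_seed() so modules regenerate independently.

#' Derive per-generator sub-seeds from one global seed
#'
#' @param seed Integer global seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` distinct seeds below 2^31.
#' @export
fanout_seed <- function(seed, n) {
  (as.integer(seed) * 1000003L + 7919L * seq_len(n)) %% 2147483647L
}

SYNTH_GENOME <- c(chr1 = 10e6, chr2 = 10e6)

synth_strains <- function(n) sprintf("STRAIN%02d", seq_len(n))

default_sharing_tree <- function(strains) {
  # nested clades from recursive halving of the strain order: emulates
  # blocks of ancestry shared by related strain groups
  clades <- list()
  recurse <- function(v) {
    if (length(v) < 2L) return(invisible())
    clades[[length(clades) + 1L]] <<- v
    h <- ceiling(length(v) / 2)
    recurse(v[seq_len(h)])
    recurse(v[-seq_len(h)])
  }
  recurse(strains)
  # drop the root (a variant in every strain is reference-relative noise,
  # not sharing structure we want to study) when alternatives exist
  if (length(clades) > 1L) clades <- clades[-1L]
  clades
}

#' Simulate a multi-strain genotype panel with planted private variants
#'
#' Builds a strains x sites genotype matrix over a small synthetic genome
#' (2 chromosomes x 10 Mb). Shared variants are assigned to clades of a
#' sharing tree (nested strain groupings, emulating shared ancestry
#' blocks); `n_private_per_strain` variants are planted homozygous
#' alternate in exactly one strain. Missing, low-quality and high-quality
#' heterozygous calls are then injected at the stated per-call rates, never
#' on the focal strain of a planted private site. When `rule` is supplied,
#' injections at planted private sites are additionally capped so the
#' planted verdict remains private under that rule (at most
#' `max_missing_lq` missing/low-quality comparators and no heterozygotes).
#'
#' @param n_strains Panel size (default 36).
#' @param n_sites Total variant sites (default 10000).
#' @param n_private_per_strain Planted private variants per strain.
#' @param missing_rate,lowqual_rate,het_rate Per-call injection rates.
#' @param indel_fraction Fraction of sites simulated as 1-2 bp indels
#'   rather than SNPs.
#' @param sharing_tree List of character vectors (clades); default nested
#'   halving of the strain order.
#' @param rule Optional [privacy_rule()] to guard planted sites.
#' @param strains Strain names (default `STRAIN01..`).
#' @param seed Integer seed.
#' @return List of class `panel_sim`: `matrix` (a [strain_matrix()]) and
#'   `truth` (planted private keys per strain, per-site verdicts, all
#'   parameters).
#' @export
simulate_strain_panel <- function(n_strains = 36, n_sites = 10000,
                                  n_private_per_strain = 20,
                                  missing_rate = 0.02, lowqual_rate = 0.02,
                                  het_rate = 0.005, indel_fraction = 0.2,
                                  sharing_tree = NULL, rule = NULL,
                                  strains = NULL, seed = 1) {
  if (missing_rate + lowqual_rate + het_rate > 1) {
    stop("combined injection rates exceed 1")
  }
  if (n_private_per_strain * n_strains > n_sites) {
    stop("n_private_per_strain * n_strains must not exceed n_sites")
  }
  set.seed(seed)
  if (is.null(strains)) strains <- synth_strains(n_strains)
  S <- length(strains)
  if (is.null(sharing_tree)) sharing_tree <- default_sharing_tree(strains)

  # site coordinates: unique positions spread over the genome
  chrom <- sample(names(SYNTH_GENOME), n_sites, replace = TRUE)
  pos <- integer(n_sites)
  for (cm in names(SYNTH_GENOME)) {
    i <- which(chrom == cm)
    pos[i] <- sort(sample.int(SYNTH_GENOME[[cm]] - 100L, length(i)))
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  is_indel <- runif(n_sites) < indel_fraction
  if (any(is_indel)) {
    del <- is_indel & runif(n_sites) < 0.5
    ins <- is_indel & !del
    ref[del] <- paste0(ref[del], sample(bases, sum(del), replace = TRUE))
    alt[del] <- substr(ref[del], 1L, 1L)
    alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))
  }

  gt <- matrix(GT_HOM_REF, n_sites, S, dimnames = list(NULL, strains))
  private_site <- sample.int(n_sites, n_private_per_strain * S)
  focal <- rep(seq_len(S), each = n_private_per_strain)
  gt[cbind(private_site, focal)] <- GT_HOM_ALT
  shared_site <- setdiff(seq_len(n_sites), private_site)
  clade_of <- sample.int(length(sharing_tree), length(shared_site), replace = TRUE)
  for (k in seq_along(shared_site)) {
    members <- match(sharing_tree[[clade_of[k]]], strains)
    gt[shared_site[k], members] <- GT_HOM_ALT
  }

  # noise injection
  u <- matrix(runif(n_sites * S), n_sites, S)
  inject <- matrix(0L, n_sites, S)   # 0 none, else class code
  inject[u < missing_rate] <- GT_MISSING
  inject[u >= missing_rate & u < missing_rate + lowqual_rate] <- GT_LOWQUAL
  inject[u >= missing_rate + lowqual_rate &
         u < missing_rate + lowqual_rate + het_rate] <- GT_HET
  inject[cbind(private_site, focal)] <- 0L   # never on the focal call
  if (!is.null(rule)) {
    r <- resolve_rule(rule, S)
    for (k in seq_along(private_site)) {
      i <- private_site[k]
      inject[i, inject[i, ] == GT_HET] <- 0L
      ml <- which(inject[i, ] %in% c(GT_LOWQUAL, GT_MISSING))
      if (length(ml) > r$max_missing_lq) {
        inject[i, ml[-seq_len(r$max_missing_lq)]] <- 0L
      }
    }
  }
  gt[inject != 0L] <- inject[inject != 0L]

  gq <- matrix(sample(30:99, n_sites * S, replace = TRUE), n_sites, S,
               dimnames = list(NULL, strains))
  gq[gt == GT_LOWQUAL] <- sample(0:19, sum(gt == GT_LOWQUAL), replace = TRUE)
  gq[gt == GT_MISSING] <- NA_real_
  raw <- matrix(c("0/0", "1/1", "0/1", NA, "./.")[gt], n_sites, S,
                dimnames = list(NULL, strains))
  # low-quality calls keep a plausible raw genotype
  raw[gt == GT_LOWQUAL] <- sample(c("0/0", "1/1", "0/1"),
                                  sum(gt == GT_LOWQUAL), replace = TRUE,
                                  prob = c(0.6, 0.3, 0.1))

  sites <- data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt)
  mat <- strain_matrix(strains, sites, gt, gq = gq, raw = raw)

  keys <- mat$sites$key
  planted <- split(keys[private_site], strains[focal])
  # keys sorted by (chrom, pos): sites are already in coordinate order
  planted <- lapply(planted, function(k) k[order(match(k, keys))])
  planted <- planted[strains[strains %in% names(planted)]]
  verdict <- rep(NA_character_, n_sites)
  if (!is.null(rule)) {
    pv <- identify_private_variants(mat, rule)
    for (s in names(pv)) verdict[match(pv[[s]], keys)] <- s
  } else {
    verdict[private_site] <- strains[focal]
  }
  truth <- list(private = planted,
                verdict = {
                  v <- data.table::data.table(private_to = verdict)
                  data.table::set(v, j = "key", value = keys)
                  data.table::setcolorder(v, "key")
                  v
                },
                params = list(n_strains = S, n_sites = n_sites,
                              n_private_per_strain = n_private_per_strain,
                              missing_rate = missing_rate,
                              lowqual_rate = lowqual_rate,
                              het_rate = het_rate,
                              indel_fraction = indel_fraction,
                              rule_guarded = !is.null(rule)),
                seed = seed)
  structure(list(matrix = mat, truth = truth), class = "panel_sim")
}

#' Attach simulated consequence annotations to a panel
#'
#' Every SNP site receives one primary annotation: missense (with a random
#' standard-residue amino-acid change and a SIFT score drawn below 0.05
#' for the declared deleterious fraction, above it otherwise), stop-gained,
#' synonymous, or a non-coding term. A fraction of missense sites gains a
#' second transcript annotated synonymous, exercising the
#' multiple-consequences-per-variant semantics. Genes are drawn from a
#' catalogue of `gene_catalog_size` identifiers.
#'
#' @param sim A `panel_sim` from [simulate_strain_panel()].
#' @param gene_catalog_size Number of gene identifiers.
#' @param missense_fraction,deleterious_fraction,stopgain_fraction
#'   Fractions in `[0, 1]`: sites that are missense; missense sites that
#'   are SIFT-deleterious; sites that are stop-gained.
#' @param second_transcript_fraction Missense sites also annotated on a
#'   second transcript.
#' @param seed Integer seed.
#' @return The `panel_sim` with `matrix$annotations` filled and
#'   `truth$annotations` recording planted missense / deleterious /
#'   stop-gain site keys and the per-gene mapping.
#' @export
simulate_annotations <- function(sim, gene_catalog_size = 100,
                                 missense_fraction = 0.3,
                                 deleterious_fraction = 0.3,
                                 stopgain_fraction = 0.02,
                                 second_transcript_fraction = 0.1,
                                 seed = 1) {
  stopifnot(inherits(sim, "panel_sim"))
  for (f in c(missense_fraction, deleterious_fraction, stopgain_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  set.seed(seed)
  mat <- sim$matrix
  snp <- which(vclass_index(mat, "SNP"))
  keys <- mat$sites$key[snp]
  n <- length(keys)
  genes <- sprintf("G%04d", sample.int(gene_catalog_size, n, replace = TRUE))
  u <- runif(n)
  kind <- ifelse(u < missense_fraction, "missense_variant",
          ifelse(u < missense_fraction + stopgain_fraction, "stop_gained",
          ifelse(u < missense_fraction + stopgain_fraction + 0.2,
                 "synonymous_variant",
                 sample(c("intron_variant", "intergenic_variant",
                          "upstream_gene_variant"), n, replace = TRUE))))
  aa <- rownames(grantham_matrix())
  is_mis <- kind == "missense_variant"
  aa_ref <- ifelse(is_mis, sample(aa, n, replace = TRUE), "")
  aa_alt <- rep("", n)
  aa_alt[is_mis] <- vapply(aa_ref[is_mis],
                           function(a) sample(setdiff(aa, a), 1L), "")
  deleterious <- is_mis & runif(n) < deleterious_fraction
  sift <- rep(NA_real_, n)
  sift[is_mis] <- round(ifelse(deleterious[is_mis],
                               runif(sum(is_mis), 0, 0.05),
                               runif(sum(is_mis), 0.06, 1)), 3)
  ann <- data.table::data.table(
    gene_id = genes,
    transcript_id = paste0(genes, ".T1"),
    consequence = kind,
    aa_ref = aa_ref,
    aa_pos = ifelse(is_mis | kind == "stop_gained",
                    sample.int(500L, n, replace = TRUE), NA_integer_),
    aa_alt = aa_alt,
    sift_score = sift,
    sift_call = ifelse(is_mis, ifelse(deleterious, "deleterious", "tolerated"),
                       NA_character_))
  data.table::set(ann, j = "key", value = keys)
  data.table::setcolorder(ann, "key")
  second <- is_mis & runif(n) < second_transcript_fraction
  if (any(second)) {
    ann2 <- ann[second]
    ann2[, transcript_id := paste0(gene_id, ".T2")]
    ann2[, consequence := "synonymous_variant"]
    ann2[, `:=`(aa_ref = "", aa_alt = "", aa_pos = NA_integer_,
                sift_score = NA_real_, sift_call = NA_character_)]
    ann <- rbind(ann, ann2)
  }
  data.table::setorder(ann, key, transcript_id)
  sim$matrix$annotations <- ann
  sim$truth$annotations <- list(
    missense_keys = sort(keys[is_mis]),
    deleterious_keys = sort(keys[deleterious]),
    stopgain_keys = sort(keys[kind == "stop_gained"]),
    gene_of = setNames(genes, keys),
    params = list(gene_catalog_size = gene_catalog_size,
                  missense_fraction = missense_fraction,
                  deleterious_fraction = deleterious_fraction,
                  stopgain_fraction = stopgain_fraction),
    seed = seed)
  sim
}

#' Simulate multi-caller structural-variant call sets with planted clusters
#'
#' Plants `n_true` well-separated events on the synthetic genome. Each
#' event occurs in one strain (private) or a random subset of at least two
#' strains, per `shared_across_strains`. Every carrying strain emits one
#' call per caller with endpoint jitter bounded so that, for deletions, all
#' intra-cluster reciprocal overlaps stay above `ro_guarantee` by
#' construction (generation fails if the bound cannot hold); insertion
#' jitter is bounded by half the merge window.
#'
#' @param n_true Number of planted events.
#' @param callers Caller labels (one call per caller per carrying strain).
#' @param jitter_sd_bp Gaussian endpoint jitter SD, truncated to the
#'   guarantee bound.
#' @param shared_across_strains Fraction of events carried by more than one
#'   strain.
#' @param n_strains Panel size.
#' @param svtype `"DEL"` or `"INS"`.
#' @param min_len,max_len Event length range (deletions).
#' @param ro_guarantee Intra-cluster reciprocal-overlap floor (default
#'   0.92, above the 0.9 merge threshold).
#' @param ins_window Insertion merge window the jitter must respect.
#' @param strains Strain names.
#' @param seed Integer seed.
#' @return List of class `sv_sim`: `svs` (an [sv_table()]) and `truth`
#'   (per-call true cluster ids, per-cluster carrying strains and private
#'   flags).
#' @export
simulate_sv_callsets <- function(n_true = 40,
                                 callers = c("breakdancer", "cnd", "lumpy"),
                                 jitter_sd_bp = 5, shared_across_strains = 0.3,
                                 n_strains = 3, svtype = "DEL",
                                 min_len = 300, max_len = 5000,
                                 ro_guarantee = 0.92, ins_window = 100,
                                 strains = NULL, seed = 1) {
  stopifnot(svtype %in% c("DEL", "INS"))
  if (svtype == "DEL") {
    # the per-endpoint jitter bound that keeps all intra-cluster pairwise
    # reciprocal overlaps above ro_guarantee for the shortest event
    cap_min <- floor(min_len * (1 - ro_guarantee) / (4 * (1 + ro_guarantee)) * 2)
    if (jitter_sd_bp > cap_min) {
      stop("jitter_sd_bp incompatible with the reciprocal-overlap guarantee ",
           "(max ", cap_min, " bp for min_len = ", min_len, ")")
    }
  } else if (jitter_sd_bp > ins_window / 2) {
    stop("jitter_sd_bp incompatible with the insertion window guarantee")
  }
  set.seed(seed)
  if (is.null(strains)) strains <- synth_strains(n_strains)
  genome <- SYNTH_GENOME
  spacing <- max_len * 3 + 50000
  per_chrom <- floor(genome / spacing)
  if (n_true > sum(per_chrom)) stop("too many events for the synthetic genome")
  slots <- unlist(lapply(names(genome), function(cm) {
    paste(cm, seq_len(per_chrom[[cm]]))
  }))
  chosen <- sort(sample(seq_along(slots), n_true))
  slot_chrom <- sub(" .*", "", slots[chosen])
  slot_idx <- as.integer(sub(".* ", "", slots[chosen]))
  start <- as.integer((slot_idx - 1L) * spacing + 25000 +
                        sample.int(10000L, n_true, replace = TRUE))
  len <- if (svtype == "DEL") sample(min_len:max_len, n_true, replace = TRUE)
         else rep(1L, n_true)
  end <- start + len - 1L
  shared <- runif(n_true) < shared_across_strains & length(strains) >= 2L
  carriers <- lapply(seq_len(n_true), function(i) {
    if (shared[i]) sort(sample(strains, sample(2:length(strains), 1L)))
    else sample(strains, 1L)
  })

  rows <- list()
  for (i in seq_len(n_true)) {
    if (svtype == "DEL") {
      # |jitter| <= cap on each endpoint keeps pairwise RO >=
      # (len - 4*cap) / (len + 4*cap) > ro_guarantee
      cap <- floor(len[i] * (1 - ro_guarantee) / (4 * (1 + ro_guarantee)) * 2)
      if (cap < 0) stop("jitter incompatible with reciprocal-overlap guarantee")
    } else {
      cap <- floor(ins_window / 2)
    }
    for (s in carriers[[i]]) {
      for (cl in callers) {
        j1 <- max(-cap, min(cap, round(stats::rnorm(1, 0, jitter_sd_bp))))
        j2 <- max(-cap, min(cap, round(stats::rnorm(1, 0, jitter_sd_bp))))
        st <- start[i] + j1
        en <- if (svtype == "DEL") end[i] + j2 else st
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = slot_chrom[i], start = st, end = en, svtype = svtype,
          strain = s, caller = cl, true_cluster = i)
      }
    }
  }
  calls <- data.table::rbindlist(rows)
  if (svtype == "DEL") {
    bad <- calls[, {
      ro <- outer(seq_len(.N), seq_len(.N), function(a, b)
        reciprocal_overlap(start[a], end[a], start[b], end[b]))
      list(minro = min(ro))
    }, by = true_cluster][minro <= 0.9]
    if (nrow(bad) > 0L) stop("jitter violated the reciprocal-overlap guarantee")
  }
  svs <- sv_table(calls$chrom, calls$start, calls$end, calls$svtype,
                  calls$strain, calls$caller,
                  ins_length = if (svtype == "INS") 300L else NA_integer_)
  truth <- list(
    call_cluster = calls$true_cluster,
    clusters = data.table::data.table(
      true_cluster = seq_len(n_true), chrom = slot_chrom,
      start = start, end = end,
      strains = vapply(carriers, paste, "", collapse = ","),
      private = !shared),
    params = list(n_true = n_true, callers = callers,
                  jitter_sd_bp = jitter_sd_bp,
                  shared_across_strains = shared_across_strains,
                  svtype = svtype, ro_guarantee = ro_guarantee,
                  ins_window = ins_window),
    seed = seed)
  structure(list(svs = svs, truth = truth), class = "sv_sim")
}

#' Simulate a pathway database with one planted enriched pathway
#'
#' Builds `n_pathways` gene sets over a universe of `universe_size` genes
#' and draws a candidate gene set preferentially (weight
#' `enriched_pathway_draw_weight` per gene) from one designated pathway.
#' Weight 1 is the null.
#'
#' @param n_pathways,genes_per_pathway,universe_size Database dimensions.
#' @param enriched_pathway_draw_weight Sampling weight (>= 1) applied to
#'   genes of the enriched pathway when drawing candidates.
#' @param candidate_set_size Number of candidate genes drawn.
#' @param seed Integer seed.
#' @return List of class `pathway_sim`: `pathways` (list of `pathway_set`),
#'   `candidates`, `universe`, `truth` (enriched pathway id and weight).
#' @export
simulate_pathway_db <- function(n_pathways = 20, genes_per_pathway = 50,
                                universe_size = 1000,
                                enriched_pathway_draw_weight = 20,
                                candidate_set_size = 50, seed = 1) {
  if (enriched_pathway_draw_weight < 1) stop("draw weight must be >= 1")
  if (candidate_set_size > universe_size) {
    stop("candidate_set_size must not exceed universe_size")
  }
  set.seed(seed)
  universe <- sprintf("G%05d", seq_len(universe_size))
  dbs <- rep(c("KEGG", "REACTOME"), length.out = n_pathways)
  pathways <- lapply(seq_len(n_pathways), function(i) {
    structure(list(pathway_id = sprintf("%s:P%03d", dbs[i], i),
                   name = sprintf("P%03d", i), database = dbs[i],
                   genes = sort(sample(universe, genes_per_pathway))),
              class = "pathway_set")
  })
  enriched <- sample.int(n_pathways, 1L)
  w <- ifelse(universe %in% pathways[[enriched]]$genes,
              enriched_pathway_draw_weight, 1)
  candidates <- sample(universe, candidate_set_size, prob = w)
  structure(list(pathways = pathways, candidates = sort(candidates),
                 universe = universe,
                 truth = list(enriched_pathway = pathways[[enriched]]$pathway_id,
                              weight = enriched_pathway_draw_weight,
                              seed = seed)),
            class = "pathway_sim")
}

#' Derive a concordance panel from simulated truth with planted discordances
#'
#' Copies callable genotypes of the selected strains from the simulated
#' matrix into a panel table, then flips exactly `discordance_count`
#' entries to a different homozygous genotype.
#'
#' @param sim A `panel_sim`.
#' @param discordance_count Number of entries to flip.
#' @param strains Strains to include (default: full panel).
#' @param seed Integer seed.
#' @return List: `panel` (`data.table` with `chrom`, `pos`, `strain`,
#'   `allele1`, `allele2`) and `truth` (flipped row indices and expected
#'   per-strain rates).
#' @export
simulate_panel_from_truth <- function(sim, discordance_count = 0,
                                      strains = NULL, seed = 1) {
  stopifnot(inherits(sim, "panel_sim"))
  set.seed(seed)
  mat <- sim$matrix
  if (is.null(strains)) strains <- mat$strains
  snp <- which(vclass_index(mat, "SNP"))
  rows <- list()
  for (s in strains) {
    cls <- mat$gt[snp, s]
    callable <- cls %in% c(GT_HOM_REF, GT_HOM_ALT)   # hom sites only, HapMap-style
    i <- snp[callable]
    g <- ifelse(mat$gt[i, s] == GT_HOM_REF, mat$sites$ref[i], mat$sites$alt[i])
    rows[[s]] <- data.table::data.table(chrom = mat$sites$chrom[i],
                                        pos = mat$sites$pos[i], strain = s,
                                        allele1 = g, allele2 = g)
  }
  panel <- data.table::rbindlist(rows)
  if (discordance_count > nrow(panel)) {
    stop("discordance_count exceeds panel size")
  }
  flip <- sort(sample.int(nrow(panel), discordance_count))
  if (length(flip) > 0L) {
    bases <- c("A", "C", "G", "T")
    newb <- vapply(panel$allele1[flip],
                   function(b) sample(setdiff(bases, b), 1L), "")
    panel[flip, `:=`(allele1 = newb, allele2 = newb)]
  }
  list(panel = panel,
       truth = list(flipped = flip, n_entries = nrow(panel),
                    discordance_count = discordance_count, seed = seed))
}

#' Write a panel simulation to disk (VCF + JSON truth sidecar)
#'
#' @param sim A `panel_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_panel_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "panel.vcf")
  truth <- file.path(dir, "panel.truth.json")
  write_multistrain_vcf(sim$matrix, vcf)
  jsonlite::write_json(sim$truth, truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(vcf = vcf, truth = truth))
}
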