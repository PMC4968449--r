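# Post-processing of per-caller structural-variant call sets: proximity
# and size filtering, within-strain reciprocal-overlap merging,
# cross-strain privacy, CDS overlap and validation sensitivity.

#' Construct a structural-variant table
#'
#' @param chrom,start,end Interval coordinates, 1-based inclusive.
#' @param svtype `"DEL"` or `"INS"` (vectorized). Insertions may have
#'   `end == start` (point insertions).
#' @param strain,caller Provenance labels; unknown callers are allowed and
#'   rank below the configured priority list when choosing representatives.
#' @param ins_length Inserted length for `INS` records (deletion length is
#'   `end - start + 1`).
#' @return `data.table` with one row per call and an `sv_id` column.
#' @export
sv_table <- function(chrom, start, end, svtype, strain, caller = "other",
                     ins_length = NA_integer_) {
  dt <- data.table::data.table(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), svtype = as.character(svtype),
    strain = as.character(strain), caller = as.character(caller))
  if (any(dt$start > dt$end)) stop("start > end in SV table")
  if (!all(dt$svtype %in% c("DEL", "INS"))) stop("svtype must be DEL or INS")
  dt[, length_bp := ifelse(svtype == "DEL", end - start + 1L,
                           as.integer(rep_len(ins_length, .N)))]
  dt[, sv_id := seq_len(.N)]
  dt[]
}

#' Read a BED-like SV call table
#'
#' Tab-separated columns `chrom, start, end, svtype, strain, caller`
#' (header optional); BED convention (0-based half-open) converted to
#' 1-based inclusive.
#'
#' @param path File path.
#' @return SV `data.table` as from [sv_table()].
#' @export
read_sv_bed <- function(path) {
  dt <- data.table::fread(path, header = "auto",
                          col.names = c("chrom", "start", "end", "svtype",
                                        "strain", "caller"))
  sv_table(dt$chrom, dt$start + 1L, dt$end, dt$svtype, dt$strain, dt$caller)
}

interval_distance <- function(a_start, a_end, b_start, b_end) {
  # bp separation between two closed intervals; 0 when overlapping/abutting
  pmax(0L, pmax(b_start - a_end, a_start - b_end))
}

#' Filter SV calls near assembly gaps/telomeres and oversized calls
#'
#' A call is removed when its span comes within `gap_pad` bp of any
#' assembly-gap interval, within `telo_pad` bp of any telomere/centromere
#' interval, or when its length exceeds `max_len`.
#'
#' @param svs SV `data.table` ([sv_table()]).
#' @param assembly_gaps,telomere_centromere `data.frame`s with `chrom`,
#'   `start`, `end` (1-based inclusive), or `NULL` to skip that filter.
#' @param gap_pad,telo_pad Proximity pads in bp (defaults 500 and 20000;
#'   a separation of exactly the pad is still removed).
#' @param max_len Maximum retained length in bp (default 1e6, strict).
#' @return List with `retained` (SV table) and `rejected` (SV table with a
#'   `reason` column).
#' @export
filter_svs <- function(svs, assembly_gaps = NULL, telomere_centromere = NULL,
                       gap_pad = 500, telo_pad = 20000, max_len = 1e6) {
  near_any <- function(track, pad) {
    if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, nrow(svs)))
    track <- data.table::as.data.table(track)
    out <- rep(FALSE, nrow(svs))
    for (cm in unique(svs$chrom)) {
      i <- which(svs$chrom == cm)
      tk <- track[chrom == cm]
      if (nrow(tk) == 0L) next
      for (j in i) {
        d <- interval_distance(svs$start[j], svs$end[j], tk$start, tk$end)
        if (any(d <= pad)) out[j] <- TRUE
      }
    }
    out
  }
  too_long <- !is.na(svs$length_bp) & svs$length_bp > max_len
  near_gap <- near_any(assembly_gaps, gap_pad)
  near_telo <- near_any(telomere_centromere, telo_pad)
  reason <- rep(NA_character_, nrow(svs))
  reason[near_telo] <- "telomere_centromere"
  reason[near_gap] <- "assembly_gap"
  reason[too_long] <- "max_length"   # size rule reported first
  drop <- !is.na(reason)
  list(retained = svs[!drop],
       rejected = cbind(svs[drop], reason = reason[drop]))
}

#' Reciprocal overlap of two intervals
#'
#' `min(overlap / len_a, overlap / len_b)`, in `[0, 1]`; 0 for intervals on
#' different chromosomes or disjoint intervals, 1 iff identical.
#'
#' @param a_start,a_end,b_start,b_end 1-based inclusive bounds (vectorized).
#' @param a_chrom,b_chrom Optional chromosome names; mismatch gives 0.
#' @return Numeric vector of reciprocal overlaps.
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end,
                               a_chrom = NULL, b_chrom = NULL) {
  ov <- pmin(a_end, b_end) - pmax(a_start, b_start) + 1L
  ov <- pmax(ov, 0L)
  ro <- pmin(ov / (a_end - a_start + 1L), ov / (b_end - b_start + 1L))
  if (!is.null(a_chrom) && !is.null(b_chrom)) ro[a_chrom != b_chrom] <- 0
  ro
}

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

components_from_pairs <- function(n, pi, pj) {
  parent <- seq_len(n)
  for (k in seq_along(pi)) {
    ri <- uf_find(parent, pi[k]); rj <- uf_find(parent, pj[k])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  match(roots, unique(roots))
}

#' Caller priority for representative (primary breakpoint) selection
#' @export
DEFAULT_CALLER_PRIORITY <- c("breakdancer", "lumpy", "cnd")

choose_representative <- function(members, caller_priority) {
  pr <- match(members$caller, caller_priority)
  pr[is.na(pr)] <- length(caller_priority) + 1L
  ord <- order(pr, members$start, members$end, members$caller)
  members[ord[1L]]
}

build_clusters <- function(svs, comp, caller_priority) {
  svs <- data.table::copy(svs)
  svs[, cluster_id := comp]
  clusters <- svs[, {
    rep_m <- choose_representative(.SD, caller_priority)
    list(chrom = chrom[1L],
         primary_start = rep_m$start, primary_end = rep_m$end,
         primary_caller = rep_m$caller,
         secondary_start = min(start), secondary_end = max(end),
         svtype = svtype[1L], n_members = .N,
         strains = list(sort(unique(strain))),
         members = list(data.table::copy(.SD)))
  }, by = cluster_id]
  # deterministic order independent of input order
  data.table::setorder(clusters, chrom, secondary_start, secondary_end,
                       primary_start, primary_end)
  clusters[, cluster_id := seq_len(.N)]
  clusters[]
}

#' Merge within-strain deletion calls by reciprocal overlap
#'
#' Single-linkage merging: clusters are the connected components of the
#' relation "reciprocal overlap strictly greater than `threshold`" (a pair
#' at exactly the threshold does not merge). Each cluster carries primary
#' breakpoints (from the highest-priority caller's member, ties broken by
#' `(start, end, caller)`) and secondary breakpoints (the outer bounds over
#' members). The result is deterministic regardless of input order.
#'
#' @param svs SV `data.table` of `DEL` calls (single strain expected for
#'   the within-strain merge; mixed strains are allowed and recorded).
#' @param threshold Reciprocal-overlap threshold, default 0.9 (strict).
#' @param caller_priority Character vector ranking callers for primary
#'   breakpoint selection.
#' @param max_span Optional cap (bp): pairs are only linked when the union
#'   span of the growing cluster cannot exceed this; `Inf` disables.
#' @return `data.table` of clusters with `cluster_id`, `chrom`,
#'   `primary_start/end`, `secondary_start/end`, `n_members`, `strains`
#'   (list column) and `members` (list column of member SV tables).
#' @export
merge_deletions <- function(svs, threshold = 0.9,
                            caller_priority = DEFAULT_CALLER_PRIORITY,
                            max_span = Inf) {
  if (nrow(svs) == 0L) return(empty_clusters())
  if (!all(svs$svtype == "DEL")) stop("merge_deletions requires all-DEL input")
  ir <- IRanges::IRanges(svs$start, svs$end)
  hits <- IRanges::findOverlaps(ir, ir)
  qi <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
  keep <- qi < sj & svs$chrom[qi] == svs$chrom[sj]
  qi <- qi[keep]; sj <- sj[keep]
  ro <- reciprocal_overlap(svs$start[qi], svs$end[qi], svs$start[sj], svs$end[sj])
  link <- ro > threshold
  if (is.finite(max_span)) {
    span <- pmax(svs$end[qi], svs$end[sj]) - pmin(svs$start[qi], svs$start[sj]) + 1L
    link <- link & span <= max_span
  }
  comp <- components_from_pairs(nrow(svs), qi[link], sj[link])
  build_clusters(svs, comp, caller_priority)
}

empty_clusters <- function() {
  data.table::data.table(cluster_id = integer(), chrom = character(),
                         primary_start = integer(), primary_end = integer(),
                         primary_caller = character(),
                         secondary_start = integer(), secondary_end = integer(),
                         svtype = character(), n_members = integer(),
                         strains = list(), members = list())
}

#' Merge insertion calls by breakpoint proximity
#'
#' Reciprocal overlap is degenerate for point insertions, so insertions are
#' single-linkage clustered when their breakpoints lie within `window` bp
#' on the same chromosome (separation of exactly `window` merges).
#'
#' @param svs SV `data.table` of `INS` calls.
#' @param window Breakpoint window in bp, default 100.
#' @inheritParams merge_deletions
#' @return Cluster `data.table` as in [merge_deletions()].
#' @export
merge_insertions <- function(svs, window = 100,
                             caller_priority = DEFAULT_CALLER_PRIORITY) {
  if (nrow(svs) == 0L) return(empty_clusters())
  if (!all(svs$svtype == "INS")) stop("merge_insertions requires all-INS input")
  ord <- order(svs$chrom, svs$start)
  comp_sorted <- integer(nrow(svs))
  cid <- 0L
  prev_chrom <- ""
  prev_pos <- -Inf
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (svs$chrom[i] != prev_chrom || svs$start[i] - prev_pos > window) cid <- cid + 1L
    comp_sorted[i] <- cid
    prev_chrom <- svs$chrom[i]
    prev_pos <- svs$start[i]
  }
  build_clusters(svs, comp_sorted, caller_priority)
}

cluster_relation <- function(cl_a, cl_b, threshold, window, svtype) {
  # does any cluster of b satisfy the merge relation with cluster row a?
  same <- cl_b$chrom == cl_a$chrom
  if (!any(same)) return(FALSE)
  b <- cl_b[same]
  if (svtype == "DEL") {
    any(reciprocal_overlap(cl_a$secondary_start, cl_a$secondary_end,
                           b$secondary_start, b$secondary_end) > threshold)
  } else {
    any(abs(b$secondary_start - cl_a$secondary_start) <= window)
  }
}

#' Identify clusters private to each strain
#'
#' A strain's merged cluster is private when no cluster of any other strain
#' satisfies the merge relation with it (reciprocal overlap above the
#' threshold for deletions; breakpoint window for insertions), i.e. it
#' would not have merged with any other strain's call.
#'
#' @param per_strain_clusters Named list (strain -> cluster `data.table`
#'   from [merge_deletions()] or [merge_insertions()]).
#' @param threshold Reciprocal-overlap threshold for deletions.
#' @param window Breakpoint window for insertions.
#' @return Named list (strain -> cluster `data.table` with a `private`
#'   logical column added).
#' @export
cross_strain_private_svs <- function(per_strain_clusters, threshold = 0.9,
                                     window = 100) {
  strains <- names(per_strain_clusters)
  out <- per_strain_clusters
  for (s in strains) {
    cl <- data.table::copy(per_strain_clusters[[s]])
    if (nrow(cl) == 0L) { out[[s]] <- cl; next }
    others <- data.table::rbindlist(per_strain_clusters[setdiff(strains, s)],
                                    use.names = TRUE, fill = TRUE)
    priv <- logical(nrow(cl))
    for (i in seq_len(nrow(cl))) {
      priv[i] <- nrow(others) == 0L ||
        !cluster_relation(cl[i], others, threshold, window, cl$svtype[i])
    }
    cl[, private := priv]
    out[[s]] <- cl
  }
  out
}

#' CDS overlap of SV clusters against gene models
#'
#' Tests each cluster's secondary (outer) bounds against CDS intervals only
#' (not whole gene bodies).
#'
#' @param clusters Cluster `data.table`.
#' @param gene_models Normalized gene models ([read_gene_models()]).
#' @return List with `hits` (`data.table` of `cluster_id`, `gene_id`),
#'   `n_clusters_hit` and `n_genes_hit`.
#' @export
cds_overlap <- function(clusters, gene_models) {
  if (nrow(clusters) == 0L || nrow(gene_models) == 0L) {
    return(list(hits = data.table::data.table(cluster_id = integer(),
                                              gene_id = character()),
                n_clusters_hit = 0L, n_genes_hit = 0L))
  }
  res <- list()
  for (cm in unique(clusters$chrom)) {
    cl <- clusters[chrom == cm]
    gm <- gene_models[chrom == cm]
    if (nrow(gm) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(cl$secondary_start, cl$secondary_end),
      IRanges::IRanges(gm$start, gm$end))
    if (length(hits) == 0L) next
    res[[cm]] <- unique(data.table::data.table(
      cluster_id = cl$cluster_id[S4Vectors::queryHits(hits)],
      gene_id = gm$gene_id[S4Vectors::subjectHits(hits)]))
  }
  hits <- if (length(res)) data.table::rbindlist(res) else
    data.table::data.table(cluster_id = integer(), gene_id = character())
  data.table::setorder(hits, cluster_id, gene_id)
  list(hits = hits,
       n_clusters_hit = length(unique(hits$cluster_id)),
       n_genes_hit = length(unique(hits$gene_id)))
}

#' Sensitivity of a call set against validated intervals
#'
#' Compares called clusters with externally validated intervals. Validated
#' intervals annotated as true inter-strain differences are excluded from
#' the comparable set. A validated interval counts as found when it
#' overlaps at least one called cluster under `overlap_rule` (`"any"`:
#' 1-bp overlap; `"reciprocal"`: reciprocal overlap above `threshold`).
#'
#' @param called Cluster `data.table` (or any table with `chrom`,
#'   `secondary_start`/`secondary_end` or `start`/`end`).
#' @param validated `data.frame` with `chrom`, `start`, `end`.
#' @param excluded Optional subset of `validated` rows (same columns) to
#'   exclude as true differences.
#' @param overlap_rule `"any"` (default) or `"reciprocal"`.
#' @param threshold Reciprocal-overlap threshold when
#'   `overlap_rule = "reciprocal"`.
#' @return List with `n_found`, `n_comparable`, `sensitivity` (percent;
#'   `NA` with `defined = FALSE` when nothing is comparable).
#' @export
validation_sensitivity <- function(called, validated, excluded = NULL,
                                   overlap_rule = c("any", "reciprocal"),
                                   threshold = 0.9) {
  overlap_rule <- match.arg(overlap_rule)
  validated <- data.table::as.data.table(validated)
  if (!is.null(excluded) && nrow(excluded) > 0L) {
    excluded <- data.table::as.data.table(excluded)
    vk <- paste(validated$chrom, validated$start, validated$end)
    ek <- paste(excluded$chrom, excluded$start, excluded$end)
    validated <- validated[!vk %in% ek]
  }
  n_comparable <- nrow(validated)
  if (n_comparable == 0L) {
    return(list(n_found = 0L, n_comparable = 0L, sensitivity = NA_real_,
                defined = FALSE))
  }
  called <- data.table::as.data.table(called)
  cs <- if ("secondary_start" %in% names(called)) called$secondary_start else called$start
  ce <- if ("secondary_end" %in% names(called)) called$secondary_end else called$end
  found <- logical(n_comparable)
  for (i in seq_len(n_comparable)) {
    same <- called$chrom == validated$chrom[i]
    if (!any(same)) next
    if (overlap_rule == "any") {
      found[i] <- any(cs[same] <= validated$end[i] & ce[same] >= validated$start[i])
    } else {
      found[i] <- any(reciprocal_overlap(validated$start[i], validated$end[i],
                                         cs[same], ce[same]) > threshold)
    }
  }
  n_found <- sum(found)
  list(n_found = n_found, n_comparable = n_comparable,
       sensitivity = 100 * n_found / n_comparable, defined = TRUE)
}
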