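# Damage scoring of coding variants: Grantham physicochemical distances
# computed from first principles (composition, polarity, volume), GMS
# banding, SIFT classification and consequence-term filtering.

# Per-residue property values from Grantham (1974): composition c (atomic
# weight ratio of non-carbon side-chain atoms), polarity p, molecular
# volume v. One-letter codes.
grantham_properties <- function() {
  p <- data.frame(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170)
  )
  rownames(p) <- p$aa
  p
}

# Weighting constants from the same source; rho is not hard-coded but
# solved so that the mean over the 190 unordered residue pairs is exactly
# 100 (the published scaling contract).
GRANTHAM_ALPHA <- 1.833
GRANTHAM_BETA  <- 0.1018
GRANTHAM_GAMMA <- 0.000399

grantham_env <- new.env(parent = emptyenv())

grantham_matrix_raw <- function() {
  if (!is.null(grantham_env$mat)) return(grantham_env$mat)
  pr <- grantham_properties()
  n <- nrow(pr)
  d <- matrix(0, n, n, dimnames = list(pr$aa, pr$aa))
  for (i in seq_len(n)) {
    d[i, ] <- sqrt(GRANTHAM_ALPHA * (pr$c[i] - pr$c)^2 +
                   GRANTHAM_BETA  * (pr$p[i] - pr$p)^2 +
                   GRANTHAM_GAMMA * (pr$v[i] - pr$v)^2)
  }
  rho <- 100 / mean(d[upper.tri(d)])
  grantham_env$mat <- d * rho
  grantham_env$rho <- rho
  grantham_env$mat
}

#' Grantham distance between two amino acids
#'
#' Physicochemical distance
#' \eqn{D = \rho\,[\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 + \gamma (v_i-v_j)^2]^{1/2}}
#' over side-chain composition \eqn{c}, polarity \eqn{p} and molecular
#' volume \eqn{v}, with \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018},
#' \eqn{\gamma = 0.000399} and \eqn{\rho} scaled so that the mean over all
#' 190 unordered residue pairs equals 100. The distance is symmetric and
#' zero iff the residues are identical.
#'
#' @param aa_from,aa_to One-letter codes of standard amino acids
#'   (vectorized). Non-standard residues (`X`, `*`, `U`, ...) yield `NA`.
#' @param rounded If `TRUE` (default) return the integer-rounded score used
#'   for banding; otherwise the raw value.
#' @return Numeric vector of distances (`NA` for unscorable pairs).
#' @export
grantham_distance <- function(aa_from, aa_to, rounded = TRUE) {
  m <- grantham_matrix_raw()
  i <- match(toupper(aa_from), rownames(m))
  j <- match(toupper(aa_to), rownames(m))
  out <- rep(NA_real_, max(length(i), length(j)))
  i <- rep_len(i, length(out)); j <- rep_len(j, length(out))
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- m[cbind(i[ok], j[ok])]
  if (rounded) out <- round(out)
  out
}

#' Full 20 x 20 Grantham distance matrix
#'
#' @param rounded Integer-rounded (default) or raw values.
#' @return Symmetric numeric matrix with one-letter dimnames.
#' @export
grantham_matrix <- function(rounded = TRUE) {
  m <- grantham_matrix_raw()
  if (rounded) round(m) else m
}

#' Classify a Grantham score into damage bands
#'
#' Bands partition the non-negative axis: `conservative` for scores of at
#' most 100, `moderately_radical` for scores above 100 up to and including
#' 150, `radical` above 150.
#'
#' @param score Numeric vector of non-negative Grantham scores (`NA`
#'   propagates).
#' @return Factor with levels `conservative`, `moderately_radical`,
#'   `radical`.
#' @export
classify_gms <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("negative Grantham score")
  lab <- ifelse(score > 150, "radical",
                ifelse(score > 100, "moderately_radical", "conservative"))
  factor(lab, levels = c("conservative", "moderately_radical", "radical"))
}

#' Classify SIFT annotation as tolerated/deleterious/unscored
#'
#' A categorical SIFT call attached to the annotation takes precedence;
#' otherwise a score of at most `threshold` is deleterious and above it
#' tolerated; with neither call nor score the variant is unscored.
#'
#' @param sift_score Numeric vector in `[0, 1]` (or `NA`).
#' @param sift_call Optional character vector of upstream calls
#'   (`"deleterious"` / `"tolerated"` or `NA`).
#' @param threshold Deleteriousness cutoff, default 0.05 (inclusive).
#' @return Character vector in `{"tolerated", "deleterious", "unscored"}`.
#' @export
classify_sift <- function(sift_score, sift_call = NULL, threshold = 0.05) {
  n <- length(sift_score)
  if (is.null(sift_call)) sift_call <- rep(NA_character_, n)
  sift_call <- rep_len(sift_call, n)
  out <- rep("unscored", n)
  has_call <- !is.na(sift_call) & sift_call %in% c("deleterious", "tolerated")
  out[has_call] <- sift_call[has_call]
  need <- !has_call & !is.na(sift_score)
  out[need] <- ifelse(sift_score[need] <= threshold, "deleterious", "tolerated")
  out
}

split_terms <- function(consequence) {
  strsplit(consequence, "&", fixed = TRUE)
}

#' Filter annotated sites by consequence term
#'
#' Returns one row per (site, annotation) pair whose consequence terms
#' intersect the requested set; a variant annotated differently on
#' different transcripts contributes one pair per matching transcript.
#'
#' @param mat A [strain_matrix()] with annotations attached, or an
#'   annotation `data.table`.
#' @param terms Non-empty character vector of consequence terms (e.g.
#'   `"missense_variant"`, `"stop_gained"`).
#' @return Annotation `data.table` subset (columns as in the annotation
#'   table), one row per matching annotation.
#' @export
filter_by_consequence <- function(mat, terms) {
  if (length(terms) == 0L) stop("empty consequence term set")
  ann <- if (inherits(mat, "strain_matrix")) mat$annotations else data.table::as.data.table(mat)
  if (nrow(ann) == 0L) return(ann)
  hit <- vapply(split_terms(ann$consequence),
                function(tt) any(tt %in% terms), TRUE)
  ann[hit]
}

#' Score annotations: Grantham distance, band and SIFT class
#'
#' Adds `gms`, `gms_band` and `sift_class` columns to an annotation table.
#' Missense annotations with non-standard residues are left unscored
#' (`NA` GMS) and flagged.
#'
#' @param ann Annotation `data.table` (or [strain_matrix()]).
#' @param sift_threshold SIFT deleteriousness cutoff (default 0.05).
#' @return Scored copy of the annotation table with `gms`, `gms_band`,
#'   `sift_class` and logical `gms_unscored`.
#' @export
score_annotations <- function(ann, sift_threshold = 0.05) {
  if (inherits(ann, "strain_matrix")) ann <- ann$annotations
  ann <- data.table::copy(data.table::as.data.table(ann))
  is_mis <- vapply(split_terms(ann$consequence),
                   function(tt) "missense_variant" %in% tt, TRUE)
  g <- rep(NA_real_, nrow(ann))
  g[is_mis] <- grantham_distance(ann$aa_ref[is_mis], ann$aa_alt[is_mis])
  ann[, gms := g]
  ann[, gms_band := classify_gms(g)]
  ann[, gms_unscored := is_mis & is.na(g)]
  ann[, sift_class := classify_sift(sift_score, sift_call, sift_threshold)]
  ann[]
}

#' Most-damaging per-variant summary over transcripts
#'
#' Collapses a scored annotation table to one row per site key using the
#' worst-case rule: maximum GMS, and `deleterious` dominating `tolerated`
#' dominating `unscored` for SIFT.
#'
#' @param scored Output of [score_annotations()].
#' @return `data.table` with one row per `key`: `gms`, `gms_band`,
#'   `sift_class`, `genes` (comma-joined genes over missense annotations).
#' @export
summarize_per_variant <- function(scored) {
  sev <- c(unscored = 0L, tolerated = 1L, deleterious = 2L)
  scored[, {
    gmax <- if (all(is.na(gms))) NA_real_ else max(gms, na.rm = TRUE)
    list(gms = gmax,
         gms_band = if (is.na(gmax)) factor(NA, levels = levels(classify_gms(0))) else classify_gms(gmax),
         sift_class = sift_class[which.max(sev[sift_class])],
         genes = paste(sort(unique(gene_id)), collapse = ","))
  }, by = key]
}
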