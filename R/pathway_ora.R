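# Hypergeometric pathway over-representation with Benjamini-Hochberg
# correction.

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(`N` genes in the
#' universe, `K` of them in the pathway, `n` drawn as candidates), computed
#' through the log-space survival function.
#'
#' @param k Observed overlap (candidates in the pathway).
#' @param n Candidate set size within the universe.
#' @param K Pathway size within the universe.
#' @param N Universe size.
#' @return Probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || K > N || n > N || k > min(n, K)) {
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K), K,n <= N)")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted[i] = min over j with p[j] ranked >= rank(p[i]) of
#' (m * p_(j) / j)`, capped at 1; the output preserves input order.
#'
#' @param pvalues Numeric vector with all values in `(0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p values must lie in (0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  adj_sorted <- rev(cummin(rev(m * pvalues[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}

#' Pathway over-representation analysis
#'
#' Tests a candidate gene set against each pathway with the upper-tail
#' hypergeometric probability, then corrects across the tested family with
#' Benjamini-Hochberg. The universe defaults to all genes annotated to at
#' least one loaded pathway (`universe_mode = "annotated"`); pass an
#' explicit gene universe with `universe_mode = "explicit"`. Candidate and
#' pathway gene sets are intersected with the universe before counting.
#' Pathways with zero candidate overlap are reported untested (`NA` p) and
#' do not enter the BH family.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param pathways List of `pathway_set` objects ([read_gmt()]).
#' @param universe_mode `"annotated"` or `"explicit"`.
#' @param universe Gene universe when `universe_mode = "explicit"`.
#' @param alpha Significance level on the corrected p (default 0.05,
#'   strict: `p_adj < alpha`).
#' @return `data.table` sorted by `p_adj` with columns `pathway_id`, `name`,
#'   `database`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `significant`,
#'   `tested`, `candidate_genes` (comma-joined). Attribute `flagged` is
#'   `TRUE` when no test could be performed (empty universe or no candidate
#'   in the universe).
#' @export
run_ora <- function(candidates, pathways,
                    universe_mode = c("annotated", "explicit"),
                    universe = NULL, alpha = 0.05) {
  universe_mode <- match.arg(universe_mode)
  if (length(pathways) == 0L) stop("no pathways to test")
  if (universe_mode == "annotated") {
    universe <- unique(unlist(lapply(pathways, `[[`, "genes")))
  } else if (is.null(universe)) {
    stop("universe_mode = 'explicit' needs a universe")
  }
  universe <- unique(universe)
  cand <- intersect(unique(candidates), universe)
  N <- length(universe)
  n <- length(cand)
  res <- data.table::rbindlist(lapply(pathways, function(p) {
    genes <- intersect(p$genes, universe)
    ov <- intersect(cand, genes)
    data.table::data.table(pathway_id = p$pathway_id, name = p$name,
                           database = p$database,
                           k = length(ov), K = length(genes), n = n, N = N,
                           candidate_genes = paste(sort(ov), collapse = ","))
  }))
  flagged <- N == 0L || n == 0L
  res[, p_raw := NA_real_]
  res[, p_adj := NA_real_]
  res[, tested := FALSE]
  if (!flagged) {
    test_i <- which(res$k >= 1L)
    if (length(test_i) > 0L) {
      pr <- vapply(test_i, function(i) hypergeom_upper_tail(res$k[i], n, res$K[i], N), 0)
      res[test_i, p_raw := pr]
      res[test_i, p_adj := bh_adjust(pr)]
      res[test_i, tested := TRUE]
    }
  }
  res[, significant := !is.na(p_adj) & p_adj < alpha]
  data.table::setorder(res, p_adj, pathway_id, na.last = TRUE)
  data.table::setattr(res, "flagged", flagged)
  res[]
}
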