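# Privacy rule, sharing statistics, and oracle equivalence.

priv_of <- function(mat, rule) identify_private_variants(mat, rule)

test_that("privacy rule verdicts match the stated boundary cases at S = 36", {
  rule <- privacy_rule(30, 5)
  row_for <- function(n_ref, n_missing, n_het = 0, extra_alt = 0) {
    c(HA, rep(HA, extra_alt), rep(HR, n_ref), rep(MI, n_missing),
      rep(HE, n_het))
  }
  # 1 hom-alt + 35 hom-ref -> private
  m <- make_matrix(list(row_for(35, 0)))
  expect_equal(priv_of(m, rule)$S01, m$sites$key)
  # 1 hom-alt + 30 hom-ref + 5 missing -> still private (allowance boundary)
  m <- make_matrix(list(row_for(30, 5)))
  expect_equal(priv_of(m, rule)$S01, m$sites$key)
  # 29 hom-ref + 6 missing -> not private
  m <- make_matrix(list(row_for(29, 6)))
  expect_equal(lengths(priv_of(m, rule)), setNames(rep(0L, 36), m$strains),
               ignore_attr = TRUE)
  # two hom-alt carriers -> private for neither
  m <- make_matrix(list(row_for(34, 0, extra_alt = 1)))
  expect_true(all(lengths(priv_of(m, rule)) == 0L))
  # a single high-quality het among the others disqualifies
  m <- make_matrix(list(row_for(34, 0, n_het = 1)))
  expect_true(all(lengths(priv_of(m, rule)) == 0L))
  # low-quality counts against the same allowance as missing
  m <- make_matrix(list(c(HA, rep(HR, 30), rep(LQ, 3), rep(MI, 2))))
  expect_equal(priv_of(m, rule)$S01, m$sites$key)
  m <- make_matrix(list(c(HA, rep(HR, 29), rep(LQ, 3), rep(MI, 3))))
  expect_true(all(lengths(priv_of(m, rule)) == 0L))
})

test_that("rule incompatible with the panel size is a configuration error", {
  m <- make_matrix(list(c(HA, HR, HR)))
  expect_error(identify_private_variants(m, privacy_rule(30, 5)),
               "incompatible")
  # derived default min_homref_others = S - 1 - max_missing_lq always fits
  expect_silent(identify_private_variants(m, privacy_rule(NULL, 1)))
})

test_that("identify_private_variants equals the brute-force oracle", {
  set.seed(71)
  for (rep in 1:8) {
    S <- sample(4:12, 1)
    n <- 300
    gt <- matrix(sample(1:5, n * S, replace = TRUE,
                        prob = c(0.55, 0.25, 0.05, 0.07, 0.08)), n, S)
    sites <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                        pos = sample.int(1e6, n),
                        ref = "A", alt = "G")
    mat <- strain_matrix(sprintf("S%02d", 1:S), sites, gt)
    max_ml <- sample(0:3, 1)
    rule <- privacy_rule(NULL, max_ml)
    got <- identify_private_variants(mat, rule)
    want <- oracle_private_variants(mat$gt, mat$strains,
                                    S - 1L - max_ml, max_ml,
                                    keys = mat$sites$key, sites = mat$sites)
    expect_identical(got, want)
  }
})

test_that("privacy is monotone in the rule parameters", {
  set.seed(72)
  S <- 10
  n <- 400
  gt <- matrix(sample(1:5, n * S, replace = TRUE,
                      prob = c(0.5, 0.25, 0.05, 0.1, 0.1)), n, S)
  mat <- strain_matrix(sprintf("S%02d", 1:S),
                       data.frame(chrom = "chr1", pos = seq_len(n),
                                  ref = "A", alt = "G"), gt)
  for (ml in 0:3) {
    lo <- identify_private_variants(mat, privacy_rule(0, ml))
    hi <- identify_private_variants(mat, privacy_rule(0, ml + 1))
    for (s in mat$strains) {
      # relaxing the missing allowance never removes a private site
      expect_true(all(lo[[s]] %in% hi[[s]]))
    }
  }
  for (mh in c(0, 2, 4, 5)) {
    lo <- identify_private_variants(mat, privacy_rule(mh, 3))
    hi <- identify_private_variants(mat, privacy_rule(mh + 1, 3))
    for (s in mat$strains) {
      # tightening the hom-ref requirement never adds one
      expect_true(all(hi[[s]] %in% lo[[s]]))
    }
  }
})

test_that("shared_fraction counts allele-identical hom-alt sites", {
  m <- make_matrix(list(
    c(HA, HA, HR), c(HA, HA, HR), c(HA, HA, HR), c(HA, HA, HR), c(HA, HA, HR),
    c(HA, HA, HR), c(HA, HA, HR), c(HA, HA, HR), c(HA, HA, HR),
    c(HA, HR, HR)))
  sf <- shared_fraction(m, "S01", "S02")
  expect_equal(sf$fraction, 0.9)
  expect_equal(sf$numerator, 9L)
  expect_equal(sf$denominator, 10L)
  # self-comparison is identically 1
  expect_equal(shared_fraction(m, "S01", "S01")$fraction, 1)
  # degenerate: no hom-alt in a -> flagged undefined
  sf0 <- shared_fraction(m, "S03", "S01")
  expect_false(sf0$defined)
  expect_equal(sf0$denominator, 0L)
  expect_error(shared_fraction(m, "S01", "nope"), "unknown strain")
})

test_that("pairwise sharing table equals the brute-force double loop", {
  set.seed(73)
  S <- 5; n <- 200
  gt <- matrix(sample(1:5, n * S, replace = TRUE), n, S)
  mat <- strain_matrix(sprintf("S%02d", 1:S),
                       data.frame(chrom = "chr1", pos = seq_len(n),
                                  ref = "A", alt = "G"), gt)
  tab <- pairwise_sharing_table(mat)
  for (a in 1:S) for (b in 1:S) {
    expect_equal(tab[a, b], sum(gt[, a] == 2L & gt[, b] == 2L))
  }
  expect_true(isSymmetric(unname(tab)))
  # single-strain matrix: 1x1 table equal to its variant count
  m1 <- strain_matrix("only",
                      data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G"),
                      matrix(c(HA, HA, HR, MI), ncol = 1))
  expect_equal(unname(pairwise_sharing_table(m1)), matrix(2L))
  # disjoint variants -> off-diagonal zero
  m2 <- make_matrix(list(c(HA, HR, HR), c(HR, HA, HR)))
  expect_equal(unname(pairwise_sharing_table(m2)),
               matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L), 3))
})

test_that("catalog_summary splits SNP and indel counts", {
  sim <- simulate_strain_panel(n_strains = 6, n_sites = 400,
                               n_private_per_strain = 4,
                               rule = privacy_rule(NULL, 1),
                               missing_rate = 0, lowqual_rate = 0,
                               het_rate = 0, seed = 21)
  summ <- catalog_summary(sim$matrix, privacy_rule(NULL, 1))
  expect_equal(summ$strain, sim$matrix$strains)
  expect_equal(summ$n_private_snps + summ$n_private_indels,
               unname(lengths(sim$truth$private)))
  expect_equal(summ$n_snps + summ$n_indels,
               unname(colSums(sim$matrix$gt == 2L)))
})
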