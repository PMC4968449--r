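# SV filtering, reciprocal-overlap merging, privacy, CDS overlap and
# validation sensitivity.

test_that("reciprocal overlap matches base-counting on random pairs", {
  expect_equal(reciprocal_overlap(100, 199, 100, 199), 1)
  expect_equal(reciprocal_overlap(100, 199, 150, 249), 0.5)
  expect_equal(reciprocal_overlap(100, 199, 300, 400), 0)
  expect_equal(reciprocal_overlap(1, 10, 1, 10, "chr1", "chr2"), 0)
  set.seed(41)
  for (i in 1:50) {
    a <- sort(sample.int(500, 2)); b <- sort(sample.int(500, 2))
    ov <- length(intersect(seq(a[1], a[2]), seq(b[1], b[2])))
    want <- min(ov / (a[2] - a[1] + 1), ov / (b[2] - b[1] + 1))
    expect_equal(reciprocal_overlap(a[1], a[2], b[1], b[2]), want)
  }
})

test_that("proximity and size filters remove the right calls", {
  svs <- sv_table(chrom = rep("chr1", 4),
                  start = c(1000, 200000, 500000, 800000),
                  end = c(1400, 201000, 501500, 800000 + 1.5e6),
                  svtype = "DEL", strain = "s1",
                  caller = c("breakdancer", "cnd", "lumpy", "breakdancer"))
  gaps <- data.frame(chrom = "chr1", start = 1800, end = 2000)
  telo <- data.frame(chrom = "chr1", start = 480000, end = 481000)
  res <- filter_svs(svs, gaps, telo)
  # call 1 ends 400 bp before the gap start -> removed
  expect_true("assembly_gap" %in% res$rejected$reason)
  expect_equal(res$rejected[reason == "assembly_gap", start], 1000L)
  # call 3 is 19 kb from the telomere track -> removed
  expect_equal(res$rejected[reason == "telomere_centromere", start], 500000L)
  # call 4 is 1.5 Mb -> removed by the size rule
  expect_equal(res$rejected[reason == "max_length", start], 800000L)
  expect_equal(res$retained$start, 200000L)
  # 25 kb separation from the telomere is retained
  svs2 <- sv_table("chr1", 506000, 507000, "DEL", "s1")
  expect_equal(nrow(filter_svs(svs2, NULL, telo)$retained), 1L)
})

test_that("merge_deletions: threshold strictness and representative choice", {
  # two 1000-bp calls overlapping exactly 900 bp: RO = 0.9, NOT merged
  svs <- sv_table("chr1", c(1000, 1100), c(1999, 2099), "DEL", "s1",
                  c("breakdancer", "lumpy"))
  cl <- merge_deletions(svs, threshold = 0.9)
  expect_equal(nrow(cl), 2L)
  # nudging one endpoint above the threshold merges them
  svs2 <- sv_table("chr1", c(1000, 1099), c(1999, 2098), "DEL", "s1",
                   c("lumpy", "cnd"))
  cl2 <- merge_deletions(svs2, threshold = 0.9)
  expect_equal(nrow(cl2), 1L)
  # primary breakpoints from the highest-priority caller (lumpy here),
  # secondary from the outer bounds
  expect_equal(cl2$primary_start, 1000L)
  expect_equal(cl2$primary_end, 1999L)
  expect_equal(cl2$secondary_start, 1000L)
  expect_equal(cl2$secondary_end, 2098L)
  # identical calls from three callers -> one cluster, secondary = shared span
  svs3 <- sv_table("chr1", rep(5000, 3), rep(5999, 3), "DEL", "s1",
                   c("cnd", "breakdancer", "lumpy"))
  cl3 <- merge_deletions(svs3)
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$n_members, 3L)
  expect_equal(c(cl3$secondary_start, cl3$secondary_end), c(5000L, 5999L))
  expect_equal(cl3$primary_caller, "breakdancer")
  expect_error(merge_deletions(sv_table("chr1", 1, 1, "INS", "s")), "DEL")
})

test_that("cluster assignment equals brute-force transitive closure", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(30:120, 1)
    start <- sample.int(50000, n)
    len <- sample(100:2000, n, replace = TRUE)
    svs <- sv_table(sample(c("chr1", "chr2"), n, TRUE), start,
                    start + len - 1L, "DEL",
                    strain = "s1",
                    caller = sample(c("breakdancer", "cnd", "lumpy"), n, TRUE))
    cl <- merge_deletions(svs)
    # recover the implementation's member partition
    got <- canonical_partition(lapply(cl$members, function(m) sort(m$sv_id)))
    want <- canonical_partition(cluster_partition(oracle_del_clusters(svs)))
    expect_identical(got, want)
  }
})

test_that("merging is order-invariant and idempotent", {
  sim <- simulate_sv_callsets(n_true = 25, n_strains = 1, seed = 43)
  svs <- sim$svs
  cl1 <- merge_deletions(svs)
  perm <- svs[sample.int(nrow(svs)), ]
  cl2 <- merge_deletions(perm)
  cols <- c("chrom", "primary_start", "primary_end",
            "secondary_start", "secondary_end", "n_members")
  expect_identical(as.data.frame(cl1[, ..cols]), as.data.frame(cl2[, ..cols]))
  # idempotence: re-merging the merged representatives changes nothing
  again <- sv_table(cl1$chrom, cl1$secondary_start, cl1$secondary_end,
                    "DEL", "s1", "other")
  cl3 <- merge_deletions(again)
  expect_equal(nrow(cl3), nrow(cl1))
  expect_identical(cl3$secondary_start, cl1$secondary_start)
  expect_identical(cl3$secondary_end, cl1$secondary_end)
  # secondary bounds contain primary bounds and every member
  expect_true(all(cl1$secondary_start <= cl1$primary_start))
  expect_true(all(cl1$secondary_end >= cl1$primary_end))
  for (i in seq_len(nrow(cl1))) {
    m <- cl1$members[[i]]
    expect_true(all(m$start >= cl1$secondary_start[i]))
    expect_true(all(m$end <= cl1$secondary_end[i]))
  }
})

test_that("insertion merging clusters by breakpoint window", {
  svs <- sv_table("chr1", c(1000, 1000, 5000, 5101), c(1000, 1000, 5000, 5101),
                  "INS", "s1", "retroseq", ins_length = 300L)
  cl <- merge_insertions(svs, window = 100)
  # identical positions merge; 101 bp apart does not
  expect_equal(nrow(cl), 3L)
  cl2 <- merge_insertions(svs, window = 101)
  expect_equal(nrow(cl2), 2L)
  expect_error(merge_insertions(sv_table("chr1", 1, 500, "DEL", "s")), "INS")
})

test_that("planted SV clusters and privacy flags are recovered exactly", {
  sim <- simulate_sv_callsets(n_true = 30, n_strains = 4,
                              shared_across_strains = 0.4, seed = 44)
  per_strain <- lapply(split(sim$svs, sim$svs$strain), merge_deletions)
  # within each strain, clusters correspond 1:1 to that strain's true events
  truth <- sim$truth$clusters
  for (s in names(per_strain)) {
    expected <- truth[grepl(s, truth$strains, fixed = TRUE)]
    expect_equal(nrow(per_strain[[s]]), nrow(expected))
  }
  flagged <- cross_strain_private_svs(per_strain)
  got_private <- data.table::rbindlist(lapply(names(flagged), function(s) {
    cl <- flagged[[s]]
    data.table::data.table(strain = s, start = cl$secondary_start,
                           private = cl$private)
  }))
  # map each called cluster back to its planted event by proximity
  truth_at <- function(st) {
    i <- which.min(abs(truth$start - st))
    truth$private[i]
  }
  expect_equal(got_private$private,
               vapply(got_private$start, truth_at, TRUE))
  # insertions: planted clusters with jitter < window are recovered exactly
  isim <- simulate_sv_callsets(n_true = 20, n_strains = 2, svtype = "INS",
                               jitter_sd_bp = 10, seed = 45)
  icl <- merge_insertions(isim$svs, window = 100)
  expect_equal(nrow(icl), length(unique(isim$truth$call_cluster)))
})

test_that("cds_overlap tests CDS intervals only, via secondary bounds", {
  clusters <- merge_deletions(sv_table(
    "chr1", c(1000, 9000), c(3000, 9500), "DEL", "s1", "breakdancer"))
  gm <- data.table::data.table(
    gene_id = c("gA", "gA", "gB"), chrom = "chr1",
    start = c(1500L, 2500L, 9600L), end = c(1600L, 2600L, 9900L))
  res <- cds_overlap(clusters, gm)
  # deletion 1 spans both gA CDS exons: gene reported once
  expect_equal(res$hits[, .N, by = gene_id]$N, 1L)
  expect_equal(res$n_clusters_hit, 1L)
  expect_equal(res$n_genes_hit, 1L)
  # deletion 2 stops short of gB's CDS (intronic/upstream): no hit
  expect_false(any(res$hits$gene_id == "gB"))
  # random instances vs brute-force interval intersection
  set.seed(46)
  for (rep in 1:5) {
    n <- 40
    st <- sample.int(100000, n); en <- st + sample(100:3000, n, TRUE)
    cl <- merge_deletions(sv_table("chr1", st, en, "DEL", "s1", "cnd"))
    gs <- sample.int(100000, 30); ge <- gs + sample(50:500, 30, TRUE)
    gm2 <- data.table::data.table(gene_id = sprintf("g%02d", 1:30),
                                  chrom = "chr1", start = gs, end = ge)
    res2 <- cds_overlap(cl, gm2)
    want <- 0L
    for (i in seq_len(nrow(cl))) for (j in 1:30) {
      if (cl$secondary_start[i] <= ge[j] && cl$secondary_end[i] >= gs[j]) {
        want <- want + 1L
      }
    }
    expect_equal(nrow(res2$hits), want)
  }
})

test_that("validation sensitivity reproduces the exclusion arithmetic", {
  # 10 validated, 2 excluded as true differences, 7 of the rest found
  called <- sv_table("chr1", seq(1000, 7000, by = 1000),
                     seq(1000, 7000, by = 1000) + 500, "DEL", "s1", "cnd")
  validated <- data.frame(chrom = "chr1",
                          start = c(seq(1000, 7000, by = 1000), 50000, 60000, 70000),
                          end = c(seq(1000, 7000, by = 1000) + 400, 50100, 60100, 70100))
  excluded <- validated[8:9, ]
  r <- validation_sensitivity(called, validated, excluded)
  expect_equal(r$n_comparable, 8L)
  expect_equal(r$n_found, 7L)
  expect_equal(r$sensitivity, 100 * 7 / 8)
  # nothing found -> 0 %
  r0 <- validation_sensitivity(called[0], validated)
  expect_equal(r0$sensitivity, 0)
  # nothing comparable -> undefined and flagged
  rNA <- validation_sensitivity(called, validated[0, ])
  expect_false(rNA$defined)
})
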