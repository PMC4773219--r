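iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("reciprocal overlap handles identity, disjointness and chromosomes", {
  r <- reciprocal_overlap(iv("chr1", 100, 200), iv("chr1", 100, 200))
  expect_equal(unlist(r), c(overlap_bp = 100, fraction_a = 1,
                            fraction_b = 1))
  r <- reciprocal_overlap(iv("chr1", 0, 1000), iv("chr1", 5000, 6000))
  expect_equal(r$overlap_bp, 0)
  expect_equal(r$fraction_a, 0)
  r <- reciprocal_overlap(iv("chr1", 0, 1000), iv("chr2", 0, 1000))
  expect_equal(unlist(r), c(overlap_bp = 0, fraction_a = 0,
                            fraction_b = 0))
})

test_that("reciprocal overlap equals base-by-base counting on random pairs", {
  set.seed(31)
  for (k in 1:300) {
    a <- iv(sample(c("chr1", "chr2"), 1), s <- sample(500, 1),
            s + sample(80, 1))
    b <- iv(sample(c("chr1", "chr2"), 1), s2 <- sample(500, 1),
            s2 + sample(80, 1))
    got <- reciprocal_overlap(a, b)
    want <- bf_reciprocal(a, b)
    expect_equal(got$overlap_bp, unname(want["overlap_bp"]))
    expect_equal(got$fraction_a, unname(want["fraction_a"]))
    expect_equal(got$fraction_b, unname(want["fraction_b"]))
  }
})

test_that("reciprocal overlap is symmetric and translation invariant", {
  set.seed(32)
  for (k in 1:100) {
    a <- iv("chr1", s <- sample(1000, 1), s + sample(100, 1))
    b <- iv("chr1", s2 <- sample(1000, 1), s2 + sample(100, 1))
    ab <- reciprocal_overlap(a, b); ba <- reciprocal_overlap(b, a)
    expect_equal(ab$fraction_a, ba$fraction_b)
    expect_equal(ab$fraction_b, ba$fraction_a)
    shift <- sample(1e6, 1)
    a2 <- iv("chr1", a$start + shift, a$end + shift)
    b2 <- iv("chr1", b$start + shift, b$end + shift)
    expect_equal(reciprocal_overlap(a2, b2), ab)
  }
})

cons_call <- function(alg, sample, chrom, start, end, type = "loss") {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             type = type, copy_number = if (type == "loss") 1L else 3L,
             probe_count = 10L, algorithm = alg, confidence = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("identical calls from three algorithms merge to one consensus", {
  calls <- rbind(cons_call("a1", "S1", "chr1", 100, 2000),
                 cons_call("a2", "S1", "chr1", 100, 2000),
                 cons_call("a3", "S1", "chr1", 100, 2000))
  cons <- merge_algorithm_calls(calls)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$n_algorithms, 3)
  expect_equal(cons$algorithms, "a1,a2,a3")
  expect_equal(c(cons$start, cons$end), c(100, 2000))
})

test_that("single-algorithm calls yield no stringent consensus", {
  calls <- cons_call("a1", "S1", "chr1", 100, 2000)
  expect_equal(nrow(merge_algorithm_calls(calls)), 0)
  # but survive at min_support 1
  expect_equal(nrow(merge_algorithm_calls(calls, min_support = 1)), 1)
})

test_that("single linkage chains A~B~C even when A and C do not link", {
  # A=[0,100), B=[50,150), C=[100,200): A~B and B~C at 50%, A/C disjoint
  calls <- rbind(cons_call("a1", "S1", "chr1", 0, 100),
                 cons_call("a2", "S1", "chr1", 50, 150),
                 cons_call("a3", "S1", "chr1", 100, 200))
  cons <- merge_algorithm_calls(calls, link_fraction = 0.5)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$n_algorithms, 3)
  expect_equal(c(cons$start, cons$end), c(0, 200))  # outer bounds
})

test_that("merging matches the brute-force clustering oracle on small instances", {
  set.seed(33)
  for (trial in 1:200) {
    n <- sample(2:6, 1)
    start <- sample(200, n, replace = TRUE)
    calls <- data.frame(
      sample_id = "S1", chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = start, end = start + sample(60, n, TRUE),
      type = sample(c("gain", "loss"), n, TRUE),
      copy_number = NA_integer_, probe_count = 0L,
      algorithm = sample(c("a1", "a2", "a3"), n, TRUE),
      confidence = NA_real_, stringsAsFactors = FALSE)
    calls <- calls[!duplicated(calls[c("algorithm", "chrom", "start",
                                       "end", "type")]), ]
    got <- cluster_by_overlap(calls, 0.5, c("sample_id", "chrom", "type"))
    want <- bf_clusters(calls, 0.5, c("sample_id", "chrom", "type"))
    expect_true(same_partition(got, want))
  }
})

test_that("duplicate (algorithm, sample, interval) calls collapse with warning", {
  calls <- rbind(cons_call("a1", "S1", "chr1", 100, 2000),
                 cons_call("a1", "S1", "chr1", 100, 2000),
                 cons_call("a2", "S1", "chr1", 100, 2000))
  expect_warning(cons <- merge_algorithm_calls(calls), "duplicate")
  expect_equal(cons$n_members, 2)
})

test_that("merging is idempotent and monotone in min_support", {
  set.seed(34)
  for (trial in 1:20) {
    calls <- random_calls(40, samples = c("S1", "S2"))
    cons2 <- merge_algorithm_calls(calls, min_support = 2)
    cons3 <- merge_algorithm_calls(calls, min_support = 3)
    expect_lte(nrow(cons3), nrow(cons2))
    if (nrow(cons2) == 0) next
    # re-merging the consensus set at the same linkage returns it unchanged
    again <- cons2[c("sample_id", "chrom", "start", "end", "type")]
    again$copy_number <- NA_integer_
    again$probe_count <- 0L
    again$algorithm <- cons2$algorithms
    again$confidence <- NA_real_
    re <- merge_algorithm_calls(again, min_support = 1)
    expect_setequal(call_key(re), call_key(cons2))
  }
})

test_that("probe counts match a linear scan and respect interval bounds", {
  manifest <- tiny_manifest()  # probes at 1000, 3000, 5000, ...
  # [999, 9001) spans probes 1000..9000 -> 5 probes
  expect_equal(count_probes(iv("chr1", 999, 9001), manifest), 5)
  # interval strictly between two probes
  expect_equal(count_probes(iv("chr1", 1001, 2999), manifest), 0)
  # boundary: probe at position p supports [p, p+1) but not [p+1, ...)
  expect_equal(count_probes(iv("chr1", 1000, 1001), manifest), 1)
  expect_equal(count_probes(iv("chr1", 1001, 3000), manifest), 0)

  set.seed(35)
  for (k in 1:200) {
    s <- sample(1e6, 1)
    cand <- iv("chr1", s, s + sample(50000, 1))
    oracle <- sum(manifest$pos >= cand$start & manifest$pos < cand$end)
    expect_equal(count_probes(cand, manifest), oracle)
  }
  expect_warning(n <- count_probes(iv("chr9", 0, 1000), manifest),
                 "no manifest probes")
  expect_equal(n, 0)
})

filter_fixture <- function(start, end, chrom = "chr1", probes = 10L) {
  df <- data.frame(sample_id = "S1", chrom = chrom, start = start,
                   end = end, type = "loss", n_algorithms = 2L,
                   algorithms = "a1,a2", n_members = 2L,
                   probe_count = probes, stringsAsFactors = FALSE)
  df$members <- list(df)
  df
}

test_that("each CNV filter falls on the documented side of its threshold", {
  ann <- tiny_annotation()

  few <- apply_cnv_filters(filter_fixture(1e6, 1.02e6, probes = 4L), ann)
  expect_equal(few$outcomes$reasons, "FEW_PROBES")
  ok <- apply_cnv_filters(filter_fixture(1e6, 1.02e6, probes = 5L), ann)
  expect_true(ok$outcomes$retained)

  # GC: call inside the 0.75 window fails; weighted mean exactly 0.70 passes
  hi <- apply_cnv_filters(filter_fixture(2e6, 2.005e6), ann)
  expect_equal(hi$outcomes$reasons, "HIGH_GC")
  ann70 <- ann
  ann70$gc$gc[ann70$gc$start == 2e6] <- 0.70
  at <- apply_cnv_filters(filter_fixture(2e6, 2.005e6), ann70)
  expect_true(at$outcomes$retained)
  ann71 <- ann
  ann71$gc$gc[ann71$gc$start == 2e6] <- 0.71
  over <- apply_cnv_filters(filter_fixture(2e6, 2.005e6), ann71)
  expect_equal(over$outcomes$reasons, "HIGH_GC")

  # centromere margin: centromere ends at 5.1e6; gap 29,999 fails, 30,000 passes
  near <- apply_cnv_filters(filter_fixture(5.1e6 + 29999, 5.1e6 + 79999),
                            ann)
  expect_equal(near$outcomes$reasons, "CENTROTELO")
  clear <- apply_cnv_filters(filter_fixture(5.1e6 + 30000, 5.1e6 + 80000),
                             ann)
  expect_true(clear$outcomes$retained)

  # size: 999 bp fails, exactly 1,000 bp is retained
  small <- apply_cnv_filters(filter_fixture(1e6, 1e6 + 999), ann)
  expect_equal(small$outcomes$reasons, "TOO_SMALL")
  kb <- apply_cnv_filters(filter_fixture(1e6, 1e6 + 1000), ann)
  expect_true(kb$outcomes$retained)

  # sex chromosomes are excluded outright
  annx <- ann
  annx$chrom_lengths <- rbind(annx$chrom_lengths,
                              data.frame(chrom = "chrX", length = 1e7))
  x <- apply_cnv_filters(filter_fixture(1e6, 1.02e6, chrom = "chrX"), annx)
  expect_equal(x$outcomes$reasons, "SEX_CHROM")

  # > 1 Mb calls are review-flagged, not auto-excluded
  big <- apply_cnv_filters(filter_fixture(5.5e6, 6.6e6, probes = 200L),
                           ann)
  expect_equal(big$outcomes$review_flag, "LARGE_CALL")
  expect_true(big$outcomes$retained)
  # the optional hard cap does exclude them
  capped <- apply_cnv_filters(filter_fixture(5.5e6, 6.6e6, probes = 200L),
                              ann,
                              cnv_filter_params(large_call_cap = 1e6))
  expect_equal(capped$outcomes$reasons, "LARGE")
  expect_false(capped$outcomes$retained)
})

test_that("filter tallies conserve: input = retained + excluded", {
  set.seed(36)
  ann <- tiny_annotation()
  manifest <- tiny_manifest()
  calls <- random_calls(120, chroms = "chr1", max_pos = 9.5e6)
  cons <- merge_algorithm_calls(calls, min_support = 1)
  cons <- annotate_probe_counts(cons, manifest)
  out <- apply_cnv_filters(cons, ann)
  tally <- stats::setNames(out$tally$n, out$tally$reason)
  expect_equal(tally[["input"]], nrow(cons))
  expect_equal(tally[["input"]], tally[["retained"]] + tally[["excluded"]])
  expect_equal(sum(out$outcomes$retained), tally[["retained"]])
  # multi-reason calls counted once in the total, per-reason in breakdown
  expect_gte(sum(tally[c("FEW_PROBES", "HIGH_GC", "CENTROTELO",
                         "TOO_SMALL", "SEX_CHROM", "LARGE")]),
             tally[["excluded"]])
})

test_that("a missing GC track skips HIGH_GC with a warning", {
  ann <- tiny_annotation()
  ann$gc <- ann$gc[0, ]
  expect_warning(out <- apply_cnv_filters(filter_fixture(2e6, 2.005e6),
                                          ann),
                 "GC")
  expect_true(out$outcomes$retained)
})
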