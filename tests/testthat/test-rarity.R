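rare_call <- function(sample, chrom, start, end, type = "loss") {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             type = type, stringsAsFactors = FALSE)
}

ref_set <- function(..., name = "ref") {
  out <- do.call(rbind, lapply(list(...), function(x) {
    data.frame(id = x$id, chrom = x$chrom, start = x$start, end = x$end,
               type = if (is.null(x$type)) "any" else x$type,
               frequency = if (is.null(x$frequency)) NA_real_
                           else x$frequency,
               stringsAsFactors = FALSE)
  }))
  attr(out, "set_name") <- name
  out
}

test_that("known-CNP rule triggers on any single-base overlap above 1% frequency", {
  cnp <- ref_set(list(id = "c1", chrom = "chr1", start = 1000, end = 2000,
                      frequency = 0.05),
                 list(id = "c2", chrom = "chr1", start = 5000, end = 6000,
                      frequency = 0.005))
  # one-base overlap with the 5% CNP
  d <- filter_known_cnp(rare_call("S1", "chr1", 1999, 3000), cnp)
  expect_true(d$known_cnp)
  expect_equal(d$cnp_ids, "c1")
  # overlap only with the 0.5% variant: below threshold, not excluded
  d <- filter_known_cnp(rare_call("S1", "chr1", 5500, 7000), cnp)
  expect_false(d$known_cnp)
  # abutting but not overlapping
  d <- filter_known_cnp(rare_call("S1", "chr1", 2000, 3000), cnp)
  expect_false(d$known_cnp)
})

test_that("known-CNP decisions match a brute-force scan on random configurations", {
  set.seed(51)
  for (trial in 1:50) {
    nref <- sample(1:6, 1)
    rs <- sample(400, nref)
    refs <- do.call(rbind, lapply(seq_len(nref), function(i) {
      data.frame(id = paste0("r", i), chrom = sample(c("chr1", "chr2"), 1),
                 start = rs[i], end = rs[i] + sample(80, 1), type = "any",
                 frequency = sample(c(0.005, 0.05, 0.2), 1),
                 stringsAsFactors = FALSE)
    }))
    calls <- do.call(rbind, lapply(1:5, function(i) {
      s <- sample(400, 1)
      rare_call(paste0("S", i), sample(c("chr1", "chr2"), 1), s,
                s + sample(80, 1))
    }))
    got <- filter_known_cnp(calls, refs)$known_cnp
    want <- vapply(seq_len(nrow(calls)), function(i) {
      any(vapply(seq_len(nrow(refs)), function(j) {
        refs$frequency[j] > 0.01 &&
          bf_overlap_bp(calls[i, ], refs[j, ]) >= 1
      }, logical(1)))
    }, logical(1))
    expect_equal(got, want)
  }
})

test_that("reference novelty uses two-sided 50% reciprocal overlap, >= excludes", {
  ref <- ref_set(list(id = "d1", chrom = "chr1", start = 0, end = 1000))
  # (0.6, 0.6): known
  d <- filter_reference_overlap(rare_call("S1", "chr1", 400, 1400), ref)
  expect_true(d$known_reference)
  # one-sided (call covered 0.6, reference only 0.3): retained
  wide <- ref_set(list(id = "d2", chrom = "chr1", start = 0, end = 2000))
  d <- filter_reference_overlap(rare_call("S1", "chr1", 0, 600), wide)
  expect_false(d$known_reference)
  # exactly 50% on both sides counts as known
  d <- filter_reference_overlap(rare_call("S1", "chr1", 500, 1500), ref)
  expect_true(d$known_reference)
  # just under 50%: novel
  d <- filter_reference_overlap(rare_call("S1", "chr1", 501, 1501), ref)
  expect_false(d$known_reference)
})

test_that("multiple reference sets are matched sequentially with per-set records", {
  dgv <- ref_set(list(id = "d1", chrom = "chr1", start = 0, end = 1000),
                 name = "dgv")
  sgvp <- ref_set(list(id = "s1", chrom = "chr2", start = 0, end = 1000),
                  name = "sgvp")
  calls <- rbind(rare_call("S1", "chr1", 0, 1000),
                 rare_call("S2", "chr2", 100, 1100),
                 rare_call("S3", "chr1", 5000, 6000))
  d <- filter_reference_overlap(calls, list(dgv = dgv, sgvp = sgvp))
  expect_equal(d$known_reference, c(TRUE, TRUE, FALSE))
  expect_equal(d$matches_dgv, c("d1", "", ""))
  expect_equal(d$matches_sgvp, c("", "s1", ""))
})

test_that("reference decisions agree with an all-pairs brute-force oracle", {
  set.seed(52)
  for (trial in 1:40) {
    refs <- do.call(rbind, lapply(1:4, function(i) {
      s <- sample(300, 1)
      data.frame(id = paste0("r", i), chrom = "chr1", start = s,
                 end = s + sample(60, 1), type = "any",
                 frequency = NA_real_, stringsAsFactors = FALSE)
    }))
    calls <- do.call(rbind, lapply(1:6, function(i) {
      s <- sample(300, 1)
      rare_call(paste0("S", i), "chr1", s, s + sample(60, 1))
    }))
    got <- filter_reference_overlap(calls, refs)$known_reference
    want <- vapply(seq_len(nrow(calls)), function(i) {
      any(vapply(seq_len(nrow(refs)), function(j) {
        r <- bf_reciprocal(calls[i, ], refs[j, ])
        min(r["fraction_a"], r["fraction_b"]) >= 0.5
      }, logical(1)))
    }, logical(1))
    expect_equal(got, want)
  }
})

test_that("singleton detection separates unique from multi-sample loci", {
  calls <- rbind(rare_call("S1", "chr1", 1000, 2000),
                 rare_call("S2", "chr1", 1000, 2000),
                 rare_call("S3", "chr1", 9000, 10000))
  d <- find_singletons(calls)
  expect_equal(d$singleton, c(FALSE, FALSE, TRUE))
  expect_equal(d$n_samples, c(2, 2, 1))
  # same locus, opposite type: not the same occurrence cluster
  calls2 <- rbind(rare_call("S1", "chr1", 1000, 2000, "loss"),
                  rare_call("S2", "chr1", 1000, 2000, "gain"))
  expect_equal(find_singletons(calls2)$singleton, c(TRUE, TRUE))
})

test_that("occurrence clusters match the exhaustive pairwise-linkage oracle", {
  set.seed(53)
  for (trial in 1:80) {
    n <- sample(3:8, 1)
    start <- sample(150, n, replace = TRUE)
    calls <- data.frame(
      sample_id = sample(sprintf("S%d", 1:4), n, TRUE),
      chrom = "chr1", start = start, end = start + sample(50, n, TRUE),
      type = sample(c("gain", "loss"), n, TRUE),
      stringsAsFactors = FALSE)
    got <- cluster_by_overlap(calls, 0.5, c("chrom", "type"))
    want <- bf_clusters(calls, 0.5, c("chrom", "type"))
    expect_true(same_partition(got, want))
    d <- find_singletons(calls)
    want_single <- vapply(seq_len(n), function(i) {
      length(unique(calls$sample_id[want == want[i]])) == 1
    }, logical(1))
    expect_equal(d$singleton, want_single)
  }
})

test_that("case/control specificity removes shared loci in both directions", {
  groups <- c(S1 = "case", S2 = "case", S3 = "control", S4 = "control")
  calls <- rbind(
    rare_call("S1", "chr1", 1000, 2000),    # case-only locus
    rare_call("S3", "chr1", 9000, 10000),   # control-only locus
    rare_call("S2", "chr2", 1000, 2000),    # shared locus (60/60 overlap)
    rare_call("S4", "chr2", 1000, 2000))
  sp <- case_control_specific(calls, groups)
  expect_equal(sp$case_specific$sample_id, "S1")
  expect_equal(sp$control_specific$sample_id, "S3")
  expect_equal(sort(sp$shared$sample_id), c("S2", "S4"))
  tally <- attr(sp$case_specific, "tally")
  expect_equal(unname(tally["total"]),
               unname(tally["gain"] + tally["loss"]))
})

test_that("planted case-only loci are recovered and shared loci never appear", {
  sim <- simulate_study(small_sim_config(sensitivity = c(1, 1, 1),
                                         jitter_fraction = 0,
                                         fp_per_genome = 0))
  res <- run_pipeline(sim$callsets, sim$cohort, sim$manifest,
                      sim$annotation, sim$references)
  truth <- sim$planted$truth
  cases <- sim$cohort$sample_id[sim$cohort$group == "case"]
  planted_case <- truth[truth$class %in% c("singleton", "recurrent_case") &
                          truth$sample_id %in% cases, ]
  expect_setequal(call_key(res$specificity$case_specific),
                  call_key(planted_case))
  # the ledger helper agrees when no sample was excluded
  expect_setequal(call_key(ledger_case_specific(truth, sim$cohort,
                                                res$kept_samples)),
                  call_key(planted_case))
  shared <- truth[truth$class == "shared_rare", ]
  expect_length(intersect(call_key(res$specificity$case_specific),
                          call_key(shared)), 0)
  expect_length(intersect(call_key(res$specificity$control_specific),
                          call_key(shared)), 0)
})

test_that("recurrent loci require two distinct carriers and report genes", {
  genes <- data.frame(chrom = "chr1", start = 1500, end = 1800,
                      gene = "GENE1")
  calls <- rbind(rare_call("S1", "chr1", 1000, 2000),
                 rare_call("S2", "chr1", 1100, 2100),
                 rare_call("S3", "chr1", 1050, 2050),
                 rare_call("S4", "chr1", 9000, 9900))
  rec <- find_recurrent(calls, genes = genes)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_samples, 3)
  expect_equal(rec$sample_ids, "S1,S2,S3")
  expect_equal(c(rec$start, rec$end), c(1000, 2100))  # outer bounds
  expect_equal(rec$genes, "GENE1")
  # all-singleton input yields an empty table
  expect_equal(nrow(find_recurrent(rare_call("S1", "chr1", 0, 100))), 0)
})

test_that("recurrence clusters equal brute-force enumeration on random inputs", {
  set.seed(54)
  for (trial in 1:60) {
    n <- sample(3:8, 1)
    start <- sample(120, n, replace = TRUE)
    calls <- data.frame(
      sample_id = sample(sprintf("S%d", 1:5), n, TRUE),
      chrom = "chr1", start = start, end = start + sample(40, n, TRUE),
      type = "loss", stringsAsFactors = FALSE)
    rec <- find_recurrent(calls, min_samples = 2)
    want <- bf_clusters(calls, 0.5, c("chrom", "type"))
    want_n <- vapply(split(calls$sample_id, want),
                     function(s) length(unique(s)), integer(1))
    expect_equal(nrow(rec), sum(want_n >= 2))
  }
})

test_that("gene annotation lists intersecting genes, dash when none", {
  genes <- data.frame(chrom = c("chr1", "chr1"),
                      start = c(1000, 5000), end = c(2000, 6000),
                      gene = c("A1", "B2"))
  calls <- rbind(rare_call("S1", "chr1", 900, 2100),   # contains A1
                 rare_call("S1", "chr1", 3000, 4000),  # intergenic
                 rare_call("S1", "chr1", 5999, 7000))  # clips B2 by 1 bp
  expect_equal(annotate_genes(calls, genes), c("A1", "-", "B2"))
  expect_equal(annotate_genes(calls, genes, mode = "contained"),
               c("A1", "-", "-"))
  set.seed(55)
  for (trial in 1:30) {
    g <- do.call(rbind, lapply(1:4, function(i) {
      s <- sample(200, 1)
      data.frame(chrom = "chr1", start = s, end = s + sample(50, 1),
                 gene = paste0("G", i), stringsAsFactors = FALSE)
    }))
    s <- sample(200, 1)
    cl <- rare_call("S1", "chr1", s, s + sample(50, 1))
    want <- sort(g$gene[vapply(seq_len(4), function(j) {
      bf_overlap_bp(cl, g[j, ]) >= 1
    }, logical(1))])
    got <- annotate_genes(cl, g)
    expect_equal(got, if (length(want)) paste(want, collapse = ",")
                      else "-")
  }
})

test_that("burden report renders the per-genome means and conserves splits", {
  set.seed(56)
  mk <- function(n, gains) {
    start <- sample(1e6, n)
    data.frame(sample_id = "x", chrom = "chr1", start = start,
               end = start + sample(2e4, n),
               type = rep(c("gain", "loss"), c(gains, n - gains)),
               stringsAsFactors = FALSE)
  }
  case <- mk(208, 35); ctrl <- mk(283, 75)
  rep_ <- burden_report(case, ctrl, 44, 72)
  s <- rep_$summary
  expect_equal(s$per_genome, c(208 / 44, 283 / 72))
  # two-decimal rendering of the per-genome averages (truncated)
  expect_equal(floor(100 * s$per_genome) / 100, c(4.72, 3.93))
  expect_equal(s$gains + s$losses, s$n_cnv)
  expect_equal(s$gains, c(35, 75))
  expect_equal(colSums(rep_$histogram[c("case_pct", "control_pct")]),
               c(case_pct = 100, control_pct = 100))
  # identical length samples: statistic 0, p = 1
  same <- burden_report(case, case, 44, 44)
  expect_equal(same$length_test$statistic, 0)
  expect_equal(same$length_test$p_value, 1)
})

test_that("rarity statuses are mutually exclusive and conserve counts", {
  sim <- simulate_study(small_sim_config(seed = 12))
  res <- run_pipeline(sim$callsets, sim$cohort, sim$manifest,
                      sim$annotation, sim$references)
  st <- table(res$rarity$status)
  expect_equal(sum(st), nrow(res$rarity))
  expect_equal(unname(st["novel"]), nrow(res$novel))
  expect_true(all(res$rarity$status %in%
                    c("known_cnp", "known_reference", "novel")))
  # singleton status is only defined for novel calls
  expect_true(all(is.na(res$rarity$singleton[res$rarity$status !=
                                               "novel"])))
})
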