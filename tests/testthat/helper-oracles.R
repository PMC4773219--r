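# Independent brute-force oracles and fixture builders.
# The oracles deliberately avoid the implementation's code paths: overlaps
# are counted base by base over materialized integer sets, and clusters are
# the connected components of the full pairwise link matrix obtained by
# boolean matrix powering.

# Base-by-base intersection count (only for small coordinates).
bf_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L)))
}

bf_reciprocal <- function(a, b) {
  ov <- bf_overlap_bp(a, b)
  c(overlap_bp = ov, fraction_a = ov / (a$end - a$start),
    fraction_b = ov / (b$end - b$start))
}

# Connected components of the pairwise linkage graph: adjacency closure by
# repeated boolean multiplication, then component labels by row identity.
bf_clusters <- function(df, min_fraction, key_cols = "chrom") {
  n <- nrow(df)
  if (n == 0) return(integer(0))
  key <- do.call(paste, df[key_cols])
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || key[i] != key[j]) next
    ov <- bf_overlap_bp(df[i, ], df[j, ])
    if (ov > 0 && ov >= min_fraction * (df$end[i] - df$start[i]) &&
        ov >= min_fraction * (df$end[j] - df$start[j])) {
      adj[i, j] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  labels <- apply(adj, 1, function(r) paste(which(r), collapse = ","))
  match(labels, unique(labels))
}

# Two cluster labelings describe the same partition? Canonical form: each
# element labelled by the smallest index sharing its cluster.
same_partition <- function(a, b) {
  canon <- function(x) {
    mins <- tapply(seq_along(x), x, min)
    as.integer(unname(mins[as.character(x)]))
  }
  identical(canon(a), canon(b))
}

# Random valid call table for round-trip and clustering tests.
random_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                         samples = sprintf("S%02d", 1:5),
                         algorithms = c("a1", "a2", "a3")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(5000, n, replace = TRUE)
  type <- sample(c("gain", "loss"), n, replace = TRUE)
  data.frame(
    sample_id = sample(samples, n, replace = TRUE),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len, type = type,
    copy_number = ifelse(type == "loss",
                         sample(0:1, n, replace = TRUE),
                         sample(3:4, n, replace = TRUE)),
    probe_count = sample.int(50, n, replace = TRUE),
    algorithm = sample(algorithms, n, replace = TRUE),
    confidence = NA_real_,
    stringsAsFactors = FALSE)
}

call_key <- function(df) {
  paste(df$sample_id, df$chrom, df$start, df$end, df$type)
}

# Small deterministic annotation for filter tests: one 10 Mb chromosome,
# telomeres 0-20 kb and 9.98-10 Mb, centromere 4.9-5.1 Mb, flat 0.45 GC
# except a 0.75 window at 2.00-2.01 Mb, one gene at 1.50-1.52 Mb.
tiny_annotation <- function() {
  ann <- list(
    chrom_lengths = data.frame(chrom = "chr1", length = 1e7),
    centromeres = data.frame(chrom = "chr1", start = 49e5, end = 51e5),
    telomeres = data.frame(chrom = "chr1", start = c(0, 998e4),
                           end = c(2e4, 1e7)),
    gc = {
      starts <- seq(0, 1e7 - 1e4, by = 1e4)
      g <- rep(0.45, length(starts))
      g[starts == 2e6] <- 0.75
      data.frame(chrom = "chr1", start = starts, end = starts + 1e4,
                 gc = g)
    },
    genes = data.frame(chrom = "chr1", start = 15e5, end = 152e4,
                       gene = "GENE1"))
  class(ann) <- "genome_annotation"
  ann
}

# Evenly spaced manifest on tiny_annotation's chr1: probes at 1000, 3000,
# 5000, ... (internal 0-based), i.e. spacing 2 kb.
tiny_manifest <- function(spacing = 2000, chrom = "chr1", L = 1e7) {
  pos <- seq(1000, L - 1, by = spacing)
  data.frame(probe_id = sprintf("p%05d", seq_along(pos)), chrom = chrom,
             pos = pos, stringsAsFactors = FALSE)
}

# Fast noiseless simulation shared across tests (desk scale, downsized
# genome so the whole suite stays quick).
small_sim_config <- function(seed = 11, ...) {
  sim_config(seed,
             chrom_lengths = c(chr1 = 30e6, chr2 = 25e6, chrX = 15e6),
             n_case = 10L, n_control = 14L,
             n_cnp_loci = 5L, n_shared_rare_loci = 3L,
             singleton_rate_case = 1.5, singleton_rate_control = 1.5,
             recurrent_case_carriers = c(3L, 2L),
             qc_n_probes = 1200L, ...)
}
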