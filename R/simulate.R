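# Synthetic study generator.
#
# Emulates every input the pipeline consumes: a desk-scale genome scaffold
# with centromeres, telomeres and a windowed GC track; a probe manifest; a
# phenotyped case-control cohort (44 cases with left-ventricular
# hypertrophy, 72 hypertensive controls); reference variant catalogues; a
# planted CNV landscape (common polymorphisms, loci shared across groups,
# singletons, recurrent case loci); and three imperfect calling algorithms
# with configurable sensitivity, breakpoint jitter and false-positive rate.
# Every generated object is recorded in a ground-truth ledger so recovery
# can be measured exactly. All randomness flows from config$seed.

#' Simulation configuration with study-design defaults
#'
#' Defaults are fixed to the emulated study's conditions: 44 case and 72
#' control genomes, three callers at realistic 95% sensitivity with 10%
#' breakpoint jitter and 2 false positives per genome, a dozen common
#' polymorphic loci (frequency > 1%), loci shared across groups, an
#' average of two singleton CNVs per genome, and three recurrent
#' case-specific loci carried by 3, 2 and 2 cases. Pass overrides as
#' arguments; unknown names are rejected.
#'
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param ... overrides of any default listed below.
#' @return named list with class "sim_config".
#' @export
sim_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome scaffold
    chrom_lengths = c(chr1 = 60e6, chr2 = 50e6, chr3 = 40e6, chrX = 30e6),
    telomere_bp = 20000,
    centromere_bp = 1e6,
    gc_window_bp = 10000,
    gc_range = c(0.35, 0.55),
    high_gc_rate = 0.02,          # fraction of windows pushed above 0.70
    high_gc_range = c(0.72, 0.80),
    probe_spacing_bp = 5000,
    # cohort
    n_case = 44L, n_control = 72L,
    p_male_case = 37 / 44, p_male_control = 48 / 72,
    lvmi_case_excess = c(mean = 20, sd = 10),   # g/m^2 above threshold
    lvmi_control_deficit = c(mean = 20, sd = 8),# g/m^2 below threshold
    phenotype_error_rate = 0,
    # planted CNV landscape
    n_cnp_loci = 12L,
    cnp_freq_range = c(0.05, 0.30),
    n_shared_rare_loci = 6L,
    singleton_rate_case = 2, singleton_rate_control = 2,
    recurrent_case_carriers = c(3L, 2L, 2L),
    locus_length_range = c(30000, 100000),
    p_loss = 0.8,
    locus_min_probes = 7L,
    locus_separation_bp = 200000,
    # reference catalogues
    n_decoys_dgv = 30L, n_decoys_hapmap3 = 10L, n_decoys_sgvp = 10L,
    hapmap3_cnp_fraction = 0.6, sgvp_cnp_fraction = 0.6,
    decoy_freq_range = c(0.02, 0.20),
    # calling algorithms
    algorithms = c("cnvpart", "penncnv", "ipattern"),
    sensitivity = c(0.95, 0.95, 0.95),
    jitter_fraction = 0.10,
    fp_per_genome = 2,
    fp_length_range = c(2000, 20000),
    fp_buffer_bp = 50000,
    # QC signal emulation
    qc_n_probes = 2000L,
    qc_fail_rate = 0,             # per-sample chance of an injected failure
    call_rate_range = c(0.997, 0.9995),
    lrr_sd_range = c(0.12, 0.20),
    baf_sd_range = c(0.02, 0.05)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(length(cfg$seed) == 1, !is.na(cfg$seed),
            all(cfg$sensitivity >= 0 & cfg$sensitivity <= 1),
            cfg$jitter_fraction >= 0 & cfg$jitter_fraction < 0.5,
            all(cfg$cnp_freq_range > 0.01),
            cfg$phenotype_error_rate >= 0 & cfg$phenotype_error_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the genome scaffold and probe manifest
#'
#' Deterministic under the config seed. Telomeres sit at both chromosome
#' ends, the centromere in the middle; GC windows tile each chromosome
#' with a configurable fraction pushed above 0.70 so the GC filter is
#' exercised; probes are laid at fixed spacing with sub-spacing jitter,
#' giving floor(L / spacing) probes per chromosome to within one.
#'
#' @param config see [sim_config()]; the caller controls the RNG state.
#' @return list: annotation ("genome_annotation"), manifest.
#' @export
make_genome <- function(config) {
  lens <- config$chrom_lengths
  chroms <- names(lens)
  stopifnot(all(chroms %in% .CHROMS), all(lens > 4 * config$centromere_bp))
  regions <- do.call(rbind, lapply(chroms, function(ch) {
    L <- lens[[ch]]
    mid <- round(L / 2)
    data.frame(
      chrom = ch,
      start = c(0, L - config$telomere_bp,
                mid - round(config$centromere_bp / 2)),
      end = c(config$telomere_bp, L,
              mid + round(config$centromere_bp / 2)),
      name = c("telomere", "telomere", "centromere"),
      stringsAsFactors = FALSE)
  }))
  gc <- do.call(rbind, lapply(chroms, function(ch) {
    L <- lens[[ch]]
    starts <- seq(0, L - 1, by = config$gc_window_bp)
    ends <- pmin(starts + config$gc_window_bp, L)
    g <- stats::runif(length(starts), config$gc_range[1],
                      config$gc_range[2])
    hi <- stats::runif(length(starts)) < config$high_gc_rate
    g[hi] <- stats::runif(sum(hi), config$high_gc_range[1],
                          config$high_gc_range[2])
    data.frame(chrom = ch, start = starts, end = ends, gc = g,
               stringsAsFactors = FALSE)
  }))
  s <- config$probe_spacing_bp
  manifest <- do.call(rbind, lapply(chroms, function(ch) {
    L <- lens[[ch]]
    centers <- seq(round(s / 2), L - 1, by = s)
    pos <- pmin(pmax(centers +
                       round(stats::runif(length(centers), -s / 4, s / 4)),
                     0), L - 1)
    data.frame(probe_id = sprintf("%s_p%06d", ch, seq_along(pos)),
               chrom = ch, pos = sort(pos), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(manifest[c("chrom", "pos")])) {
    # spacing/4 jitter cannot cross neighbours, but guard anyway
    manifest <- manifest[!duplicated(manifest[c("chrom", "pos")]), ]
  }
  ann <- list(
    chrom_lengths = data.frame(chrom = chroms, length = unname(lens),
                               stringsAsFactors = FALSE),
    centromeres = regions[regions$name == "centromere",
                          c("chrom", "start", "end")],
    telomeres = regions[regions$name == "telomere",
                        c("chrom", "start", "end")],
    gc = gc,
    genes = .make_genes(chroms, lens))
  class(ann) <- "genome_annotation"
  list(annotation = validate_annotation(ann), manifest = manifest)
}

# A sparse deterministic gene track: one gene every ~400 kb on autosomes.
.make_genes <- function(chroms, lens) {
  do.call(rbind, lapply(setdiff(chroms, .SEX_CHROMS), function(ch) {
    starts <- seq(1e6, lens[[ch]] - 1e6, by = 4e5)
    data.frame(chrom = ch, start = starts,
               end = starts + round(stats::runif(length(starts), 2e4, 2e5)),
               gene = sprintf("%s_G%04d", toupper(ch), seq_along(starts)),
               stringsAsFactors = FALSE)
  }))
}

#' Generate the phenotyped cohort
#'
#' Cases are drawn so their left-ventricular mass index exceeds the
#' sex-specific hypertrophy threshold (controls fall below it), except for
#' a configured fraction of deliberate misclassifications. Echo
#' measurements are solved back from the target LVMI through the Devereux
#' formula so the phenotype module closes the loop exactly.
#'
#' @param config see [sim_config()].
#' @param thresholds see [lvh_thresholds()].
#' @return cohort data.frame with manifest columns plus true_group.
#' @export
make_cohort <- function(config, thresholds = lvh_thresholds()) {
  n <- config$n_case + config$n_control
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  sample_id <- sprintf("S%03d", seq_len(n))
  p_male <- ifelse(group == "case", config$p_male_case,
                   config$p_male_control)
  sex <- ifelse(stats::runif(n) < p_male, "male", "female")
  thr <- ifelse(sex == "female", thresholds$female, thresholds$male)
  excess <- pmax(1, stats::rnorm(n, config$lvmi_case_excess["mean"],
                                 config$lvmi_case_excess["sd"]))
  deficit <- pmax(1, stats::rnorm(n, config$lvmi_control_deficit["mean"],
                                  config$lvmi_control_deficit["sd"]))
  lvmi_target <- ifelse(group == "case", thr + excess,
                        pmax(40, thr - deficit))
  flip <- stats::runif(n) < config$phenotype_error_rate
  lvmi_target[flip] <- ifelse(group[flip] == "case",
                              pmax(40, thr[flip] - deficit[flip]),
                              thr[flip] + excess[flip])
  height <- pmin(1.90, pmax(1.45, stats::rnorm(n, 1.65, 0.07)))
  lvidd <- pmin(6.5, pmax(3.5, stats::rnorm(n, 5.0, 0.4)))
  mass <- lvmi_target * height^2
  # invert Devereux: (lvidd + 2w)^3 = lvidd^3 + (mass - 0.6)/(0.8*1.04)
  outer_dim <- (lvidd^3 + (mass - 0.6) / (0.8 * 1.04))^(1 / 3)
  w <- (outer_dim - lvidd) / 2
  split_f <- stats::runif(n, 0.45, 0.55)
  pwtd <- 2 * w * split_f
  ivstd <- 2 * w - pwtd
  data.frame(
    sample_id = sample_id, group = group, sex = sex,
    age = round(pmin(60, pmax(30, stats::rnorm(n, 53, 6)))),
    bmi = round(stats::rnorm(n, ifelse(group == "case", 28.1, 26.2), 3), 1),
    sbp = round(stats::rnorm(n, ifelse(group == "case", 155.6, 149.9), 15)),
    dbp = round(stats::rnorm(n, 94, 10)),
    lvidd = lvidd, pwtd = pwtd, ivstd = ivstd, height = height,
    stringsAsFactors = FALSE)
}

# Draw a planted locus on an autosome satisfying all CNV filters with
# margin (probe support, GC, centromere/telomere distance, separation from
# previously placed loci). Hard failure after max_tries.
.place_locus <- function(config, genome, existing, max_tries = 2000) {
  ann <- genome$annotation
  auto <- ann$chrom_lengths[!ann$chrom_lengths$chrom %in% .SEX_CHROMS, ]
  features <- rbind(ann$centromeres, ann$telomeres)
  for (k in seq_len(max_tries)) {
    ch <- sample(auto$chrom, 1, prob = auto$length)
    L <- auto$length[auto$chrom == ch]
    len <- round(exp(stats::runif(1, log(config$locus_length_range[1]),
                                  log(config$locus_length_range[2]))))
    start <- floor(stats::runif(1, 0, L - len))
    cand <- data.frame(chrom = ch, start = start, end = start + len)
    if (.gap_to_nearest(cand, features) < 30000 + 2 * len) next
    if (count_probes(cand, genome$manifest) < config$locus_min_probes) next
    gc <- .call_gc(cand, ann$gc)
    if (!is.na(gc) && gc > 0.65) next
    if (nrow(existing)) {
      near <- existing$chrom == ch &
        existing$start < cand$end + config$locus_separation_bp &
        existing$end > cand$start - config$locus_separation_bp
      if (any(near)) next
    }
    return(cand)
  }
  stop("could not place a CNV locus after ", max_tries,
       " tries; enlarge the genome or reduce locus counts")
}

#' Plant the true CNV landscape
#'
#' Loci classes: `cnp` (common polymorphisms, carriers drawn per sample by
#' binomial at the locus frequency), `shared_rare` (carried by at least
#' one case and one control), `singleton` (unique to one sample; the count
#' per genome is Poisson at the configured rate), `recurrent_case`
#' (carried by exactly the configured numbers of distinct case samples).
#' Loci are separated so no two distinct loci reciprocally overlap, and
#' are placed to survive the CNV-level filters.
#'
#' @param config see [sim_config()].
#' @param genome from [make_genome()].
#' @param cohort from [make_cohort()].
#' @return list: `loci` (locus_id, class, chrom, start, end, type,
#'   copy_number, frequency), `truth` (per-sample true CNVs: sample_id +
#'   locus columns).
#' @export
plant_cnvs <- function(config, genome, cohort) {
  loci <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  meta <- list()
  new_locus <- function(class, frequency = NA_real_) {
    cand <- .place_locus(config, genome, loci)
    loci <<- rbind(loci, cand)
    type <- if (stats::runif(1) < config$p_loss) "loss" else "gain"
    meta[[length(meta) + 1]] <<- data.frame(
      locus_id = sprintf("L%03d", length(meta) + 1L),
      class = class, chrom = cand$chrom, start = cand$start,
      end = cand$end, type = type,
      copy_number = if (type == "loss") 1L else 3L,
      frequency = frequency, stringsAsFactors = FALSE)
    meta[[length(meta)]]
  }

  carriers <- list()
  assign_carriers <- function(locus, ids) {
    if (length(ids)) {
      carriers[[length(carriers) + 1]] <<-
        data.frame(sample_id = ids, locus_id = locus$locus_id,
                   stringsAsFactors = FALSE)
    }
  }

  cases <- cohort$sample_id[cohort$group == "case"]
  controls <- cohort$sample_id[cohort$group == "control"]

  for (i in seq_len(config$n_cnp_loci)) {
    fr <- stats::runif(1, config$cnp_freq_range[1], config$cnp_freq_range[2])
    loc <- new_locus("cnp", fr)
    hit <- stats::runif(nrow(cohort)) < fr
    assign_carriers(loc, cohort$sample_id[hit])
  }
  for (i in seq_len(config$n_shared_rare_loci)) {
    loc <- new_locus("shared_rare")
    assign_carriers(loc, c(sample(cases, 1), sample(controls, 1)))
  }
  for (nc in config$recurrent_case_carriers) {
    loc <- new_locus("recurrent_case")
    assign_carriers(loc, sample(cases, nc))
  }
  rate <- ifelse(cohort$group == "case", config$singleton_rate_case,
                 config$singleton_rate_control)
  n_single <- stats::rpois(nrow(cohort), rate)
  for (i in seq_len(nrow(cohort))) {
    for (k in seq_len(n_single[i])) {
      loc <- new_locus("singleton")
      assign_carriers(loc, cohort$sample_id[i])
    }
  }

  loci_meta <- do.call(rbind, meta)
  carrier_df <- if (length(carriers)) do.call(rbind, carriers)
                else data.frame(sample_id = character(0),
                                locus_id = character(0))
  truth <- merge(carrier_df, loci_meta, by = "locus_id", sort = FALSE)
  truth <- truth[order(truth$sample_id, match(truth$chrom, .CHROMS),
                       truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(loci = loci_meta, truth = truth)
}

#' Build the reference variant catalogues
#'
#' Every planted common-polymorphism locus appears in the DGV-like set at
#' its true frequency; configurable fractions also appear in the
#' HapMap3-like and SGVP-like sets. Each set additionally carries decoy
#' variants placed away from all planted loci.
#'
#' @param config see [sim_config()].
#' @param genome from [make_genome()].
#' @param planted from [plant_cnvs()].
#' @return named list of reference sets (dgv, hapmap3, sgvp).
#' @export
make_reference_sets <- function(config, genome, planted) {
  cnp <- planted$loci[planted$loci$class == "cnp", , drop = FALSE]
  all_loci <- planted$loci
  decoys <- function(n, prefix) {
    if (n == 0) return(NULL)
    rows <- vector("list", n)
    occupied <- all_loci[c("chrom", "start", "end")]
    for (i in seq_len(n)) {
      cand <- .place_locus(config, genome, occupied)
      occupied <- rbind(occupied, cand)
      rows[[i]] <- data.frame(
        id = sprintf("%s_D%03d", prefix, i), chrom = cand$chrom,
        start = cand$start, end = cand$end,
        type = sample(c("gain", "loss", "any"), 1),
        frequency = stats::runif(1, config$decoy_freq_range[1],
                                 config$decoy_freq_range[2]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  as_ref <- function(loci, decoy_df, name) {
    base <- if (nrow(loci)) {
      data.frame(id = paste0(name, "_", loci$locus_id), chrom = loci$chrom,
                 start = loci$start, end = loci$end, type = loci$type,
                 frequency = loci$frequency, stringsAsFactors = FALSE)
    } else NULL
    out <- rbind(base, decoy_df)
    if (is.null(out)) {
      out <- data.frame(id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        type = character(0), frequency = numeric(0),
                        stringsAsFactors = FALSE)
    }
    attr(out, "set_name") <- name
    class(out) <- c("reference_set", class(out))
    out
  }
  pick <- function(fraction) {
    if (nrow(cnp) == 0) return(cnp)
    k <- max(1L, round(fraction * nrow(cnp)))
    cnp[sort(sample(nrow(cnp), k)), , drop = FALSE]
  }
  list(
    dgv = as_ref(cnp, decoys(config$n_decoys_dgv, "dgv"), "dgv"),
    hapmap3 = as_ref(pick(config$hapmap3_cnp_fraction),
                     decoys(config$n_decoys_hapmap3, "hapmap3"), "hapmap3"),
    sgvp = as_ref(pick(config$sgvp_cnp_fraction),
                  decoys(config$n_decoys_sgvp, "sgvp"), "sgvp"))
}

#' Emulate the three calling algorithms
#'
#' Each algorithm emits each true CNV with its configured sensitivity,
#' boundaries jittered independently by up to +/- jitter_fraction of the
#' locus length (clamped inside the chromosome), plus Poisson false
#' positives per genome placed away from every planted locus so ledger
#' provenance is unambiguous.
#'
#' @param config see [sim_config()].
#' @param genome from [make_genome()].
#' @param cohort from [make_cohort()].
#' @param planted from [plant_cnvs()].
#' @return list: `callsets` (named list of per-algorithm calls
#'   data.frames, each with a provenance `locus_id` column — NA for false
#'   positives), `emitted` (all emitted calls with algorithm and
#'   true_positive flags).
#' @export
emulate_algorithm_calls <- function(config, genome, cohort, planted) {
  lens <- stats::setNames(genome$annotation$chrom_lengths$length,
                          genome$annotation$chrom_lengths$chrom)
  truth <- planted$truth
  algos <- config$algorithms
  sens <- config$sensitivity
  if (length(sens) == 1) sens <- rep(sens, length(algos))
  stopifnot(length(sens) == length(algos))
  jf <- config$jitter_fraction
  out <- list()
  for (a in seq_along(algos)) {
    # true positives
    tp <- NULL
    if (nrow(truth)) {
      hit <- stats::runif(nrow(truth)) < sens[a]
      tp <- truth[hit, , drop = FALSE]
      if (nrow(tp)) {
        len <- tp$end - tp$start
        js <- round(stats::runif(nrow(tp), -jf, jf) * len)
        je <- round(stats::runif(nrow(tp), -jf, jf) * len)
        start <- pmax(0, tp$start + js)
        end <- pmin(unname(lens[tp$chrom]), tp$end + je)
        bad <- end <= start
        end[bad] <- start[bad] + 1L
        tp <- data.frame(sample_id = tp$sample_id, chrom = tp$chrom,
                         start = as.integer(start), end = as.integer(end),
                         type = tp$type, copy_number = tp$copy_number,
                         probe_count = 0L, algorithm = algos[a],
                         confidence = NA_real_, locus_id = tp$locus_id,
                         stringsAsFactors = FALSE)
      } else tp <- NULL
    }
    # false positives
    fp <- NULL
    n_fp <- stats::rpois(nrow(cohort), config$fp_per_genome)
    if (sum(n_fp) > 0) {
      rows <- vector("list", sum(n_fp))
      r <- 0L
      buffer <- config$fp_buffer_bp
      loci <- planted$loci
      for (i in which(n_fp > 0)) {
        for (k in seq_len(n_fp[i])) {
          repeat {
            ch <- sample(names(lens), 1, prob = lens)
            len <- round(exp(stats::runif(
              1, log(config$fp_length_range[1]),
              log(config$fp_length_range[2]))))
            start <- floor(stats::runif(1, 0, lens[[ch]] - len))
            clash <- loci$chrom == ch & loci$start < start + len + buffer &
              loci$end > start - buffer
            if (!any(clash)) break
          }
          type <- if (stats::runif(1) < config$p_loss) "loss" else "gain"
          r <- r + 1L
          rows[[r]] <- data.frame(
            sample_id = cohort$sample_id[i], chrom = ch,
            start = as.integer(start), end = as.integer(start + len),
            type = type, copy_number = if (type == "loss") 1L else 3L,
            probe_count = 0L, algorithm = algos[a],
            confidence = NA_real_, locus_id = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
      fp <- do.call(rbind, rows)
    }
    calls <- rbind(tp, fp)
    if (is.null(calls)) {
      calls <- cbind(.empty_calls(), locus_id = character(0))
    }
    calls <- calls[order(calls$sample_id, match(calls$chrom, .CHROMS),
                         calls$start), , drop = FALSE]
    rownames(calls) <- NULL
    out[[algos[a]]] <- calls
  }
  emitted <- do.call(rbind, lapply(out, function(df) {
    df$true_positive <- !is.na(df$locus_id)
    df
  }))
  rownames(emitted) <- NULL
  list(callsets = out, emitted = emitted)
}

#' Emulate probe-level QC signals for the cohort
#'
#' Draws per-sample LRR, BAF and genotype-call matrices over a probe
#' subset, with a configurable rate of injected QC failures (a failing
#' sample gets one of: depressed call rate, inflated LRR noise, inflated
#' heterozygous BAF noise, or inflated batch-ratio noise).
#'
#' @param config see [sim_config()].
#' @param cohort from [make_cohort()].
#' @return list: lrr, baf, called matrices (probes x samples, named
#'   columns), `injected` data.frame (sample_id, failure among "" /
#'   CALL_RATE / LRR_SD / BAF_SD / BATCH_RATIO_SD).
#' @export
emulate_qc_signals <- function(config, cohort) {
  n <- nrow(cohort)
  p <- config$qc_n_probes
  fail <- ifelse(stats::runif(n) < config$qc_fail_rate,
                 sample(c("CALL_RATE", "LRR_SD", "BAF_SD",
                          "BATCH_RATIO_SD"), n, replace = TRUE), "")
  lrr_sd <- stats::runif(n, config$lrr_sd_range[1], config$lrr_sd_range[2])
  lrr_sd[fail == "LRR_SD"] <- stats::runif(sum(fail == "LRR_SD"), 0.45, 0.6)
  lrr_sd[fail == "BATCH_RATIO_SD"] <- 0.55  # ratio noise tracks LRR noise
  call_rate <- stats::runif(n, config$call_rate_range[1],
                            config$call_rate_range[2])
  call_rate[fail == "CALL_RATE"] <-
    stats::runif(sum(fail == "CALL_RATE"), 0.93, 0.97)
  baf_sd <- stats::runif(n, config$baf_sd_range[1], config$baf_sd_range[2])

  lrr <- matrix(stats::rnorm(p * n, 0, rep(lrr_sd, each = p)), nrow = p,
                dimnames = list(NULL, cohort$sample_id))
  het <- stats::runif(p) < 1 / 3
  baf <- matrix(0, nrow = p, ncol = n,
                dimnames = list(NULL, cohort$sample_id))
  for (j in seq_len(n)) {
    b <- ifelse(stats::runif(p) < 0.5, 0, 1) +
      stats::rnorm(p, 0, 0.01)
    if (fail[j] == "BAF_SD") {
      # artifactual split of the heterozygous band (two sub-clusters)
      b[het] <- 0.5 + sample(c(-0.2, 0.2), sum(het), replace = TRUE) +
        stats::rnorm(sum(het), 0, 0.03)
    } else {
      b[het] <- stats::rnorm(sum(het), 0.5, baf_sd[j])
    }
    baf[, j] <- pmin(1, pmax(0, b))
  }
  called <- matrix(stats::runif(p * n) < rep(call_rate, each = p), nrow = p,
                   dimnames = list(NULL, cohort$sample_id))
  list(lrr = lrr, baf = baf, called = called,
       injected = data.frame(sample_id = cohort$sample_id, failure = fail,
                             stringsAsFactors = FALSE))
}

#' Expected case-specific calls implied by the truth ledger
#'
#' Given the samples the pipeline actually analyzed, the noiseless-limit
#' case-specific set is every planted non-polymorphic call carried by a
#' kept case sample whose locus has no kept control carrier. (Common
#' polymorphisms are always removed by the reference rules; a locus whose
#' control carriers were all excluded at sample QC is legitimately
#' case-specific among the analyzed genomes.)
#'
#' @param truth truth ledger from [plant_cnvs()].
#' @param cohort cohort data.frame (sample_id, group).
#' @param kept sample_ids retained by QC (default: all).
#' @return the expected case-specific subset of `truth`.
#' @export
ledger_case_specific <- function(truth, cohort, kept = cohort$sample_id) {
  grp <- stats::setNames(cohort$group, cohort$sample_id)
  t_kept <- truth[truth$sample_id %in% kept &
                    truth$class != "cnp", , drop = FALSE]
  ctrl_loci <- unique(t_kept$locus_id[grp[t_kept$sample_id] == "control"])
  t_kept[grp[t_kept$sample_id] == "case" &
           !t_kept$locus_id %in% ctrl_loci, , drop = FALSE]
}

#' Generate a complete synthetic study
#'
#' Runs the full generator chain under the config seed and returns every
#' pipeline input plus the ground-truth ledger.
#'
#' @param config see [sim_config()].
#' @return list: config, annotation, manifest, cohort, planted (loci +
#'   truth), references, callsets, emitted, signals.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  genome <- make_genome(config)
  cohort <- make_cohort(config)
  planted <- plant_cnvs(config, genome, cohort)
  references <- make_reference_sets(config, genome, planted)
  calls <- emulate_algorithm_calls(config, genome, cohort, planted)
  signals <- emulate_qc_signals(config, cohort)
  list(config = config,
       annotation = genome$annotation, manifest = genome$manifest,
       cohort = cohort, planted = planted, references = references,
       callsets = calls$callsets, emitted = calls$emitted,
       signals = signals)
}
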