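# Readers and writers for the tabular genomic formats the pipeline touches.
#
# Disk conventions:
#   * rawcnv and DGV-style reference files: 1-based, closed intervals.
#   * BED-flavoured files (generic call TSV, gene models, GC track,
#     centromere/telomere regions): 0-based, half-open.
# Everything is converted to the internal 0-based half-open convention on
# read and back on write, so the conversion is an involution.

.CALL_COLS <- c("sample_id", "chrom", "start", "end", "type",
                "copy_number", "probe_count", "algorithm", "confidence")

.empty_calls <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), type = character(0),
             copy_number = integer(0), probe_count = integer(0),
             algorithm = character(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

.check_calls <- function(calls) {
  validate_intervals(calls, "CNV call")
  stopifnot(all(calls$type %in% c("gain", "loss")))
  cn <- calls$copy_number
  has <- !is.na(cn)
  bad <- has & ((cn < 2 & calls$type != "loss") |
                (cn > 2 & calls$type != "gain") | cn == 2)
  if (any(bad)) stop("copy_number inconsistent with cnv type in ",
                     sum(bad), " call(s)")
  invisible(calls)
}

#' Read CNV calls from disk
#'
#' Supports the PennCNV-style `rawcnv` dialect (whitespace-separated fields
#' `chrN:start-end numsnp= length= stateK,cn= sample startsnp= endsnp=`,
#' 1-based closed coordinates) and a generic BED-flavoured TSV with header
#' `sample_id chrom start end type cn probes algorithm` (0-based half-open).
#'
#' Records with unknown chromosome labels are dropped with a warning giving
#' their count; an unparseable mandatory field is a hard failure naming the
#' offending line.
#'
#' @param path input file.
#' @param dialect "rawcnv" or "tsv".
#' @return calls data.frame (internal 0-based half-open coordinates), in
#'   file order.
#' @export
read_calls <- function(path, dialect = c("rawcnv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "rawcnv") .read_rawcnv(path) else .read_call_tsv(path)
}

.read_rawcnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(.empty_calls())
  grab <- function(fields, key, lineno, mandatory = TRUE) {
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (length(hit) == 0) {
      if (mandatory) stop("rawcnv line ", lineno, ": missing ", key, "=")
      return(NA_character_)
    }
    sub(paste0("^", key, "="), "", hit[1])
  }
  recs <- vector("list", length(lines))
  n_bad_chrom <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    m <- regmatches(f[1], regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", f[1]))[[1]]
    if (length(m) != 4) stop("rawcnv line ", i, ": cannot parse region '",
                             f[1], "'")
    chrom <- normalize_chrom(m[2], strict = FALSE)
    if (is.na(chrom)) { n_bad_chrom <- n_bad_chrom + 1L; next }
    start1 <- as.integer(gsub(",", "", m[3]))
    end1 <- as.integer(gsub(",", "", m[4]))
    numsnp <- suppressWarnings(as.integer(grab(f, "numsnp", i)))
    statef <- grep("^state[0-9]+,cn=[0-9]+$", f, value = TRUE)
    if (length(statef) == 0) stop("rawcnv line ", i, ": missing state,cn field")
    cn <- as.integer(sub("^state[0-9]+,cn=", "", statef[1]))
    sample_id <- setdiff(f[-1], grep("=", f[-1], value = TRUE))[1]
    if (is.na(sample_id)) stop("rawcnv line ", i, ": missing sample field")
    if (is.na(start1) || is.na(end1) || is.na(numsnp) || is.na(cn)) {
      stop("rawcnv line ", i, ": unparseable numeric field")
    }
    recs[[i]] <- data.frame(
      sample_id = sample_id, chrom = chrom,
      start = start1 - 1L, end = end1,
      type = if (cn < 2) "loss" else "gain",
      copy_number = cn, probe_count = numsnp,
      algorithm = NA_character_, confidence = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (n_bad_chrom > 0) {
    warning("dropped ", n_bad_chrom, " record(s) with unknown chromosome")
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else .empty_calls()
  .check_calls(out)
  out
}

.read_call_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("call TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(.empty_calls())
  chrom <- normalize_chrom(df$chrom, strict = FALSE)
  n_bad <- sum(is.na(chrom))
  if (n_bad > 0) warning("dropped ", n_bad,
                         " record(s) with unknown chromosome")
  keep <- !is.na(chrom)
  out <- data.frame(
    sample_id = as.character(df$sample_id[keep]),
    chrom = chrom[keep],
    start = as.integer(df$start[keep]),
    end = as.integer(df$end[keep]),
    type = as.character(df$type[keep]),
    copy_number = if ("cn" %in% names(df)) as.integer(df$cn[keep])
                  else NA_integer_,
    probe_count = if ("probes" %in% names(df)) as.integer(df$probes[keep])
                  else 0L,
    algorithm = if ("algorithm" %in% names(df))
                  as.character(df$algorithm[keep]) else NA_character_,
    confidence = if ("confidence" %in% names(df))
                  as.numeric(df$confidence[keep]) else NA_real_,
    stringsAsFactors = FALSE)
  .check_calls(out)
  out
}

#' Write CNV calls to disk
#'
#' Rows are sorted deterministically by (chromosome, start, sample_id).
#' The rawcnv dialect writes 1-based closed coordinates; the tsv dialect is
#' BED-flavoured (0-based half-open).
#'
#' @param calls calls data.frame.
#' @param path output file.
#' @param dialect "rawcnv" or "tsv".
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, dialect = c("rawcnv", "tsv")) {
  dialect <- match.arg(dialect)
  .check_calls(calls)
  ord <- order(match(calls$chrom, .CHROMS), calls$start, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  if (dialect == "rawcnv") {
    cn <- ifelse(is.na(calls$copy_number),
                 ifelse(calls$type == "loss", 1L, 3L), calls$copy_number)
    state <- ifelse(cn < 2, 2L, 5L)  # PennCNV-style state labels
    lines <- sprintf(
      "%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s startsnp=na endsnp=na",
      calls$chrom, calls$start + 1L, calls$end, calls$probe_count,
      formatC(calls$end - calls$start, big.mark = ",", format = "d"),
      state, cn, calls$sample_id)
    writeLines(lines, path)
  } else {
    out <- data.frame(sample_id = calls$sample_id, chrom = calls$chrom,
                      start = calls$start, end = calls$end,
                      type = calls$type, cn = calls$copy_number,
                      probes = calls$probe_count,
                      algorithm = calls$algorithm,
                      confidence = calls$confidence)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a reference variant set (DGV-style TSV)
#'
#' Expected header: `id chrom start end type frequency`, with 1-based closed
#' coordinates and `type` one of gain/loss/any. `frequency` may be empty.
#'
#' @param path input TSV.
#' @param name label attached to the set (used in match records).
#' @return data.frame with class "reference_set" (internal coordinates).
#' @export
read_reference_set <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("reference set missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(
    id = as.character(df$id),
    chrom = normalize_chrom(df$chrom),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    type = as.character(df$type),
    frequency = if ("frequency" %in% names(df)) as.numeric(df$frequency)
                else NA_real_,
    stringsAsFactors = FALSE)
  stopifnot(all(out$type %in% c("gain", "loss", "any")))
  fr <- out$frequency
  if (any(!is.na(fr) & (fr < 0 | fr > 1))) {
    stop("reference frequencies must lie in [0, 1]")
  }
  validate_intervals(out, "reference variant")
  attr(out, "set_name") <- name
  class(out) <- c("reference_set", class(out))
  out
}

#' Write a reference variant set (DGV-style TSV, 1-based closed)
#' @param ref reference set data.frame.
#' @param path output file.
#' @export
write_reference_set <- function(ref, path) {
  out <- data.frame(id = ref$id, chrom = ref$chrom,
                    start = ref$start + 1L, end = ref$end,
                    type = ref$type, frequency = ref$frequency)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a probe manifest
#'
#' Expected header: `probe_id chrom position` with 1-based positions.
#' Probe ids must be unique; positions are sorted within chromosome.
#'
#' @param path input TSV.
#' @return data.frame (probe_id, chrom, pos) with pos 0-based internal.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("probe_id", "chrom", "position"), names(df))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("manifest probe_ids must be unique")
  out <- data.frame(probe_id = as.character(df$probe_id),
                    chrom = normalize_chrom(df$chrom),
                    pos = as.integer(df$position) - 1L,
                    stringsAsFactors = FALSE)
  out[order(match(out$chrom, .CHROMS), out$pos), , drop = FALSE]
}

#' Write a probe manifest (1-based positions on disk)
#' @param manifest manifest data.frame.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(probe_id = manifest$probe_id, chrom = manifest$chrom,
                    position = manifest$pos + 1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genome annotation from its component files
#'
#' @param chrom_lengths_path TSV `chrom length`.
#' @param regions_path BED4-style TSV `chrom start end name` where name is
#'   "centromere" or "telomere" (0-based half-open).
#' @param gc_path TSV `chrom start end gc` (0-based half-open windows).
#' @param genes_path BED4 `chrom start end gene` (0-based half-open); GFF3
#'   gene lines (`seqid source type start end . strand . ID=...;Name=...`)
#'   are also accepted.
#' @return a "genome_annotation" list: chrom_lengths, centromeres,
#'   telomeres, gc, genes.
#' @export
read_annotation <- function(chrom_lengths_path, regions_path, gc_path,
                            genes_path) {
  lens <- utils::read.delim(chrom_lengths_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "length"), names(lens))
  if (length(miss)) stop("chromosome lengths missing column(s): ",
                         paste(miss, collapse = ", "))
  lens$chrom <- normalize_chrom(lens$chrom)

  reg <- utils::read.delim(regions_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  reg$chrom <- normalize_chrom(reg$chrom)

  gc <- utils::read.delim(gc_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "start", "end", "gc"), names(gc))
  if (length(miss)) stop("GC track missing column(s): ",
                         paste(miss, collapse = ", "))
  gc$chrom <- normalize_chrom(gc$chrom)

  genes <- .read_genes(genes_path)

  ann <- list(
    chrom_lengths = lens,
    centromeres = reg[reg$name == "centromere",
                      c("chrom", "start", "end"), drop = FALSE],
    telomeres = reg[reg$name == "telomere",
                    c("chrom", "start", "end"), drop = FALSE],
    gc = gc,
    genes = genes)
  class(ann) <- "genome_annotation"
  validate_annotation(ann)
  ann
}

.read_genes <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t.*\t.*\t.*\t.*\t.*\t.*\t.*\t", first)) {  # 9-column GFF3
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    df <- df[df$V3 == "gene", , drop = FALSE]
    sym <- sub(".*Name=([^;]+).*", "\\1", df$V9)
    data.frame(chrom = normalize_chrom(df$V1),
               start = as.integer(df$V4) - 1L, end = as.integer(df$V5),
               gene = sym, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "gene"))
    data.frame(chrom = normalize_chrom(df$chrom),
               start = as.integer(df$start), end = as.integer(df$end),
               gene = as.character(df$gene), stringsAsFactors = FALSE)
  }
}

#' Validate a genome annotation object
#' @param ann "genome_annotation" list.
#' @return the input, invisibly.
#' @export
validate_annotation <- function(ann) {
  lens <- stats::setNames(ann$chrom_lengths$length, ann$chrom_lengths$chrom)
  for (part in c("centromeres", "telomeres", "gc", "genes")) {
    df <- ann[[part]]
    if (nrow(df) == 0) next
    validate_intervals(df, part)
    if (any(df$start < 0) || any(df$end > lens[df$chrom])) {
      stop(part, ": interval outside chromosome bounds")
    }
  }
  if (nrow(ann$gc) && (any(ann$gc$gc < 0) || any(ann$gc$gc > 1))) {
    stop("GC fractions must lie in [0, 1]")
  }
  invisible(ann)
}

#' Read a sample manifest (cohort CSV)
#'
#' Expected columns: sample_id, group (case/control), sex (male/female),
#' age, bmi, sbp, dbp, lvidd, pwtd, ivstd, height. Echo columns may be
#' empty for samples without echocardiography.
#'
#' @param path input CSV.
#' @return cohort data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "group", "sex"), names(df))
  if (length(miss)) stop("sample manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample_ids must be unique")
  stopifnot(all(df$group %in% c("case", "control")),
            all(df$sex %in% c("male", "female")))
  df
}

#' Write a sample manifest
#' @param samples cohort data.frame.
#' @param path output CSV.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
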