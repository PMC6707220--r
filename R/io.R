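## -------------------------------------------------------------------------
## Plain-text input/output: SNV read tables (TSV / minimal VCF), segment
## tables (Battenberg-like TSV, 1-based inclusive), SV breakpoint pairs
## (BEDPE, 0-based half-open) and flat key=value config files.
## -------------------------------------------------------------------------

#' Write / read an SNV read-count table (TSV)
#'
#' Columns: `mutation_id`, `sample_id`, `alt_reads`, `total_reads`,
#' `segment_id`.
#'
#' @param reads Data.frame as produced by [simulate_reads()].
#' @param path File path.
#' @return `read_snv_tsv` returns the data.frame.
#' @export
write_snv_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snv_tsv
#' @export
read_snv_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write SNVs as a minimal VCF
#'
#' One record per mutation with AD-style per-sample fields
#' (`GT:AD:DP`, AD = ref,alt depths). Positions are taken from `chrom` /
#' `pos` columns when present, otherwise synthesized deterministically from
#' the segment id.
#'
#' @param reads Long read table (`mutation_id`, `sample_id`, `alt_reads`,
#'   `total_reads`, `segment_id`, optional `chrom`, `pos`).
#' @param path Output path (uncompressed `.vcf`).
#' @export
write_snv_vcf <- function(reads, path) {
  muts <- unique(reads$mutation_id)
  samples <- sort(unique(reads$sample_id))
  chrom <- if ("chrom" %in% names(reads)) {
    reads$chrom[match(muts, reads$mutation_id)]
  } else {
    sub("_.*", "", reads$segment_id[match(muts, reads$mutation_id)])
  }
  pos <- if ("pos" %in% names(reads)) {
    reads$pos[match(muts, reads$mutation_id)]
  } else {
    seq_along(muts) * 1000L
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(muts), function(i) {
    cells <- vapply(samples, function(s) {
      row <- reads[reads$mutation_id == muts[i] & reads$sample_id == s, ]
      if (nrow(row) == 0L) return("./.:.,.:.")
      sprintf("0/1:%d,%d:%d", row$total_reads[1] - row$alt_reads[1],
              row$alt_reads[1], row$total_reads[1])
    }, character(1))
    paste(c(chrom[i], pos[i], muts[i], "A", "T", ".", "PASS", ".",
            "GT:AD:DP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF back into a long read table
#'
#' Uses vcfR when installed; expects the `GT:AD:DP` layout written by
#' [write_snv_vcf()].
#'
#' @param path VCF path.
#' @return Data.frame with `mutation_id`, `sample_id`, `alt_reads`,
#'   `total_reads`.
#' @export
read_snv_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ids <- v@fix[, "ID"]
  out <- do.call(rbind, lapply(colnames(ad), function(s) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    alt <- suppressWarnings(vapply(parts, function(p)
      as.numeric(p[2]), numeric(1)))
    data.frame(mutation_id = ids, sample_id = s, alt_reads = alt,
               total_reads = dp[, s])
  }))
  rownames(out) <- NULL
  out[!is.na(out$alt_reads), , drop = FALSE]
}

#' Write / read an allele-specific copy-number segment table
#'
#' Battenberg-like TSV: `segment_id`, `chrom`, `start`, `end` (1-based,
#' inclusive), `major_cn`, `minor_cn`, `ccf`, `purity`.
#'
#' @param segments Segment data.frame.
#' @param path File path.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
  df
}

#' Write / read SV breakpoint pairs as BEDPE
#'
#' 0-based half-open coordinates, ten standard columns then `sv_class`,
#' `supporting_reads`, `total_reads`.
#'
#' @param svs Data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `strand1`, `strand2`, `sv_id`, `sv_class`, `supporting_reads`,
#'   `total_reads` (positions 1-based; converted on write).
#' @param path File path.
#' @export
write_bedpe <- function(svs, path) {
  df <- data.frame(chrom1 = svs$chrom1, start1 = svs$pos1 - 1L,
                   end1 = svs$pos1, chrom2 = svs$chrom2,
                   start2 = svs$pos2 - 1L, end2 = svs$pos2,
                   name = svs$sv_id, score = ".",
                   strand1 = svs$strand1 %||% "+",
                   strand2 = svs$strand2 %||% "-",
                   sv_class = svs$sv_class %||% "deletion",
                   supporting_reads = svs$supporting_reads,
                   total_reads = svs$total_reads)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:13] <- c("chrom1", "start1", "end1", "chrom2", "start2",
                       "end2", "sv_id", "score", "strand1", "strand2",
                       "sv_class", "supporting_reads", "total_reads")
  df$pos1 <- df$start1 + 1L
  df$pos2 <- df$start2 + 1L
  df
}

#' Flat key=value configuration files
#'
#' @param config Named list of scalars.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), "=", unlist(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' Default pipeline configuration
#'
#' All tunables in one place: pigeonhole tolerated error 0.001 and minimum
#' subclone size 50, DP chain 1000 sweeps with 300 burn-in, timing
#' eligibility (> 1 Mb, > 50 clonal SNVs), WGD ploidy threshold 3,
#' multiplicity posterior threshold 0.8, SV posterior threshold 0.9,
#' 1000 bootstrap replicates at the 95% level.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(tolerated_error = 0.001, min_mutations = 50,
       n_iter = 1000, n_burnin = 300,
       min_segment_length = 1e6, min_clonal_snvs = 50,
       wgd_ploidy = 3, min_assign_prob = 0.8,
       rvaf_threshold = 0.9, n_boot = 1000, alpha = 0.05)
}
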