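# VCF interchange for variant records. The INFO dialect used (all optional):
#   AF (vaf), DP (depth), MQ (mapping quality), MPOS (mean position in read),
#   NM (mean read mismatches), MSILEN (microsatellite length), TLOD, FS,
#   POP_AF / POP_AC (population frequency / carrier count), GENE,
#   COSMIC_N (COSMIC patient count), PON_N (pool-of-normal patient count),
#   and the flags CGC_TIER1, COSMIC, CLINVAR.
# Filter labels travel in the FILTER column (PASS when somatic_pass).

.vcf_info_spec <- c(
  AF = "vaf", DP = "depth", MQ = "mapping_quality", MPOS = "mean_read_position",
  NM = "mean_mismatches", MSILEN = "microsatellite_length", TLOD = "tlod",
  FS = "fs_phred", POP_AF = "population_af", POP_AC = "population_count",
  COSMIC_N = "cosmic_patient_count", PON_N = "pon_patients"
)
.vcf_flag_spec <- c(CGC_TIER1 = "cgc_tier1", COSMIC = "in_cosmic",
                    CLINVAR = "in_clinvar")

#' Read variant records from a VCF file
#'
#' Maps the INFO keys of a (possibly gzipped) VCF into the variant-record
#' columns the filtering cascade consumes: `AF`, `DP`, `MQ`, `MPOS`, `NM`,
#' `MSILEN`, `TLOD`, `FS`, `POP_AF`, `POP_AC`, `GENE`, `COSMIC_N`, `PON_N`,
#' plus the flags `CGC_TIER1`, `COSMIC`, `CLINVAR`. Missing keys yield NA (or
#' FALSE for flags). The FILTER column is kept in `filter_labels`.
#'
#' @param file Path to a VCF file.
#' @return Data frame of variant records.
#' @export
read_variant_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(
    chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  for (key in names(.vcf_info_spec)) {
    out[[.vcf_info_spec[[key]]]] <-
      suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  out$depth <- as.integer(out$depth)
  out$microsatellite_length <- as.integer(out$microsatellite_length)
  out$population_count <- as.integer(out$population_count)
  out$cosmic_patient_count <- as.integer(out$cosmic_patient_count)
  out$pon_patients <- as.integer(out$pon_patients)
  gene <- vcfR::extract.info(v, element = "GENE")
  out$gene <- ifelse(is.na(gene), NA_character_, gene)
  info <- v@fix[, "INFO"]
  for (key in names(.vcf_flag_spec)) {
    out[[.vcf_flag_spec[[key]]]] <-
      grepl(paste0("(^|;)", key, "(;|$)"), info)
  }
  out$filter_labels <- fix$FILTER
  out
}

#' Write labeled variant records as a VCF file
#'
#' Inverse of [read_variant_vcf()]: record fields become INFO keys, and the
#' cascade's labels are serialized into the FILTER column (`PASS` for records
#' with `somatic_pass`, the semicolon-joined label set otherwise, `.` when the
#' cascade has not run). Output is bgzip-compressed when `file` ends in `.gz`,
#' plain text otherwise.
#'
#' @param records Variant data frame (labeled or not).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_variant_vcf <- function(records, file) {
  .check_records(records)
  n <- nrow(records)
  info <- character(n)
  add <- function(info, key, value) {
    text <- if (is.numeric(value)) {
      vapply(value, function(v) {
        if (is.na(v)) "" else format(v, trim = TRUE, scientific = FALSE)
      }, character(1))
    } else {
      ifelse(is.na(value), "", as.character(value))
    }
    piece <- ifelse(text == "", "", paste0(key, "=", text))
    ifelse(piece == "", info, ifelse(info == "", piece,
                                     paste(info, piece, sep = ";")))
  }
  for (key in names(.vcf_info_spec)) {
    col <- .vcf_info_spec[[key]]
    if (col %in% names(records)) info <- add(info, key, records[[col]])
  }
  if ("gene" %in% names(records)) info <- add(info, "GENE", records$gene)
  for (key in names(.vcf_flag_spec)) {
    col <- .vcf_flag_spec[[key]]
    if (col %in% names(records)) {
      info <- ifelse(!is.na(records[[col]]) & records[[col]],
                     ifelse(info == "", key, paste(info, key, sep = ";")), info)
    }
  }
  info[info == ""] <- "."

  label_cols <- c("quality_fail", "common_germline", "vaf_germline", "pon",
                  "rescued_hotspot")
  have <- intersect(label_cols, names(records))
  filter <- rep(".", n)
  if ("somatic_pass" %in% names(records)) {
    labels <- vapply(seq_len(n), function(i) {
      set <- have[vapply(have, function(c) isTRUE(records[[c]][i]), logical(1))]
      paste(set, collapse = ";")
    }, character(1))
    filter <- ifelse(records$somatic_pass, "PASS",
                     ifelse(labels == "", ".", labels))
  }

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            c(names(.vcf_info_spec), "GENE", names(.vcf_flag_spec)),
            c(rep("Float", length(.vcf_info_spec)), "String",
              rep("Flag", length(.vcf_flag_spec))),
            c(.vcf_info_spec, "gene symbol", .vcf_flag_spec)),
    paste0("##FILTER=<ID=", label_cols, ",Description=\"", label_cols, "\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", records$chromosome,
                  records$position, records$ref, records$alt, filter, info)
  if (grepl("\\.gz$", file)) {
    con <- gzfile(file, "w")
    on.exit(close(con))
    writeLines(c(header, body), con)
  } else {
    writeLines(c(header, body), file)
  }
  invisible(file)
}
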