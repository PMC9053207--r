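#' @name tmbsite-io
#' @title Tabular dialects
#' @description All tables are written as UTF-8 tab-separated text with a
#'   `# tmbsite <name> v1` dialect line, a header row and ISO-8601 dates;
#'   comma-separated files are accepted on read. Specimen tables carry the
#'   columns `specimen_id`, `patient_id`, `cancer_type`, `biopsy_site`,
#'   `collection_date`, `tmb`, `purity_pathologist`, `purity_computational`,
#'   `median_coverage`, `is_primary_site`; metastasis records carry
#'   `patient_id`, `site`, `record_date`; site maps carry `cancer_type`,
#'   `primary_site`.
NULL

.specimen_cols <- c("specimen_id", "patient_id", "cancer_type",
                    "biopsy_site", "collection_date", "tmb",
                    "purity_pathologist", "purity_computational",
                    "median_coverage", "is_primary_site")

.sniff_sep <- function(path) {
  for (ln in readLines(path, n = 5L))
    if (!startsWith(ln, "#"))
      return(if (grepl("\t", ln)) "\t" else ",")
  "\t"
}

.read_dialect <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = .sniff_sep(path), comment.char = "#",
                    stringsAsFactors = FALSE)
}

.write_dialect <- function(x, path, name) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# tmbsite %s v1", name), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a specimen table
#'
#' Parses and validates the specimen dialect (see [tmbsite-io]). Rows that
#' violate record invariants (purity outside \[0,1\], non-positive
#' coverage, negative TMB, unparseable date) are rejected with their line
#' numbers reported via `warning()`.
#'
#' @param path delimited text file.
#' @return validated specimen data.frame.
#' @export
read_specimen_table <- function(path) {
  x <- .read_dialect(path)
  miss <- setdiff(.specimen_cols, names(x))
  if (length(miss))
    stop("specimen table missing required column(s): ",
         paste(miss, collapse = ", "))
  x <- x[.specimen_cols]
  x$collection_date <- as.Date(as.character(x$collection_date),
                               format = "%Y-%m-%d")
  x$is_primary_site <- as.logical(x$is_primary_site)
  # tmb may be NA (scored later from variants); negative scores are invalid
  bad <- is.na(x$collection_date) |
    (!is.na(x$tmb) & x$tmb < 0) |
    is.na(x$purity_pathologist) | x$purity_pathologist < 0 |
    x$purity_pathologist > 1 |
    is.na(x$purity_computational) | x$purity_computational < 0 |
    x$purity_computational > 1 |
    is.na(x$median_coverage) | x$median_coverage <= 0
  if (any(bad)) {
    warning(sprintf("rejected %d malformed specimen row(s) at line(s): %s",
                    sum(bad),
                    paste(which(bad) + 2L, collapse = ", ")))
    x <- x[!bad, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_specimen_table
#' @param specimens specimen data.frame to write.
#' @export
write_specimen_table <- function(specimens, path) {
  .write_dialect(specimens[.specimen_cols], path, "specimens")
}

#' Read / write metastasis-history records
#'
#' Three columns: `patient_id`, `site`, `record_date` (ISO-8601).
#'
#' @param path delimited text file.
#' @return data.frame of records.
#' @export
read_met_records <- function(path) {
  x <- .read_dialect(path)
  miss <- setdiff(c("patient_id", "site", "record_date"), names(x))
  if (length(miss))
    stop("metastasis table missing required column(s): ",
         paste(miss, collapse = ", "))
  x$record_date <- as.Date(as.character(x$record_date), format = "%Y-%m-%d")
  bad <- is.na(x$record_date)
  if (any(bad)) {
    warning(sprintf("rejected %d metastasis row(s) with unparseable dates at line(s): %s",
                    sum(bad), paste(which(bad) + 2L, collapse = ", ")))
    x <- x[!bad, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_met_records
#' @param met_records data.frame to write.
#' @export
write_met_records <- function(met_records, path) {
  .write_dialect(met_records[c("patient_id", "site", "record_date")],
                 path, "met_records")
}

#' Read / write the primary-site map
#'
#' Two columns: `cancer_type`, `primary_site`.
#'
#' @param path delimited text file.
#' @return named character vector, cancer type -> primary site.
#' @export
read_site_map <- function(path) {
  x <- .read_dialect(path)
  miss <- setdiff(c("cancer_type", "primary_site"), names(x))
  if (length(miss))
    stop("site map missing required column(s): ", paste(miss, collapse = ", "))
  as_site_map(x)
}

#' @rdname read_site_map
#' @param site_map named vector or data.frame to write.
#' @export
write_site_map <- function(site_map, path) {
  site_map <- as_site_map(site_map)
  .write_dialect(data.frame(cancer_type = names(site_map),
                            primary_site = unname(site_map)),
                 path, "site_map")
}

#' Read / write variant calls
#'
#' The tabular dialect mirrors the [generate_cohort()] variant table.
#' `write_variants_vcf()` emits a minimal VCF 4.2 with per-record INFO keys
#' `AF` (allele frequency), `FC` (functional class) and `SS` (somatic
#' status) plus a `SPECIMEN` key; `read_variants_vcf()` parses the same
#' minimal subset back.
#'
#' @param path file path.
#' @return variant data.frame.
#' @export
read_variant_table <- function(path) {
  x <- .read_dialect(path)
  miss <- setdiff(c("specimen_id", "allele_frequency", "functional_class",
                    "somatic_status"), names(x))
  if (length(miss))
    stop("variant table missing required column(s): ",
         paste(miss, collapse = ", "))
  if ("chrom" %in% names(x)) x$chrom <- as.character(x$chrom)
  x
}

#' @rdname read_variant_table
#' @param variants variant data.frame.
#' @export
write_variant_table <- function(variants, path) {
  .write_dialect(variants, path, "variants")
}

#' @rdname read_variant_table
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=FC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=SS,Number=1,Type=String,Description=\"Somatic status\">",
    "##INFO=<ID=SPECIMEN,Number=1,Type=String,Description=\"Specimen id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- sprintf("AF=%.6g;FC=%s;SS=%s;SPECIMEN=%s",
                  variants$allele_frequency, variants$functional_class,
                  variants$somatic_status, variants$specimen_id)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                     as.character(variants$chrom), as.integer(variants$pos),
                     variants$ref, variants$alt, info), con)
  invisible(path)
}

#' @rdname read_variant_table
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variants_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  if (nrow(fx) == 0L)
    return(data.frame(specimen_id = character(),
                      allele_frequency = numeric(),
                      functional_class = character(),
                      somatic_status = character()))
  data.frame(
    specimen_id = vcfR::extract.info(v, "SPECIMEN"),
    chrom = unname(fx[, "CHROM"]),
    pos = as.integer(fx[, "POS"]),
    ref = unname(fx[, "REF"]),
    alt = unname(fx[, "ALT"]),
    allele_frequency = vcfR::extract.info(v, "AF", as.numeric = TRUE),
    functional_class = vcfR::extract.info(v, "FC"),
    somatic_status = vcfR::extract.info(v, "SS"),
    stringsAsFactors = FALSE
  )
}
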