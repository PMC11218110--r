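#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds unique gene IDs and
#' whose header names the samples. Duplicate gene IDs and non-numeric cells
#' are rejected with the offending line reported.
#'
#' @param path file path
#' @param unit unit tag to attach ("counts", "FPKM", "normalized", "log2")
#' @return numeric matrix with gene rownames, sample colnames and a `unit`
#'   attribute
#' @export
read_expression <- function(path, unit = c("counts", "FPKM", "normalized", "log2")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expected gene-ID column plus at least one sample")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0)
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (anyNA(num)) {
    bad_row <- which(rowSums(is.na(num)) > 0)[1]
    stop("non-numeric cell at data line ", bad_row + 1, " of ", path)
  }
  num <- matrix(num, nrow = length(genes),
                dimnames = list(genes, colnames(vals)))
  expression_matrix(num, unit)
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples matrix
#' @param path output path
#' @param id_column header of the gene-ID column
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path, id_column = "gene") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal annotated VCF into a variant table
#'
#' Parses a VCF v4.2 file whose INFO field carries `GENE=`, `CHASM=` and
#' `VEST=` keys (driver and pathogenicity scores precomputed upstream).
#' Positions stay 1-based. The patient ID is taken from the single genotype
#' sample column when present, otherwise from `patient`. Records missing
#' any of the three INFO keys are an error in strict mode and skipped with
#' a warning otherwise. A FILTER of "." is preserved as-is and therefore
#' counts as non-PASS downstream.
#'
#' @param path VCF path
#' @param strict error (TRUE) or skip-with-warning (FALSE) on records
#'   lacking GENE/CHASM/VEST
#' @param patient fallback patient ID when the VCF has no sample column
#' @return data.frame with patient, gene, chrom, pos, ref, alt, filter,
#'   chasm, vest
#' @export
read_vcf_minimal <- function(path, strict = TRUE, patient = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  gene <- vcfR::extract.info(vcf, element = "GENE")
  chasm <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "CHASM")))
  vest <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "VEST")))
  incomplete <- is.na(gene) | is.na(chasm) | is.na(vest)
  if (any(incomplete)) {
    if (strict)
      stop(sum(incomplete), " record(s) missing GENE/CHASM/VEST in ", path)
    warning(sum(incomplete), " record(s) missing GENE/CHASM/VEST skipped")
  }
  samp <- colnames(vcf@gt)
  pid <- if (!is.null(samp) && length(samp) >= 2) samp[2] else patient
  out <- data.frame(patient = pid, gene = gene,
                    chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
                    chasm = chasm, vest = vest, stringsAsFactors = FALSE)
  out <- out[!incomplete, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a single patient's variants as a minimal VCF v4.2
#'
#' @param variants variant data.frame for one patient
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf_minimal <- function(variants, path) {
  stopifnot(all(c("patient", "gene", "chrom", "pos", "ref", "alt", "filter",
                  "chasm", "vest") %in% names(variants)))
  pid <- unique(variants$patient)
  if (length(pid) != 1)
    stop("write one VCF per patient; got ", length(pid), " patients")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CHASM,Number=1,Type=Float,Description=\"Driver score\">",
    "##INFO=<ID=VEST,Number=1,Type=Float,Description=\"Pathogenicity score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pid), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tGENE=%s;CHASM=%g;VEST=%g\tGT\t0/1",
                  variants$chrom, as.integer(variants$pos), variants$ref,
                  variants$alt, variants$filter, variants$gene,
                  variants$chasm, variants$vest)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' @param path TSV with columns patient, time_months, event, subgroup
#' @return data.frame
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient", "time_months", "event", "subgroup")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("survival table missing column(s): ", paste(missing, collapse = ", "))
  stopifnot(all(is.finite(df$time_months)), all(df$time_months > 0),
            all(df$event %in% c(0, 1)))
  df
}

#' Write a survival table as TSV
#'
#' @param surv survival data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a marker panel as TSV
#'
#' @param panel a `marker_panel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_marker_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
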