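#' Clinical characteristics of the NSCLC discovery cohort
#'
#' Patient counts by clinical characteristic for the 31-patient NSCLC
#' discovery cohort treated with neoadjuvant anti-PD-1 plus chemotherapy:
#' gender, age band, smoking history, histology, stage and pathological
#' response status. Shipped so the cohort-composition percentages can be
#' recomputed as a worked example.
#'
#' @return data.frame with characteristic, category, count
#' @export
discovery_cohort_characteristics <- function() {
  path <- system.file("extdata", "cohort_characteristics.tsv",
                      package = "pdblood", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Cohort-composition percentages from a count table
#'
#' Computes 100 * count / N per category, where N is the cohort size
#' (the sum of counts within each characteristic).
#'
#' @param counts data.frame with characteristic, category, count (defaults
#'   to [discovery_cohort_characteristics()])
#' @param digits rounding for the reported percentage (1 decimal, the usual
#'   reporting convention)
#' @return input data.frame with added `percent` column
#' @export
cohort_percentages <- function(counts = discovery_cohort_characteristics(),
                               digits = 1) {
  stopifnot(all(c("characteristic", "category", "count") %in% names(counts)))
  totals <- tapply(counts$count, counts$characteristic, sum)
  counts$percent <- round(100 * counts$count /
                            as.vector(totals[counts$characteristic]), digits)
  counts
}
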