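#' Per-sample sequencing QC metrics
#'
#' Container for the library-level QC statistics the pipeline gates on:
#' duplicate rate and mapping rate for low-pass WGS libraries, duplicate
#' rate and pull-down enrichment fold for 5hmC libraries. The enrichment
#' fold is an externally supplied metric of the 5hmC capture efficiency.
#'
#' @param assay `"wgs"` or `"hmc"`.
#' @param duplicate_rate PCR duplicate rate in \[0, 1\].
#' @param mapping_rate mapping rate in \[0, 1\] (WGS libraries).
#' @param enrichment_fold capture enrichment fold, >= 0 (5hmC libraries).
#' @return an object of class `qc_metrics`.
#' @examples
#' qc_gate(qc_metrics("wgs", duplicate_rate = 0.10, mapping_rate = 0.97))
#' @export
qc_metrics <- function(assay = c("wgs", "hmc"), duplicate_rate = NA_real_,
                       mapping_rate = NA_real_, enrichment_fold = NA_real_) {
  assay <- match.arg(assay)
  chk01 <- function(v, nm) {
    if (!is.na(v) && (v < 0 || v > 1))
      stop("`", nm, "` must be in [0, 1]", call. = FALSE)
  }
  chk01(duplicate_rate, "duplicate_rate")
  chk01(mapping_rate, "mapping_rate")
  if (!is.na(enrichment_fold) && enrichment_fold < 0)
    stop("`enrichment_fold` must be >= 0", call. = FALSE)
  structure(list(assay = assay, duplicate_rate = duplicate_rate,
                 mapping_rate = mapping_rate,
                 enrichment_fold = enrichment_fold),
            class = "qc_metrics")
}

#' QC gates for WGS and 5hmC cfDNA libraries
#'
#' A WGS library passes iff duplicate rate < 0.15 and mapping rate > 0.95;
#' a 5hmC library passes iff duplicate rate < 0.65 and enrichment fold > 95.
#' All four inequalities are strict. A missing required metric fails with
#' reason `"missing <metric>"`. The gates are pure functions of the metrics.
#'
#' @param q a [qc_metrics()] record; its `assay` field selects the gate.
#' @param max_duplicate,min_mapping,min_enrichment gate thresholds; defaults
#'   are the standard cfDNA pipeline values quoted above.
#' @return list with logical `pass` and character `reason` (`"ok"` on pass).
#' @export
qc_gate <- function(q, max_duplicate = NULL, min_mapping = 0.95,
                    min_enrichment = 95) {
  stopifnot(inherits(q, "qc_metrics"))
  if (is.null(max_duplicate))
    max_duplicate <- if (q$assay == "wgs") 0.15 else 0.65
  fail <- function(reason) list(pass = FALSE, reason = reason)
  if (is.na(q$duplicate_rate)) return(fail("missing duplicate_rate"))
  if (q$assay == "wgs") {
    if (is.na(q$mapping_rate)) return(fail("missing mapping_rate"))
    if (!(q$duplicate_rate < max_duplicate))
      return(fail(sprintf("duplicate_rate %.3f not < %.3f",
                          q$duplicate_rate, max_duplicate)))
    if (!(q$mapping_rate > min_mapping))
      return(fail(sprintf("mapping_rate %.3f not > %.3f",
                          q$mapping_rate, min_mapping)))
  } else {
    if (is.na(q$enrichment_fold)) return(fail("missing enrichment_fold"))
    if (!(q$duplicate_rate < max_duplicate))
      return(fail(sprintf("duplicate_rate %.3f not < %.3f",
                          q$duplicate_rate, max_duplicate)))
    if (!(q$enrichment_fold > min_enrichment))
      return(fail(sprintf("enrichment_fold %.1f not > %.1f",
                          q$enrichment_fold, min_enrichment)))
  }
  list(pass = TRUE, reason = "ok")
}

#' Apply a QC gate to a list of samples
#'
#' @param qcs list of [qc_metrics()] records, named by sample.
#' @return data frame with columns `sample`, `pass`, `reason`; one row per
#'   input sample (pass + fail counts always sum to the input count).
#' @export
qc_gate_batch <- function(qcs) {
  res <- lapply(qcs, qc_gate)
  data.frame(sample = if (is.null(names(qcs)))
    as.character(seq_along(qcs)) else names(qcs),
    pass = vapply(res, `[[`, logical(1), "pass"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE, row.names = NULL)
}
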