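# Plain-text I/O for the pipeline's file formats.

#' Read a progress-curve CSV
#'
#' Expects a header `time_s,product_nM`; lines starting with `#` are
#' ignored.
#'
#' @param path CSV file.
#' @param conditions an [assay_conditions()] attached to the curve.
#' @param label curve label (defaults to the file name).
#' @return A [progress_curve()].
#' @export
read_progress_csv <- function(path, conditions, label = basename(path)) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "product_nM") %in% names(d)))
    stop("expected columns time_s,product_nM in ", path, call. = FALSE)
  progress_curve(d$time_s, d$product_nM, conditions, label)
}

#' Write a progress curve as CSV
#' @param curve a [progress_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_progress_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$times,
                              product_nM = curve$product),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a steady-state rate CSV
#'
#' Columns `substrate_mM,inhibitor_uM,rate_uM_per_s`, or the absorbance
#' variant `substrate_mM,inhibitor_uM,a405` which is converted with
#' [absorbance_to_rate()].
#'
#' @param path CSV file.
#' @param enzyme_conc enzyme concentration, uM.
#' @param incubation_s reaction time for the absorbance variant, s.
#' @param ... further arguments to [absorbance_to_rate()].
#' @return A [rate_dataset()].
#' @export
read_rate_csv <- function(path, enzyme_conc, incubation_s = NULL, ...) {
  d <- utils::read.csv(path, comment.char = "#")
  if ("a405" %in% names(d)) {
    if (is.null(incubation_s))
      stop("absorbance input needs incubation_s", call. = FALSE)
    d$rate_uM_per_s <- absorbance_to_rate(d$a405,
                                          incubation_s = incubation_s, ...)
  }
  if (!all(c("substrate_mM", "inhibitor_uM", "rate_uM_per_s") %in% names(d)))
    stop("expected columns substrate_mM,inhibitor_uM,rate_uM_per_s in ",
         path, call. = FALSE)
  rate_dataset(d$substrate_mM, d$inhibitor_uM, d$rate_uM_per_s, enzyme_conc)
}

#' Serialize a processive fit as JSON
#' @param fit a `processive_fit`.
#' @param path output file; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to file.
#' @export
write_fit_json <- function(fit, path = NULL) {
  obj <- list(parameters = as.list(unlist(fit$params)),
              stderr = fit$stderr,
              correlation = as.numeric(t(fit$corr)),  # row-major
              ssr = fit$ssr, converged = fit$converged,
              n_starts = fit$n_starts)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write an alignment as FASTA
#' @param aln a [lineage_alignment()] or character matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  mat <- if (inherits(aln, "lineage_alignment")) aln$mat else as.matrix(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(mat)))
    writeLines(c(paste0(">", rownames(mat)[i]),
                 paste(mat[i, ], collapse = "")), con)
  invisible(path)
}

#' Write the per-column RCA table as TSV
#' @param rca an `rca_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rca_tsv <- function(rca, path) {
  utils::write.table(rca$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
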