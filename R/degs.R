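#' Call per-patient differentially expressed genes from paired expression
#'
#' For each patient *j* and gene *i* the log2 fold change is
#' \deqn{lfc_{ij} = \log_2\frac{tumor_{ij} + p}{normal_{ij} + p},}
#' with pseudocount *p* making zero-expression cells well defined.  Gene *i*
#' is a DEG of patient *j* iff \eqn{|lfc_{ij}|} strictly exceeds `threshold`
#' (a gene at exactly the threshold is not called).  The cohort DEG set is
#' the union of the per-patient sets.  This is a pure fold-change rule — no
#' variance model and no multiple-testing correction — matching how
#' matched-pair driver pipelines define per-patient dysregulation.
#'
#' @param e An `expression_pair` (see [read_expression_pair()]).
#' @param threshold Positive log2 fold-change cutoff; default 1 (two-fold).
#' @param pseudocount Nonnegative value added to numerator and denominator;
#'   default 1.  With `pseudocount = 0` any zero denominator is an error.
#' @return A `deg_set`: list with `cohort` (character vector, union),
#'   `per_patient` (named list of character vectors), `threshold`.
#' @export
call_degs <- function(e, threshold = 1, pseudocount = 1) {
  stopifnot(inherits(e, "expression_pair"))
  if (!(is.numeric(threshold) && length(threshold) == 1 && threshold > 0)) {
    stop("threshold must be a positive scalar")
  }
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (any(e$tumor < 0) || any(e$normal < 0)) stop("negative expression value")
  denom <- e$normal + pseudocount
  num <- e$tumor + pseudocount
  if (any(denom == 0) || any(num == 0)) {
    bad <- which(denom == 0 | num == 0, arr.ind = TRUE)[1, ]
    stop("zero expression with pseudocount 0 for gene ",
         rownames(e$normal)[bad[1]], ", patient ", colnames(e$normal)[bad[2]])
  }
  # log of the ratio, not a difference of logs: keeps exactly representable
  # fold changes (e.g. 2.0) exact at the threshold boundary
  lfc <- log2(num / denom)
  hit <- abs(lfc) > threshold
  per_patient <- lapply(seq_len(ncol(hit)), function(j) rownames(hit)[hit[, j]])
  names(per_patient) <- colnames(e$tumor)
  structure(
    list(cohort = unique(unlist(per_patient, use.names = FALSE)),
         per_patient = per_patient,
         threshold = threshold),
    class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat("<deg_set> ", length(x$cohort), " cohort DEGs across ",
      length(x$per_patient), " patients (|log2FC| > ", x$threshold, ")\n",
      sep = "")
  invisible(x)
}

#' Export a DEG set as a long TSV (patient, gene)
#'
#' @param degs A `deg_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degs <- function(degs, path) {
  tab <- tibble::tibble(
    patient = rep(names(degs$per_patient), lengths(degs$per_patient)),
    gene = unlist(degs$per_patient, use.names = FALSE))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
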