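#' Precision/recall/F1 curve of a ranking against a benchmark gene set
#'
#' For each cutoff \eqn{k \le} `max_k`:
#' \deqn{precision(k) = |top_k \cap B| / k, \quad
#'       recall(k) = |top_k \cap B| / D, \quad
#'       F1(k) = 2\,P\,R/(P+R)}
#' where *B* is the benchmark set and the recall denominator *D* is either
#' the benchmark genes mutated in the cohort (`"in_dataset"`, default — a
#' cohort-restricted ranker cannot recover drivers never mutated in it) or
#' the full benchmark (`"full_set"`).  F1 is 0 when both precision and
#' recall are 0.
#'
#' @param r A `driver_ranking` from [rank_drivers()], or any data frame with
#'   a `gene` column ordered best-first.
#' @param benchmark `gene_set` / character vector of known drivers (e.g. a
#'   Cancer Gene Census list).
#' @param mutated `gene_set` / character vector of genes mutated in the
#'   cohort (used for the `"in_dataset"` denominator).
#' @param max_k Largest cutoff; defaults to the full ranking length.
#' @param recall_denominator `"in_dataset"` or `"full_set"`.
#' @return A tibble of class `driver_evaluation` with columns `k`,
#'   `precision`, `recall`, `f1`; attribute `benchmark_size` holds *D*.
#' @export
evaluate_ranking <- function(r, benchmark, mutated = NULL, max_k = nrow(r),
                             recall_denominator = c("in_dataset", "full_set")) {
  recall_denominator <- match.arg(recall_denominator)
  benchmark <- as.character(benchmark)
  if (max_k > nrow(r)) stop("max_k exceeds ranking length")
  d <- if (recall_denominator == "in_dataset") {
    if (is.null(mutated)) stop("'mutated' is required for in_dataset recall")
    length(intersect(benchmark, as.character(mutated)))
  } else {
    length(unique(benchmark))
  }
  if (d == 0) stop("recall denominator is zero: benchmark does not overlap the cohort")
  genes <- r$gene[seq_len(max_k)]
  hits <- cumsum(genes %in% benchmark)
  k <- seq_len(max_k)
  precision <- hits / k
  recall <- hits / d
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  out <- tibble::tibble(k = k, precision = precision, recall = recall, f1 = f1)
  class(out) <- c("driver_evaluation", class(out))
  attr(out, "benchmark_size") <- d
  out
}

#' Mutation count and frequency of a gene in the cohort
#'
#' @param m A `mutation_matrix`.
#' @param gene A gene symbol present in `m`.
#' @return A list with `count` (row sum) and `pct` (percent of patients,
#'   `100 * count / n_patients`).
#' @examples
#' # a gene mutated in 5 of 316 patients has frequency 1.582278 percent
#' @export
mutation_frequency <- function(m, gene) {
  if (!(gene %in% rownames(m))) stop("unknown gene: ", gene)
  count <- sum(m[gene, ])
  list(count = as.integer(count), pct = 100 * count / ncol(m))
}

#' Flag rare drivers among the top-ranked genes
#'
#' A top-ranked gene is flagged rare when its mutation frequency is strictly
#' below `threshold_pct` percent of the patient population (default 2%) —
#' these are the candidates a frequency-based ranker would miss.  Membership
#' in the benchmark catalog is reported as an annotation (`in_benchmark`),
#' not used as a filter: curated catalogs also contain low-frequency
#' drivers, and flagging them alongside novel genes is informative.
#'
#' @param r A `driver_ranking`.
#' @param m The cohort's `mutation_matrix`.
#' @param benchmark `gene_set` / character vector of known drivers.
#' @param top_n How many top-ranked genes to scan.
#' @param threshold_pct Rarity cutoff in percent (strict `<`).
#' @return A tibble of class `rare_driver_table` with columns `rank`, `gene`,
#'   `mut_count`, `frequency_pct`, `in_benchmark`, ordered by rank.
#' @export
flag_rare_drivers <- function(r, m, benchmark, top_n = 20, threshold_pct = 2) {
  if (top_n > nrow(r)) stop("top_n exceeds ranking length")
  benchmark <- as.character(benchmark)
  top <- dplyr::slice_head(tibble::as_tibble(r), n = top_n)
  freq <- purrr::map(top$gene, function(g) {
    if (g %in% rownames(m)) mutation_frequency(m, g) else list(count = 0L, pct = 0)
  })
  out <- tibble::tibble(
    rank = top$rank,
    gene = top$gene,
    mut_count = purrr::map_int(freq, "count"),
    frequency_pct = purrr::map_dbl(freq, "pct"),
    in_benchmark = top$gene %in% benchmark)
  out <- dplyr::filter(out, .data$frequency_pct < threshold_pct)
  class(out) <- c("rare_driver_table", class(out))
  out
}

#' Export an evaluation curve as TSV (k, precision, recall, f1)
#'
#' @param ev A `driver_evaluation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(ev, path) {
  readr::write_tsv(ev, path, progress = FALSE)
  invisible(path)
}

#' Export a rare-driver table as TSV
#'
#' Frequencies are written with six decimal places.
#'
#' @param rare A `rare_driver_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rare_drivers <- function(rare, path) {
  out <- dplyr::mutate(tibble::as_tibble(rare),
                       frequency_pct = sprintf("%.6f", .data$frequency_pct))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
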