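#' Per-gene mutation scores with a background score
#'
#' For each gene *i* the mutation score is
#' \deqn{M(i) = \sum_{k \in K_i} 1/N_k,}
#' where \eqn{K_i} is the set of patients carrying a mutation in gene *i* and
#' \eqn{N_k} is the number of mutated genes in patient *k*.  A mutation in a
#' quiet genome is strong evidence; one among hundreds of co-mutations is
#' weak.  Genes never mutated in the cohort receive the background mutation
#' score \eqn{BMS = 1/N_{max}} (with \eqn{N_{max}} the largest per-patient
#' mutation count), which by construction is no greater than the score of any
#' mutated gene.
#'
#' @param m A `mutation_matrix` (see [read_mutation_matrix()]) with at least
#'   one nonzero entry.
#' @return A tibble of class `mutation_score_table` with columns `gene`,
#'   `score`, `is_bms`, and attribute `bms` (the background score).
#' @examples
#' m <- new_mutation_matrix(matrix(c(1L, 1L, 0L, 0L, 1L, 0L), nrow = 3,
#'   byrow = TRUE, dimnames = list(c("A", "B", "C"), c("p1", "p2"))))
#' mutation_scores(m)
#' @export
mutation_scores <- function(m) {
  n_k <- colSums(m)
  n_max <- max(n_k)
  if (n_max == 0) stop("all-zero mutation matrix: background score undefined")
  bms <- 1 / n_max
  # each mutated patient k contributes 1/N_k to every gene mutated in k
  w <- ifelse(n_k > 0, 1 / n_k, 0)
  score <- as.numeric(unclass(m) %*% w)
  mutated <- rowSums(m) > 0
  score[!mutated] <- bms
  out <- tibble::tibble(gene = rownames(m), score = score, is_bms = !mutated)
  class(out) <- c("mutation_score_table", class(out))
  attr(out, "bms") <- bms
  out
}

#' Euclidean distance between two mutation profiles
#'
#' For binary rows this equals the square root of the Hamming distance, so it
#' measures how dissimilar the patient sets of two genes are.
#'
#' @param row_i,row_j Equal-length numeric/integer vectors (typically rows of
#'   a mutation matrix).
#' @return Nonnegative scalar distance.
#' @export
gene_distance <- function(row_i, row_j) {
  if (length(row_i) != length(row_j)) {
    stop("gene_distance: vectors differ in length (",
         length(row_i), " vs ", length(row_j), ")")
  }
  sqrt(sum((as.numeric(row_i) - as.numeric(row_j))^2))
}

#' Mutation impact function between two genes
#'
#' A gravity-style pairwise interaction score: two genes with high mutation
#' scores whose mutations hit similar patient sets exert a high mutual
#' impact.  In the default `"gravity"` mode
#' \deqn{MIF(i,j) = M(i)\,M(j)/d_{ij}^2,}
#' with \eqn{d_{ij}} the Euclidean distance between the genes' rows of the
#' mutation matrix; identical rows (\eqn{d = 0}) are floored at \eqn{d = 1},
#' the smallest achievable nonzero distance between distinct binary rows, so
#' the impact stays finite and maximal.  The `"literal"` mode instead takes
#' the distance's reciprocal as the separation, giving
#' \eqn{MIF = M(i)\,M(j)\,d^2} (and \eqn{M(i)M(j)} for identical rows); it
#' inverts the similarity relationship and is kept for auditability only.
#'
#' @param scores A `mutation_score_table` from [mutation_scores()].
#' @param m The `mutation_matrix` the scores came from.
#' @param i,j Distinct gene symbols present in `m`.
#' @param mif_mode `"gravity"` (default) or `"literal"`.
#' @return A positive scalar; symmetric in `i` and `j`.
#' @export
compute_mif <- function(scores, m, i, j, mif_mode = c("gravity", "literal")) {
  mif_mode <- match.arg(mif_mode)
  if (identical(i, j)) stop("compute_mif: i and j must be distinct genes")
  if (!(i %in% rownames(m)) || !(j %in% rownames(m))) {
    stop("compute_mif: gene not present in mutation matrix")
  }
  sc <- stats::setNames(scores$score, scores$gene)
  d <- gene_distance(m[i, ], m[j, ])
  if (d == 0) d <- 1
  if (mif_mode == "gravity") sc[[i]] * sc[[j]] / d^2 else sc[[i]] * sc[[j]] * d^2
}

#' Export a mutation score table as TSV
#'
#' Columns: gene, score, is_bms.
#'
#' @param scores A `mutation_score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}
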