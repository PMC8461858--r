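#' Read a binary gene-by-patient mutation matrix
#'
#' Reads somatic mutation data into a binary gene \eqn{\times} patient
#' incidence matrix: entry `[i, j]` is 1 when gene *i* carries a somatic
#' alteration (SNV or CNV, already collapsed to gene level) in patient *j*.
#' Two input layouts are supported:
#'
#' * `format = "matrix"`: TSV with a header row of patient IDs, a first
#'   column of gene symbols, and 0/1 cells.
#' * `format = "maf"`: a minimal MAF-like table with at least the columns
#'   `Hugo_Symbol` and `Tumor_Sample_Barcode`; any number of records
#'   (\eqn{\ge 1}) for a (gene, sample) pair collapses to a single 1 —
#'   mutation multiplicity is discarded because downstream scoring is
#'   defined on a binary matrix.
#'
#' Genes whose row is all zero are retained: they receive the background
#' mutation score downstream rather than being dropped.
#'
#' @param path Path to a TSV file.
#' @param format `"matrix"` or `"maf"` (see above).
#' @param uppercase Logical; uppercase all gene symbols. The same flag should
#'   be applied to every input of an analysis at once, since mixed-case
#'   symbols across sources are the dominant matching failure.
#' @return An integer matrix of class `mutation_matrix` with gene rownames
#'   and patient colnames, entries in \{0, 1\}.
#' @seealso [write_mutation_matrix()], [mutation_scores()]
#' @export
read_mutation_matrix <- function(path, format = c("matrix", "maf"),
                                 uppercase = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (format == "matrix") {
    tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    if (ncol(tab) < 2) stop("matrix format needs a gene column plus >=1 patient column")
    genes <- norm_symbols(dplyr::pull(tab, 1), uppercase)
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!all(vals %in% c(0, 1))) {
      stop("non-binary cell in mutation matrix: values must be 0 or 1")
    }
    dup <- unique(genes[duplicated(genes)])
    if (length(dup) > 0) stop("duplicate gene row(s): ", paste(dup, collapse = ", "))
    m <- matrix(as.integer(vals), nrow = length(genes),
                dimnames = list(genes, colnames(vals)))
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
    miss <- setdiff(need, colnames(tab))
    if (length(miss) > 0) stop("MAF input missing required column(s): ",
                               paste(miss, collapse = ", "))
    genes <- norm_symbols(tab$Hugo_Symbol, uppercase)
    samples <- trimws(as.character(tab$Tumor_Sample_Barcode))
    gl <- unique(genes)
    sl <- unique(samples)
    m <- matrix(0L, nrow = length(gl), ncol = length(sl),
                dimnames = list(gl, sl))
    m[cbind(match(genes, gl), match(samples, sl))] <- 1L
  }
  new_mutation_matrix(m)
}

#' Construct a mutation matrix from a binary matrix
#'
#' @param m Integer/numeric matrix with 0/1 entries, gene rownames and
#'   patient colnames.
#' @return A `mutation_matrix`.
#' @export
new_mutation_matrix <- function(m) {
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)))
  if (ncol(m) < 1) stop("mutation matrix needs at least one patient")
  if (anyDuplicated(rownames(m))) stop("duplicate gene symbols")
  if (anyDuplicated(colnames(m))) stop("duplicate patient IDs")
  storage.mode(m) <- "integer"
  class(m) <- c("mutation_matrix", class(m))
  m
}

#' Write a mutation matrix as TSV
#'
#' @param m A `mutation_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(m, path) {
  tab <- tibble::as_tibble(unclass(m), rownames = "gene")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read an undirected PPI network from a two-column edge list
#'
#' Reads an HPRD-style TSV edge list (columns: geneA, geneB, optional header).
#' Self-loops and duplicate edges (in either orientation) are dropped; a
#' message reports how many.
#'
#' @inheritParams read_mutation_matrix
#' @return An undirected, simple [igraph::igraph] graph whose vertex names are
#'   gene symbols.
#' @export
read_ppi <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("PPI edge list needs at least 2 tab-separated columns")
  a <- vapply(parts, `[[`, character(1), 1)
  b <- vapply(parts, `[[`, character(1), 2)
  # optional header: first row looks like column labels, not symbols
  if (grepl("^(gene|node|protein|interactor|symbol)", a[1], ignore.case = TRUE) &&
      grepl("^(gene|node|protein|interactor|symbol)", b[1], ignore.case = TRUE)) {
    a <- a[-1]; b <- b[-1]
  }
  a <- norm_symbols(a, uppercase)
  b <- norm_symbols(b, uppercase)
  self <- a == b
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key) & !self
  keep <- !self & !dup
  if (any(self) || any(dup)) {
    message("read_ppi: dropped ", sum(self), " self-loop(s) and ",
            sum(dup), " duplicate edge(s)")
  }
  nodes <- unique(c(a, b))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep]),
    directed = FALSE, vertices = nodes)
  g
}

#' Write a PPI graph as a two-column TSV edge list
#'
#' Isolated vertices are not representable in an edge list and are omitted.
#'
#' @param g An undirected igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(g, path) {
  el <- igraph::as_edgelist(g)
  tab <- tibble::tibble(geneA = el[, 1], geneB = el[, 2])
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a gene set (one symbol per line)
#'
#' Blank lines are ignored and duplicate symbols deduplicated. Used for
#' benchmark driver catalogs such as the Cancer Gene Census.
#'
#' @inheritParams read_mutation_matrix
#' @param name Label for the set.
#' @return A `gene_set`: a character vector of unique members with a `name`
#'   attribute.
#' @export
read_gene_set <- function(path, name = basename(path), uppercase = FALSE) {
  lines <- readr::read_lines(path, progress = FALSE)
  members <- norm_symbols(lines[nzchar(trimws(lines))], uppercase)
  members <- unique(members)
  if (length(members) == 0) warning("gene set '", name, "' is empty")
  gene_set(members, name = name)
}

#' Construct a gene set
#'
#' @param members Character vector of gene symbols (deduplicated).
#' @param name Label.
#' @return A `gene_set` object.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- unique(as.character(members))
  structure(members, name = name, class = c("gene_set", "character"))
}

#' Write a gene set, one symbol per line
#'
#' @param gs A `gene_set` or character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  readr::write_lines(as.character(gs), path)
  invisible(path)
}

#' Read paired tumor/normal expression matrices
#'
#' Each file is a TSV with genes as rows (first column = symbol) and samples
#' as columns, values on a linear nonnegative scale. The two matrices must
#' share gene and sample axes; columns are paired by sample ID (tumor and
#' normal profile of the same patient).
#'
#' @param tumor_path,normal_path Paths to the tumor and normal TSVs.
#' @inheritParams read_mutation_matrix
#' @return An `expression_pair`: list with numeric matrices `tumor` and
#'   `normal` on identical axes.
#' @export
read_expression_pair <- function(tumor_path, normal_path, uppercase = FALSE) {
  tumor <- read_expr_matrix(tumor_path, uppercase)
  normal <- read_expr_matrix(normal_path, uppercase)
  expression_pair(tumor, normal)
}

read_expr_matrix <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  genes <- norm_symbols(dplyr::pull(tab, 1), uppercase)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Construct an expression pair
#'
#' @param tumor,normal Nonnegative numeric matrices, genes x samples, with
#'   identical dimnames (columns paired by patient).
#' @return An `expression_pair` object.
#' @export
expression_pair <- function(tumor, normal) {
  if (!identical(dimnames(tumor), dimnames(normal))) {
    stop("tumor and normal matrices must share identical gene and sample axes")
  }
  if (anyNA(tumor) || anyNA(normal) ||
      any(!is.finite(tumor)) || any(!is.finite(normal))) {
    stop("expression values must be finite")
  }
  if (any(tumor < 0) || any(normal < 0)) stop("negative expression value")
  structure(list(tumor = tumor, normal = normal), class = "expression_pair")
}

#' Write an expression pair as two TSV files
#'
#' @param e An `expression_pair`.
#' @param tumor_path,normal_path Output paths.
#' @return Invisibly, `c(tumor_path, normal_path)`.
#' @export
write_expression_pair <- function(e, tumor_path, normal_path) {
  for (nm in c("tumor", "normal")) {
    p <- if (nm == "tumor") tumor_path else normal_path
    tab <- tibble::as_tibble(e[[nm]], rownames = "gene")
    readr::write_tsv(tab, p, progress = FALSE)
  }
  invisible(c(tumor_path, normal_path))
}

# trim + optional case fold; exact string matching everywhere downstream
norm_symbols <- function(x, uppercase = FALSE) {
  x <- trimws(as.character(x))
  if (uppercase) x <- toupper(x)
  x
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("<mutation_matrix> ", nrow(x), " genes x ", ncol(x), " patients; ",
      sum(x), " mutation calls\n", sep = "")
  invisible(x)
}

#' @export
print.expression_pair <- function(x, ...) {
  cat("<expression_pair> ", nrow(x$tumor), " genes x ", ncol(x$tumor),
      " paired samples\n", sep = "")
  invisible(x)
}
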