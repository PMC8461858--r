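#' Merge mutated genes and DEGs onto the PPI network
#'
#' Restricts the PPI graph to the union of cohort-mutated genes and cohort
#' DEGs: the node set is that union intersected with the PPI vertices, and
#' the edge set is the PPI edges with both endpoints kept (induced subgraph).
#' Every node is assigned a role: `MUTATED`, `DEG`, or `BOTH` when the gene
#' is in both input sets.  Genes absent from the PPI are dropped with a
#' message reporting how many of each kind.
#'
#' @param ppi An undirected igraph PPI graph (see [read_ppi()]).
#' @param mutated Character vector / `gene_set` of genes mutated in the
#'   cohort.
#' @param degs A `deg_set` from [call_degs()], or a character vector of DEG
#'   symbols.
#' @return The induced igraph subgraph with a vertex attribute `role`.
#' @export
build_merged_graph <- function(ppi, mutated, degs) {
  mutated <- as.character(mutated)
  deg_genes <- if (inherits(degs, "deg_set")) degs$cohort else as.character(degs)
  wanted <- union(mutated, deg_genes)
  present <- intersect(wanted, igraph::V(ppi)$name)
  n_drop_mut <- length(setdiff(mutated, present))
  n_drop_deg <- length(setdiff(deg_genes, present))
  if (n_drop_mut > 0 || n_drop_deg > 0) {
    message("build_merged_graph: dropped ", n_drop_mut, " mutated gene(s) and ",
            n_drop_deg, " DEG(s) absent from the PPI")
  }
  if (length(present) == 0) stop("no mutated gene or DEG maps onto the PPI network")
  g <- igraph::induced_subgraph(ppi, present)
  nm <- igraph::V(g)$name
  role <- ifelse(nm %in% mutated & nm %in% deg_genes, "BOTH",
                 ifelse(nm %in% mutated, "MUTATED", "DEG"))
  igraph::V(g)$role <- role
  g
}

#' Extract the two-hop semi-local network around a mutated source gene
#'
#' The semi-local network of source *v* contains *v*, its neighbors, and its
#' neighbors' neighbors in the merged graph, with the edges induced among
#' them.  Restricting centrality to two hops keeps the computation local and
#' cheap while still seeing beyond direct interactors.
#'
#' @param g A merged graph from [build_merged_graph()].
#' @param v A gene symbol with role `MUTATED` or `BOTH` (mutated genes are
#'   the source nodes).
#' @return An igraph subgraph with graph attribute `source = v`; vertex
#'   roles are inherited.
#' @export
extract_semilocal <- function(g, v) {
  if (!(v %in% igraph::V(g)$name)) stop("gene ", v, " not in merged graph")
  role_v <- igraph::V(g)$role[igraph::V(g)$name == v]
  if (!(role_v %in% c("MUTATED", "BOTH"))) {
    stop("gene ", v, " is not mutated: only mutated genes are source nodes")
  }
  nodes <- igraph::ego(g, order = 2, nodes = v)[[1]]
  net <- igraph::induced_subgraph(g, nodes)
  net <- igraph::set_graph_attr(net, "source", v)
  net
}

# MIF evaluator with per-matrix memoisation: distances and scores depend only
# on the mutation matrix, so values are shared across semi-local networks.
make_mif <- function(scores, m, mif_mode = c("gravity", "literal")) {
  mif_mode <- match.arg(mif_mode)
  sc <- stats::setNames(scores$score, scores$gene)
  mm <- unclass(m)
  memo <- new.env(parent = emptyenv())
  function(i, j) {
    if (identical(i, j)) stop("MIF undefined for a gene with itself")
    key <- if (i < j) paste0(i, "\r", j) else paste0(j, "\r", i)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (!(i %in% rownames(mm)) || !(j %in% rownames(mm))) {
      stop("MIF requested for gene absent from the mutation matrix: ",
           if (i %in% rownames(mm)) j else i)
    }
    d <- gene_distance(mm[i, ], mm[j, ])
    if (d == 0) d <- 1
    val <- if (mif_mode == "gravity") sc[[i]] * sc[[j]] / d^2 else sc[[i]] * sc[[j]] * d^2
    memo[[key]] <- val
    val
  }
}

#' Semi-local centrality score of a mutated source gene
#'
#' The driver score of source *v* inside its semi-local network is
#' \deqn{score(v) = N(v) + \sum_{u \in \Gamma(v),\, u\ mutated} c(u)\,MIF(v,u)
#'   + \sum_{u \in \Gamma(v),\, u\ DEG} b(u)}
#' with the auxiliary per-neighbor quantities
#' \deqn{c(u) = \sum_{w \in \Gamma(u),\, w\ mutated} N(u)\,MIF(u,w)
#'   + \sum_{w \in \Gamma(u),\, w\ DEG} N(w)}
#' \deqn{b(u) = \sum_{w \in \Gamma(u),\, w\ mutated} c(w)
#'   + \sum_{w \in \Gamma(u),\, w\ DEG} N(w).}
#' Here \eqn{\Gamma(x)} is the neighbor set of *x* and the scalar
#' \eqn{N(x)} is its size (degree), both evaluated inside the semi-local
#' network.  Mutated neighbors contribute weighted by the mutation impact
#' function; DEG neighbors contribute pure centrality.  A gene that is both
#' mutated and differentially expressed (`BOTH`) contributes to both
#' branches of every sum, so its influence is counted twice by design.
#' Neighbor walks may revisit the source; no back-edge exclusion is applied.
#'
#' @param net A semi-local network from [extract_semilocal()].
#' @param scores A `mutation_score_table` from [mutation_scores()].
#' @param m The `mutation_matrix` (distances for MIF are computed from it).
#' @param mif_mode `"gravity"` (default) or `"literal"`; see [compute_mif()].
#' @param c_variant `"literal"` uses \eqn{N(u)} in the mutated branch of
#'   `c(u)` as printed above; `"nw"` uses \eqn{N(w)} for symmetry with the
#'   DEG branch.
#' @param neighbor_count Scalarization of \eqn{N(x)}: `"degree"` (default)
#'   or `"two_hop"` (number of nodes within two hops of *x*, excluding *x*).
#' @return A finite nonnegative scalar; 0 for an isolated source.
#' @export
score_gene <- function(net, scores, m,
                       mif_mode = c("gravity", "literal"),
                       c_variant = c("literal", "nw"),
                       neighbor_count = c("degree", "two_hop")) {
  mif_mode <- match.arg(mif_mode)
  c_variant <- match.arg(c_variant)
  neighbor_count <- match.arg(neighbor_count)
  mif <- make_mif(scores, m, mif_mode)
  score_gene_impl(net, igraph::graph_attr(net, "source"), mif,
                  c_variant, neighbor_count)
}

score_gene_impl <- function(net, v, mif, c_variant, neighbor_count) {
  nm <- igraph::V(net)$name
  role <- stats::setNames(igraph::V(net)$role, nm)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  nbr <- stats::setNames(lapply(adj, function(x) nm[as.integer(x)]), nm)
  nsize <- if (neighbor_count == "degree") {
    lengths(nbr)
  } else {
    stats::setNames(
      vapply(igraph::ego(net, order = 2, nodes = igraph::V(net)),
             function(x) length(x) - 1L, integer(1)), nm)
  }
  is_mut <- role %in% c("MUTATED", "BOTH"); names(is_mut) <- nm
  is_deg <- role %in% c("DEG", "BOTH"); names(is_deg) <- nm

  c_memo <- new.env(parent = emptyenv())
  c_of <- function(u) {
    hit <- c_memo[[u]]
    if (!is.null(hit)) return(hit)
    val <- 0
    for (w in nbr[[u]]) {
      if (is_mut[[w]]) {
        n_scal <- if (c_variant == "literal") nsize[[u]] else nsize[[w]]
        val <- val + n_scal * mif(u, w)
      }
      if (is_deg[[w]]) val <- val + nsize[[w]]
    }
    c_memo[[u]] <- val
    val
  }
  b_of <- function(u) {
    val <- 0
    for (w in nbr[[u]]) {
      if (is_mut[[w]]) val <- val + c_of(w)
      if (is_deg[[w]]) val <- val + nsize[[w]]
    }
    val
  }

  s <- nsize[[v]]
  for (u in nbr[[v]]) {
    if (is_mut[[u]]) s <- s + c_of(u) * mif(v, u)
    if (is_deg[[u]]) s <- s + b_of(u)
  }
  as.numeric(s)
}

#' Rank mutated genes by semi-local driver score
#'
#' Applies [score_gene()] to every mutated (or `BOTH`) node of the merged
#' graph, each inside its own two-hop semi-local network, and returns the
#' genes sorted by descending score.  Ties are broken by higher mutation
#' score, then alphabetically, so rankings are deterministic.
#'
#' @inheritParams score_gene
#' @param g A merged graph from [build_merged_graph()].
#' @return A tibble of class `driver_ranking` with columns `rank`, `gene`,
#'   `score`, `mutation_score`, `degree` (in the merged graph), `role`.
#' @export
rank_drivers <- function(g, scores, m,
                         mif_mode = c("gravity", "literal"),
                         c_variant = c("literal", "nw"),
                         neighbor_count = c("degree", "two_hop")) {
  mif_mode <- match.arg(mif_mode)
  c_variant <- match.arg(c_variant)
  neighbor_count <- match.arg(neighbor_count)
  nm <- igraph::V(g)$name
  role <- stats::setNames(igraph::V(g)$role, nm)
  sources <- nm[role %in% c("MUTATED", "BOTH")]
  if (length(sources) == 0) stop("merged graph contains no mutated gene")
  mif <- make_mif(scores, m, mif_mode)
  deg_g <- igraph::degree(g)
  sc_map <- stats::setNames(scores$score, scores$gene)
  vals <- vapply(sources, function(v) {
    net <- extract_semilocal(g, v)
    score_gene_impl(net, v, mif, c_variant, neighbor_count)
  }, numeric(1))
  out <- tibble::tibble(
    gene = sources,
    score = as.numeric(vals),
    mutation_score = as.numeric(sc_map[sources]),
    degree = as.integer(deg_g[sources]),
    role = unname(role[sources]))
  out <- dplyr::arrange(out, dplyr::desc(.data$score),
                        dplyr::desc(.data$mutation_score), .data$gene)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  class(out) <- c("driver_ranking", class(out))
  out
}

#' Export a driver ranking as TSV
#'
#' Columns: rank, gene, score, mutation_score, degree, role.
#'
#' @param r A `driver_ranking`.
#' @param path Output path.
#' @param top Optional integer: keep only the top `top` rows.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(r, path, top = NULL) {
  if (!is.null(top)) r <- dplyr::slice_head(r, n = top)
  readr::write_tsv(r, path, progress = FALSE)
  invisible(path)
}
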