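# Independent brute-force oracles, written directly from the formulas with
# plain loops over an adjacency matrix.  They share no code with the package
# internals they check.

naive_mif <- function(scores, m, i, j, mif_mode) {
  sc <- stats::setNames(scores$score, scores$gene)
  d <- sqrt(sum((m[i, ] - m[j, ])^2))
  if (d == 0) d <- 1
  if (mif_mode == "gravity") sc[[i]] * sc[[j]] / d^2 else sc[[i]] * sc[[j]] * d^2
}

# A: symmetric 0/1 adjacency matrix with gene dimnames; roles: named vector
naive_score_gene <- function(A, roles, v, scores, m,
                             mif_mode = "gravity", c_variant = "literal",
                             neighbor_count = "degree") {
  nodes <- rownames(A)
  nbrs <- function(x) nodes[A[x, ] == 1]
  nsize <- function(x) {
    if (neighbor_count == "degree") {
      sum(A[x, ])
    } else {
      reach <- unique(unlist(lapply(nbrs(x), nbrs)))
      length(setdiff(union(nbrs(x), reach), x))
    }
  }
  is_mut <- function(x) roles[[x]] %in% c("MUTATED", "BOTH")
  is_deg <- function(x) roles[[x]] %in% c("DEG", "BOTH")
  c_fun <- function(u) {
    val <- 0
    for (w in nbrs(u)) {
      if (is_mut(w)) {
        n_scal <- if (c_variant == "literal") nsize(u) else nsize(w)
        val <- val + n_scal * naive_mif(scores, m, u, w, mif_mode)
      }
      if (is_deg(w)) val <- val + nsize(w)
    }
    val
  }
  b_fun <- function(u) {
    val <- 0
    for (w in nbrs(u)) {
      if (is_mut(w)) val <- val + c_fun(w)
      if (is_deg(w)) val <- val + nsize(w)
    }
    val
  }
  s <- nsize(v)
  for (u in nbrs(v)) {
    if (is_mut(u)) s <- s + c_fun(u) * naive_mif(scores, m, v, u, mif_mode)
    if (is_deg(u)) s <- s + b_fun(u)
  }
  s
}

# random binary mutation matrix with at least one nonzero entry
random_mutation_matrix <- function(n_genes, n_patients, p = 0.3,
                                   genes = sprintf("g%02d", seq_len(n_genes))) {
  repeat {
    m <- matrix(rbinom(n_genes * n_patients, 1, p), n_genes, n_patients,
                dimnames = list(genes, sprintf("p%02d", seq_len(n_patients))))
    if (sum(m) > 0) break
  }
  new_mutation_matrix(m)
}

# random attributed graph: Erdos-Renyi edges, random roles, with at least one
# mutated node; returns the graph plus a matching mutation matrix and scores
random_attributed_graph <- function(n_nodes, n_patients = 6, p_edge = 0.35) {
  genes <- sprintf("g%02d", seq_len(n_nodes))
  A <- matrix(0L, n_nodes, n_nodes, dimnames = list(genes, genes))
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq((i + 1), n_nodes)) {
      if (runif(1) < p_edge) A[i, j] <- A[j, i] <- 1L
    }
  }
  roles <- sample(c("MUTATED", "DEG", "BOTH"), n_nodes, replace = TRUE)
  names(roles) <- genes
  if (!any(roles != "DEG")) roles[[sample(genes, 1)]] <- "MUTATED"
  m <- random_mutation_matrix(n_nodes, n_patients, genes = genes)
  # genes with a mutated role must be mutated in the matrix so MIF is defined
  for (g in genes[roles != "DEG"]) {
    if (sum(m[g, ]) == 0) m[g, sample.int(n_patients, 1)] <- 1L
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$role <- unname(roles[igraph::V(g)$name])
  list(graph = g, A = A, roles = roles, m = new_mutation_matrix(unclass(m)),
       scores = mutation_scores(new_mutation_matrix(unclass(m))))
}

# tiny builder used across IO and scoring tests
tiny_mutation_matrix <- function() {
  new_mutation_matrix(matrix(
    c(1L, 1L, 0L,
      0L, 1L, 0L,
      1L, 0L, 0L), nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"), c("p1", "p2", "p3"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
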