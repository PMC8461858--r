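# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a scale-free PPI-like network
#'
#' Grows a connected undirected graph by preferential attachment
#' (Barabasi-Albert), so the degree distribution is heavy-tailed like real
#' protein-interaction networks: a few hubs, many low-degree genes.
#' Deterministic given `seed`.
#'
#' @param n_genes Number of nodes (> `attach_m`).
#' @param attach_m Edges added per incoming node (>= 1); `attach_m = 1`
#'   yields a tree.
#' @param seed Integer seed.
#' @return An undirected simple igraph graph with gene names `G0001`, ...
#' @export
generate_ppi <- function(n_genes, attach_m = 2, seed = 1) {
  if (!(n_genes > attach_m && attach_m >= 1)) {
    stop("need n_genes > attach_m >= 1")
  }
  g <- with_seed(seed, igraph::sample_pa(n_genes, m = attach_m, directed = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_genes))
  g
}

#' Generate a full synthetic cohort (mutations, expression, PPI, drivers)
#'
#' Emulates the statistical structure the driver-prioritization pipeline
#' assumes, so every stage can be exercised without external downloads:
#'
#' * a scale-free PPI via [generate_ppi()];
#' * `n_drivers` planted driver genes on the highest-degree nodes (the
#'   score is degree-anchored, so recovery tests must compare against
#'   degree-matched passenger controls, not arbitrary passengers);
#' * a binary mutation matrix: each driver is mutated per patient with its
#'   own frequency drawn uniformly from `driver_freq_range` percent (the
#'   lower end may sit below 2%, so rare drivers occur); every other gene
#'   is a passenger mutated at `passenger_freq` percent.  A driver that by
#'   chance hits no patient is assigned one carrier, since an unobserved
#'   driver cannot be ranked;
#' * paired expression: per-gene baselines are log-normal; in patients
#'   carrying a driver, that driver's PPI neighbors are shifted by
#'   `fc_effect` log2 units (sign random but fixed per gene) in the tumor
#'   profile — mutated drivers dysregulate their network neighborhood —
#'   plus Gaussian log-space noise of sd `noise_sd` in both profiles.
#'
#' @param n_genes,n_patients Cohort dimensions.
#' @param n_drivers Number of planted drivers (< `n_genes`).
#' @param driver_freq_range Length-2 numeric, percent; per-driver mutation
#'   frequency is uniform in this range.
#' @param passenger_freq Passenger mutation frequency, percent.
#' @param fc_effect Expression shift in log2 units applied to driver
#'   neighbors in carrier patients.
#' @param noise_sd Log2-space Gaussian noise sd for expression.
#' @param attach_m Preferential-attachment edges per node for the PPI.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `synthetic_cohort`: list with `mutation` (mutation_matrix),
#'   `expression` (expression_pair), `ppi` (igraph), `planted_drivers`
#'   (gene_set), `driver_targets` (named list: driver -> PPI neighbors),
#'   `seed`.
#' @export
generate_cohort <- function(n_genes = 300, n_patients = 60, n_drivers = 5,
                            driver_freq_range = c(1, 20), passenger_freq = 1,
                            fc_effect = 2.5, noise_sd = 0.3, attach_m = 2,
                            seed = 7) {
  if (n_drivers >= n_genes) stop("need n_drivers < n_genes")
  lo <- driver_freq_range[1]; hi <- driver_freq_range[2]
  if (!(lo > 0 && lo <= hi && hi <= 100)) {
    stop("driver_freq_range must satisfy 0 < lo <= hi <= 100")
  }
  if (passenger_freq < 0 || passenger_freq > 100) stop("passenger_freq out of range")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")

  ppi <- generate_ppi(n_genes, attach_m = attach_m, seed = seed)
  genes <- igraph::V(ppi)$name
  deg <- igraph::degree(ppi)
  ord <- order(-deg, genes)           # ties by name: deterministic
  drivers <- genes[ord[seq_len(n_drivers)]]
  targets <- lapply(drivers, function(d) {
    igraph::neighbors(ppi, d)$name
  })
  names(targets) <- drivers

  with_seed(seed + 1L, {
    patients <- sprintf("P%03d", seq_len(n_patients))
    mut <- matrix(0L, n_genes, n_patients, dimnames = list(genes, patients))
    freq <- stats::runif(n_drivers, lo, hi) / 100
    for (i in seq_len(n_drivers)) {
      carriers <- stats::rbinom(n_patients, 1, freq[i])
      if (sum(carriers) == 0) carriers[sample.int(n_patients, 1)] <- 1L
      mut[drivers[i], ] <- as.integer(carriers)
    }
    passengers <- setdiff(genes, drivers)
    mut[passengers, ] <- matrix(
      stats::rbinom(length(passengers) * n_patients, 1, passenger_freq / 100),
      nrow = length(passengers))

    base <- stats::runif(n_genes, 6, 10)  # log2 baseline per gene
    sign_g <- sample(c(-1, 1), n_genes, replace = TRUE)
    names(sign_g) <- genes
    shift <- matrix(0, n_genes, n_patients, dimnames = list(genes, patients))
    for (d in drivers) {
      carry <- which(mut[d, ] == 1L)
      tg <- targets[[d]]
      if (length(tg) > 0 && length(carry) > 0) {
        shift[tg, carry] <- 1      # affected flag; sign applied per gene below
      }
    }
    shift <- shift * sign_g * fc_effect
    noise_n <- matrix(stats::rnorm(n_genes * n_patients, 0, noise_sd),
                      n_genes, n_patients)
    noise_t <- matrix(stats::rnorm(n_genes * n_patients, 0, noise_sd),
                      n_genes, n_patients)
    normal <- 2^(base + noise_n)
    tumor <- 2^(base + shift + noise_t)
    dimnames(normal) <- dimnames(tumor) <- list(genes, patients)
  })

  structure(
    list(mutation = new_mutation_matrix(mut),
         expression = expression_pair(tumor, normal),
         ppi = ppi,
         planted_drivers = gene_set(drivers, name = "planted_drivers"),
         driver_targets = targets,
         seed = seed),
    class = "synthetic_cohort")
}

#' Write all four cohort inputs in the formats the readers accept
#'
#' Writes `mutation.tsv`, `expression_tumor.tsv`, `expression_normal.tsv`,
#' `ppi.tsv` and `drivers.txt` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mutation = file.path(dir, "mutation.tsv"),
    tumor = file.path(dir, "expression_tumor.tsv"),
    normal = file.path(dir, "expression_normal.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    drivers = file.path(dir, "drivers.txt"))
  write_mutation_matrix(cohort$mutation, paths[["mutation"]])
  write_expression_pair(cohort$expression, paths[["tumor"]], paths[["normal"]])
  write_ppi(cohort$ppi, paths[["ppi"]])
  write_gene_set(cohort$planted_drivers, paths[["drivers"]])
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$mutation), " genes x ", ncol(x$mutation),
      " patients; ", length(x$planted_drivers), " planted drivers; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
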