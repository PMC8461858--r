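#' Assemble a pipeline run configuration
#'
#' Bundles input paths and every tunable of the pipeline into one validated
#' list.  All tunables are echoed into `run.log` by [run_pipeline()] so a
#' run is auditable.
#'
#' @param mutation Path to the mutation input (matrix or MAF TSV).
#' @param expression_tumor,expression_normal Paths to the paired expression
#'   TSVs.
#' @param ppi Path to the PPI edge-list TSV.
#' @param benchmark Optional path to a known-driver gene list (one symbol
#'   per line); enables evaluation and rare-driver flagging.
#' @param out_dir Output directory.
#' @param mutation_format `"matrix"` or `"maf"`.
#' @param deg_threshold,pseudocount DEG-calling tunables, see [call_degs()].
#' @param mif_mode,c_variant,neighbor_count Scoring tunables, see
#'   [score_gene()].
#' @param recall_denominator See [evaluate_ranking()].
#' @param top_k Truncation for the written ranking and the evaluation curve.
#' @param rare_top_n,rare_threshold_pct Rare-driver tunables, see
#'   [flag_rare_drivers()].
#' @param uppercase Uppercase gene symbols in every input at once.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mutation, expression_tumor, expression_normal, ppi,
                       benchmark = NULL, out_dir = ".",
                       mutation_format = c("matrix", "maf"),
                       deg_threshold = 1, pseudocount = 1,
                       mif_mode = c("gravity", "literal"),
                       c_variant = c("literal", "nw"),
                       neighbor_count = c("degree", "two_hop"),
                       recall_denominator = c("in_dataset", "full_set"),
                       top_k = 50, rare_top_n = 20, rare_threshold_pct = 2,
                       uppercase = FALSE) {
  cfg <- list(
    mutation = mutation, expression_tumor = expression_tumor,
    expression_normal = expression_normal, ppi = ppi, benchmark = benchmark,
    out_dir = out_dir,
    mutation_format = match.arg(mutation_format),
    deg_threshold = deg_threshold, pseudocount = pseudocount,
    mif_mode = match.arg(mif_mode), c_variant = match.arg(c_variant),
    neighbor_count = match.arg(neighbor_count),
    recall_denominator = match.arg(recall_denominator),
    top_k = top_k, rare_top_n = rare_top_n,
    rare_threshold_pct = rare_threshold_pct, uppercase = uppercase)
  stopifnot(cfg$deg_threshold > 0, cfg$pseudocount >= 0,
            cfg$top_k >= 1, cfg$rare_top_n >= 1, cfg$rare_threshold_pct > 0)
  for (p in c("mutation", "expression_tumor", "expression_normal", "ppi",
              if (!is.null(benchmark)) "benchmark")) {
    if (!file.exists(cfg[[p]])) stop("input file for '", p, "' not found: ", cfg[[p]])
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full driver-prioritization pipeline
#'
#' Executes load -> mutation scores -> DEG calling -> merged graph ->
#' per-source semi-local scoring -> ranking -> (optional) evaluation and
#' rare-driver flagging, writing `ranking.tsv`, `evaluation.tsv`,
#' `rare_drivers.tsv` (the last two only when a benchmark is given) and
#' `run.log` under `cfg$out_dir`.  Any stage failure raises an error whose
#' message names the stage.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with `ranking`, `evaluation`, `rare_drivers`,
#'   `degs`, `scores`, `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
      }),
      message = function(m) {
        note(trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }

  note("run started ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  for (p in setdiff(names(unclass(cfg)), NULL)) {
    v <- cfg[[p]]
    note("param ", p, " = ", if (is.null(v)) "NULL" else paste(v, collapse = ","))
  }

  m <- stage("load_mutation", read_mutation_matrix(
    cfg$mutation, format = cfg$mutation_format, uppercase = cfg$uppercase))
  e <- stage("load_expression", read_expression_pair(
    cfg$expression_tumor, cfg$expression_normal, uppercase = cfg$uppercase))
  ppi <- stage("load_ppi", read_ppi(cfg$ppi, uppercase = cfg$uppercase))
  benchmark <- if (!is.null(cfg$benchmark)) {
    stage("load_benchmark", read_gene_set(cfg$benchmark, uppercase = cfg$uppercase))
  }

  scores <- stage("mutation_scores", mutation_scores(m))
  degs <- stage("call_degs", call_degs(e, threshold = cfg$deg_threshold,
                                       pseudocount = cfg$pseudocount))
  mutated <- rownames(m)[rowSums(m) > 0]
  note("mutated genes in cohort: ", length(mutated))
  note("cohort DEGs: ", length(degs$cohort))
  g <- stage("build_merged_graph", build_merged_graph(ppi, mutated, degs))
  note("merged graph: ", igraph::vcount(g), " nodes, ", igraph::ecount(g), " edges")
  ranking <- stage("rank_drivers", rank_drivers(
    g, scores, m, mif_mode = cfg$mif_mode, c_variant = cfg$c_variant,
    neighbor_count = cfg$neighbor_count))
  write_ranking(ranking, file.path(cfg$out_dir, "ranking.tsv"))

  evaluation <- NULL
  rare <- NULL
  if (!is.null(benchmark)) {
    evaluation <- stage("evaluate_ranking", evaluate_ranking(
      ranking, benchmark, mutated = mutated,
      max_k = min(cfg$top_k, nrow(ranking)),
      recall_denominator = cfg$recall_denominator))
    write_evaluation(evaluation, file.path(cfg$out_dir, "evaluation.tsv"))
    rare <- stage("flag_rare_drivers", flag_rare_drivers(
      ranking, m, benchmark, top_n = min(cfg$rare_top_n, nrow(ranking)),
      threshold_pct = cfg$rare_threshold_pct))
    write_rare_drivers(rare, file.path(cfg$out_dir, "rare_drivers.tsv"))
  }

  note("ranking written: ", nrow(ranking), " mutated genes")
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(list(ranking = ranking, evaluation = evaluation,
                 rare_drivers = rare, degs = degs, scores = scores,
                 config = cfg))
}
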