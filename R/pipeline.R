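#' Read and validate a run configuration
#'
#' The configuration is a YAML file with sections `input` (alignment path
#' and format, optional Newick tree), `model` (`plus_f`, `alpha`, `p_inv`,
#' `gamma_categories`; `alpha`/`p_inv` may be numbers or `"estimate"`),
#' `masking` (`max_gap_fraction`, `drop_ambiguous`), `placement`
#' (`clade`: query taxa, `optimize`, `graft_length`), `tests` (`scales`,
#' `replicates`, `seed`), optional `indels` (`groups`, `min_len`,
#' `boundary_slack`, `reference`) and `output` (directory).
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- function(x, what) if (is.null(x)) stop("config error: missing ", what)
  need(cfg$input$alignment, "input$alignment")
  need(cfg$placement$clade, "placement$clade")
  cfg$input$format <- cfg$input$format %||% "fasta"
  cfg$model$plus_f <- isTRUE(cfg$model$plus_f)
  cfg$model$gamma_categories <- cfg$model$gamma_categories %||% 4L
  cfg$model$alpha <- cfg$model$alpha %||% "estimate"
  cfg$model$p_inv <- cfg$model$p_inv %||% "estimate"
  cfg$masking$max_gap_fraction <- cfg$masking$max_gap_fraction %||% 0.5
  cfg$masking$drop_ambiguous <- cfg$masking$drop_ambiguous %||% TRUE
  cfg$placement$optimize <- cfg$placement$optimize %||% "graft_only"
  cfg$placement$graft_length <- cfg$placement$graft_length %||% 0.1
  cfg$tests$scales <- cfg$tests$scales %||% seq(0.5, 1.4, by = 0.1)
  cfg$tests$replicates <- cfg$tests$replicates %||% 10000L
  if (is.null(cfg$tests$seed))
    stop("config error: tests$seed is required (stochastic stage)")
  cfg$output <- cfg$output %||% "regraft-run"
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full placement pipeline
#'
#' Stages, in order: read alignment, mask columns, build the model
#' (optionally `+F` and/or estimating `alpha`/`p_inv` on the backbone),
#' accept the given tree or fit one, prune the query clade and enumerate
#' all re-graft topologies, evaluate them, run the RELL/AU/KH/SH topology
#' tests, and (when configured) scan for group-specific indel blocks.
#' Every artifact is written into the run directory together with a
#' manifest recording package version, parameters, and seeds; re-running
#' with the same configuration reproduces the artifacts exactly.
#'
#' @param cfg a `run_config` (or path to one).
#' @param out_dir output directory (defaults to `cfg$output`).
#' @param quiet suppress stage messages.
#' @return list with `report` (the topology-test table, one row per
#'   placement), `placements` (the [evaluate_placements()] result),
#'   `indels`, `artifacts` (file paths), and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  out_dir <- out_dir %||% cfg$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(out_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  say <- function(stage, ...) if (!quiet)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
  on_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(stage, ": ", conditionMessage(e)), failed)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  art <- list()

  say("read", "alignment ", cfg$input$alignment)
  aln <- on_stage("read",
    read_alignment(cfg$input$alignment, cfg$input$format))
  clade_taxa <- cfg$placement$clade
  on_stage("validate", {
    miss <- setdiff(clade_taxa, rownames(aln))
    if (length(miss)) stop("query taxa absent from alignment: ",
                           paste(miss, collapse = ", "))
  })

  say("mask", "max_gap_fraction=", cfg$masking$max_gap_fraction,
      " drop_ambiguous=", cfg$masking$drop_ambiguous)
  mk <- on_stage("mask",
    mask_columns(aln, cfg$masking$max_gap_fraction,
                 cfg$masking$drop_ambiguous))
  aln <- mk$alignment
  art$masked_alignment <- file.path(out_dir, "masked.fasta")
  write_alignment(aln, art$masked_alignment)
  art$mask <- file.path(out_dir, "mask.tsv")
  write_column_mask(mk$mask, art$mask)

  pi0 <- if (cfg$model$plus_f) empirical_frequencies(aln) else WAG_FREQS
  a0 <- if (identical(cfg$model$alpha, "estimate")) 1 else cfg$model$alpha
  p0 <- if (identical(cfg$model$p_inv, "estimate")) 0.05 else cfg$model$p_inv
  model <- substitution_model(pi = pi0, alpha = a0, p_inv = p0,
                              n_cat = cfg$model$gamma_categories)

  if (!is.null(cfg$input$tree)) {
    say("tree", "accepting fixed tree ", cfg$input$tree)
    tree <- on_stage("tree", read_newick(file = cfg$input$tree))
  } else {
    say("tree", "fitting ML tree (NJ + NNI)")
    tree <- on_stage("tree", fit_ml_tree(aln, model)$tree)
  }

  free <- c(if (identical(cfg$model$alpha, "estimate")) "alpha",
            if (identical(cfg$model$p_inv, "estimate")) "p_inv")
  if (length(free)) {
    say("model", "estimating ", paste(free, collapse = ", "))
    fit <- on_stage("model", optimize_model(tree, aln, model, free = free))
    model <- fit$model
    tree <- fit$tree
  }

  say("place", "pruning {", paste(clade_taxa, collapse = ","),
      "} and enumerating placements")
  pset <- on_stage("place", place_clade(tree, clade_taxa,
                                        cfg$placement$graft_length))
  ev <- on_stage("evaluate",
    evaluate_placements(pset, aln, model,
                        optimize = cfg$placement$optimize))
  art$site_loglik <- file.path(out_dir, "site_loglik.mt")
  write_site_loglik(ev$site_loglik, art$site_loglik)

  say("tests", "RELL bootstrap, B=", cfg$tests$replicates,
      " seed=", cfg$tests$seed)
  report <- on_stage("tests",
    topology_tests(ev$site_loglik, scales = cfg$tests$scales,
                   B = cfg$tests$replicates, seed = cfg$tests$seed,
                   edge_labels = pset$edge_labels))
  report$is_original <- report$topology == (pset$original_index %||% NA)
  art$report <- file.path(out_dir, "placement_report.tsv")
  utils::write.table(report, art$report, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  indels <- NULL
  if (!is.null(cfg$indels$groups)) {
    say("indels", "scanning group-specific gap blocks")
    indels <- on_stage("indels",
      group_specific_blocks(aln, cfg$indels$groups,
                            min_len = cfg$indels$min_len %||% 2L,
                            boundary_slack = cfg$indels$boundary_slack %||% 1L,
                            ref_taxon = cfg$indels$reference))
    art$indels <- file.path(out_dir, "indel_signals.tsv")
    utils::write.table(indels, art$indels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  art$tree <- file.path(out_dir, "input_tree.nwk")
  write_newick(tree, art$tree)
  art$manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(
    package = "regraft",
    version = as.character(utils::packageVersion("regraft")),
    config = unclass(cfg),
    model = list(alpha = model$alpha, p_inv = model$p_inv,
                 n_cat = model$n_cat, plus_f = cfg$model$plus_f),
    artifacts = art[!vapply(art, is.null, logical(1))]),
    art$manifest)
  say("done", "artifacts in ", out_dir)
  list(report = report, placements = ev, indels = indels,
       artifacts = art, out_dir = out_dir)
}
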