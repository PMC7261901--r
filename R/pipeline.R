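#' Log2-normalized expression for a feature class
#'
#' Convenience accessor: `log2(counts / size_factor + 1)` with
#' median-of-ratios size factors estimated within the class.
#'
#' @param study an `expression_study`.
#' @param class `"mrna"`, `"lncrna"` or `"mirna"`.
#' @return Numeric matrix, features x samples.
#' @export
normalized_log_expression <- function(study, class) {
  counts <- study$counts[[class]]
  if (is.null(counts)) abort("study has no counts for class '%s'", class)
  sf <- estimate_size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Pipeline configuration
#'
#' Bundles all stage thresholds, the input source (paths to on-disk
#' tables, or a [simulation_config()] to generate them), the output
#' directory and the seed. The resolved configuration is serialized next
#' to the outputs for auditability.
#'
#' @param out_dir artifact directory (created if needed).
#' @param input optional named list of input paths: `mrna`, `lncrna`,
#'   `mirna` (count TSVs), `samples` (sample sheet), `targets` (target
#'   table). When `NULL`, data are simulated from `sim`.
#' @param sim [simulation_config()] used when `input` is `NULL`; its
#'   seed is overridden by `seed`.
#' @param fc_up,fc_down,de_alpha differential-expression thresholds.
#' @param pcc_min,pcc_alpha lncRNA-mRNA correlation screen thresholds.
#' @param min_shared,hyper_alpha,universe ceRNA assembly thresholds.
#' @param beta soft threshold: `"auto"` (scale-free criterion) or a
#'   positive integer.
#' @param beta_range,r2_target,min_mean_k soft-threshold selection
#'   parameters.
#' @param cut_height,min_module_size module-detection parameters.
#' @param hub_min_degree lncRNA degree cutoff for the hub sub-network.
#' @param seed integer seed governing all stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL, sim = simulation_config(),
                            fc_up = 1.2, fc_down = 0.83, de_alpha = 0.05,
                            pcc_min = 0.8, pcc_alpha = 0.05,
                            min_shared = 2, hyper_alpha = 0.05,
                            universe = NULL,
                            beta = "auto", beta_range = 1:30,
                            r2_target = 0.8, min_mean_k = 1,
                            cut_height = 0.95, min_module_size = 5,
                            hub_min_degree = 45, seed = 1L) {
  if (!(fc_down < 1 && 1 < fc_up)) abort("need fc_down < 1 < fc_up")
  for (a in c(de_alpha, pcc_alpha))
    if (!(a > 0 && a < 1)) abort("alpha thresholds must be in (0, 1)")
  if (!(hyper_alpha > 0 && hyper_alpha <= 1))
    abort("'hyper_alpha' must be in (0, 1]")
  if (!identical(beta, "auto") &&
      !(is_scalar_number(beta) && beta >= 1 && beta == round(beta)))
    abort("'beta' must be \"auto\" or a positive integer")
  if (!is.null(input)) {
    need <- c("mrna", "lncrna", "mirna", "samples", "targets")
    if (!all(need %in% names(input)))
      abort("'input' must name paths: %s", paste(need, collapse = ", "))
  }
  structure(list(out_dir = out_dir, input = input, sim = sim,
                 fc_up = fc_up, fc_down = fc_down, de_alpha = de_alpha,
                 pcc_min = pcc_min, pcc_alpha = pcc_alpha,
                 min_shared = min_shared, hyper_alpha = hyper_alpha,
                 universe = universe, beta = beta, beta_range = beta_range,
                 r2_target = r2_target, min_mean_k = min_mean_k,
                 cut_height = cut_height, min_module_size = min_module_size,
                 hub_min_degree = hub_min_degree, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e)
    abort("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full inference pipeline
#'
#' Executes simulate/read -> differential expression -> co-expression
#' network (soft-threshold selection, TOM, modules, hub sub-network) ->
#' ceRNA assembly -> export, writing per-stage tables, Cytoscape-ready
#' network files, a log recording every threshold applied, and the
#' resolved configuration. Reruns with the same configuration and seed
#' reproduce byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`study`,
#'   `de`, `de_filtered`, `beta`, `modules`, `coexpression`, `cerna`,
#'   `degree_report`) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  files <- c()
  set.seed(config$seed)

  # --- input ---------------------------------------------------------------
  if (is.null(config$input)) {
    sim <- config$sim
    sim$seed <- config$seed
    res <- run_stage("simulate", log, {
      study <- simulate_study(sim)
      targets <- simulate_target_table(study$truth, sim)
      list(study = study, targets = targets)
    })
    study <- res$study; targets <- res$targets
    log(sprintf("simulate: seed=%d, %d+%d+%d features, %d samples/group",
                config$seed, sim$n_mrna, sim$n_lncrna, sim$n_mirna,
                sim$n_per_group))
  } else {
    study <- run_stage("read_counts", log, {
      counts <- lapply(config$input[c("mrna", "lncrna", "mirna")], read_counts)
      samples <- utils::read.delim(config$input$samples,
                                   stringsAsFactors = FALSE)
      structure(list(counts = counts, samples = samples, truth = NULL),
                class = "expression_study")
    })
    targets <- run_stage("read_targets", log,
                         read_target_table(config$input$targets))
  }

  # --- differential expression --------------------------------------------
  de <- run_stage("de", log, {
    lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"), function(cl)
      de_test(study, cl, up = config$fc_up, down = config$fc_down,
              alpha = config$de_alpha))
  })
  de_filtered <- run_stage("de_filter", log, {
    lapply(de, apply_de_filter, up = config$fc_up, down = config$fc_down,
           alpha = config$de_alpha)
  })
  for (cl in names(de)) {
    f <- file.path(config$out_dir, sprintf("de_%s.tsv", cl))
    write_de_table(de[[cl]], f)
    files[sprintf("de_%s", cl)] <- f
    log(sprintf("de %s: %d up, %d down of %d (FC > %g or < %g, p < %g)",
                cl, attr(de_filtered[[cl]], "n_up"),
                attr(de_filtered[[cl]], "n_down"), nrow(de[[cl]]),
                config$fc_up, config$fc_down, config$de_alpha))
  }

  # --- co-expression network ----------------------------------------------
  expr_lnc <- normalized_log_expression(study, "lncrna")
  expr_mrna <- normalized_log_expression(study, "mrna")
  de_lnc <- de_filtered$lncrna$feature
  de_mrna <- de_filtered$mrna$feature

  coexpr <- run_stage("coexpress", log, {
    expr_de <- rbind(expr_mrna[intersect(de_mrna, rownames(expr_mrna)), ,
                               drop = FALSE],
                     expr_lnc[intersect(de_lnc, rownames(expr_lnc)), ,
                              drop = FALSE])
    if (identical(config$beta, "auto")) {
      sweep_res <- pick_beta(expr_de, beta_range = config$beta_range,
                             r2_target = config$r2_target,
                             min_mean_k = config$min_mean_k)
      beta <- sweep_res$beta
      f <- file.path(config$out_dir, "beta_sweep.tsv")
      utils::write.table(sweep_res$sweep, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files["beta_sweep"] <- f
      log(sprintf("coexpress: beta=%d chosen (signed R^2=%.3f, mean k=%.2f, criterion %s)",
                  beta, sweep_res$fit$signed_r2, sweep_res$fit$mean_k,
                  ifelse(sweep_res$criterion_met, "met", "NOT met")))
    } else {
      beta <- as.integer(config$beta)
      log(sprintf("coexpress: beta=%d fixed by configuration", beta))
    }
    S <- similarity(expr_de)
    A <- soft_adjacency(S, beta)
    TOM <- tom(A)
    modules <- cluster_modules(1 - TOM, cut_height = config$cut_height,
                               min_module_size = config$min_module_size)
    log(sprintf("coexpress: %d modules at cut height %.2f (min size %d)",
                length(setdiff(unique(modules), "unassigned")),
                config$cut_height, config$min_module_size))
    net <- build_lnc_mrna_network(
      expr_lnc[intersect(de_lnc, rownames(expr_lnc)), , drop = FALSE],
      expr_mrna[intersect(de_mrna, rownames(expr_mrna)), , drop = FALSE],
      pcc_min = config$pcc_min, alpha = config$pcc_alpha, modules = modules)
    list(beta = beta, modules = modules, network = net)
  })
  f <- file.path(config$out_dir, "modules.tsv")
  utils::write.table(data.frame(feature = names(coexpr$modules),
                                module = unname(coexpr$modules)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["modules"] <- f
  for (fmt in c("sif", "tsv")) {
    f <- file.path(config$out_dir, paste0("coexpression.", fmt))
    write_network(coexpr$network, f, fmt)
    files[paste0("coexpression_", fmt)] <- f
  }
  hub <- extract_hub_subnetwork(coexpr$network, config$hub_min_degree)
  f <- file.path(config$out_dir, "coexpression_hubs.sif")
  write_network(hub, f, "sif")
  files["coexpression_hubs"] <- f
  log(sprintf("coexpress: %d edges, hub sub-network (degree >= %d): %d edges",
              nrow(coexpr$network$edges), config$hub_min_degree,
              nrow(hub$edges)))

  # --- ceRNA network -------------------------------------------------------
  cerna <- run_stage("cerna", log, {
    pairs <- suppressWarnings(
      candidate_pairs(expr_lnc, expr_mrna, de_lnc, de_mrna,
                      pcc_min = config$pcc_min, alpha = config$pcc_alpha))
    assemble_cerna(de, pairs, targets, alpha = config$hyper_alpha,
                   min_shared = config$min_shared,
                   universe = config$universe)
  })
  log(sprintf("cerna: PCC > %g, p < %g, shared >= %d, hypergeometric p < %g -> %d pairs retained",
              config$pcc_min, config$pcc_alpha, config$min_shared,
              config$hyper_alpha, nrow(cerna$pairs)))
  for (fmt in c("sif", "tsv", "graphml")) {
    f <- file.path(config$out_dir, paste0("cerna.", fmt))
    write_network(cerna, f, fmt)
    files[paste0("cerna_", fmt)] <- f
  }
  ranked <- degree_report(cerna)
  f <- file.path(config$out_dir, "cerna_degree_report.tsv")
  utils::write.table(ranked, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["degree_report"] <- f

  # --- resolved config + log ----------------------------------------------
  f <- file.path(config$out_dir, "config.json")
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  files["config"] <- f
  f <- file.path(config$out_dir, "pipeline.log")
  writeLines(log_lines, f)
  files["log"] <- f

  invisible(list(study = study, targets = targets, de = de,
                 de_filtered = de_filtered, beta = coexpr$beta,
                 modules = coexpr$modules, coexpression = coexpr$network,
                 hub_subnetwork = hub, cerna = cerna,
                 degree_report = ranked, files = files))
}
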