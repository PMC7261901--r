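#' Simulation configuration for a two-group ceRNA study
#'
#' Collects and validates all parameters of the synthetic-data generator.
#' Counts are drawn from a negative binomial with variance
#' `mu + dispersion * mu^2`; differential expression, co-expression modules
#' and ceRNA triples are planted on the log2 scale before sampling, so that
#' correlation structure survives the count noise.
#'
#' Each planted ceRNA triple (lncRNA, miRNA, mRNA) is driven by a latent
#' "miRNA activity" factor: the miRNA loads on it with `+sponge_strength`,
#' its lncRNA and mRNA targets with `-sponge_strength`, which induces the
#' positive lncRNA-mRNA correlation the ceRNA hypothesis predicts. The
#' activity mean is shifted between groups by `de_log2fc / sponge_strength`
#' so triple members are also differentially expressed (miRNA up, targets
#' down). Because downstream assembly keeps lncRNA-mRNA pairs only when
#' they share strictly more than one differentially expressed miRNA, every
#' triple additionally gets a "companion" up-regulated miRNA targeting both
#' members (recorded in the ground truth's target edges).
#'
#' @param n_mrna,n_lncrna,n_mirna number of features per class.
#' @param n_per_group replicates per group (>= 3).
#' @param base_mean_log_range bounds (log2 scale) of the uniform baseline
#'   mean expression; default `c(5, 12)` spans mean counts of 32 to 4096,
#'   the robust-detection regime of features that survive expression and
#'   DE filtering in bulk RNA-seq (below ~32 counts, count noise alone
#'   caps attainable pairwise correlations well under the screening
#'   thresholds this pipeline uses, so planted structure there would be
#'   unrecoverable by construction).
#' @param dispersion negative-binomial dispersion phi in
#'   `var = mu + phi * mu^2`; must be > 0.
#' @param de_fraction fraction of each class planted as differentially
#'   expressed (in `[0, 1)`), directions drawn at random.
#' @param de_log2fc magnitude of the planted log2 fold change.
#' @param n_modules,module_size number and size of planted co-expression
#'   modules (members drawn from mRNAs and lncRNAs not used in triples).
#' @param module_strength loading of the latent module factor, in (0, 1].
#' @param n_cerna_triples number of planted (lncRNA, miRNA, mRNA) triples.
#' @param sponge_strength loading of the shared miRNA-activity factor,
#'   in (0, 1].
#' @param decoy_target_fraction fraction (of true edges, in `[0, 1)`) of
#'   random false miRNA-target edges added to the simulated target table.
#' @param library_size_range bounds of the uniform per-sample library-size
#'   scaling factor.
#' @param seed integer RNG seed; a fixed seed makes all three generator
#'   operations bitwise reproducible.
#' @return An object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_mrna = 50, n_lncrna = 20, n_mirna = 10,
#'                          n_cerna_triples = 2, n_modules = 1,
#'                          module_size = 5, seed = 7)
#' study <- simulate_study(cfg)
#' dim(study$counts$mrna)
simulation_config <- function(n_mrna = 500L, n_lncrna = 100L, n_mirna = 50L,
                              n_per_group = 10L,
                              base_mean_log_range = c(5, 12),
                              dispersion = 0.05,
                              de_fraction = 0.1, de_log2fc = 1.5,
                              n_modules = 3L, module_size = 30L,
                              module_strength = 0.8,
                              n_cerna_triples = 10L, sponge_strength = 0.9,
                              decoy_target_fraction = 0.1,
                              library_size_range = c(0.7, 1.3),
                              seed = 1L) {
  for (nm in c("n_mrna", "n_lncrna", "n_mirna", "n_per_group",
               "n_modules", "module_size", "n_cerna_triples")) {
    if (!is_count_scalar(get(nm))) abort("'%s' must be a non-negative integer", nm)
  }
  if (n_per_group < 3) abort("'n_per_group' must be >= 3")
  if (!is_scalar_number(dispersion) || dispersion <= 0)
    abort("'dispersion' must be > 0")
  if (!is_scalar_number(de_fraction) || de_fraction < 0 || de_fraction >= 1)
    abort("'de_fraction' must be in [0, 1)")
  if (!is_scalar_number(de_log2fc) || de_log2fc < 0)
    abort("'de_log2fc' must be >= 0")
  if (!is_scalar_number(module_strength) || module_strength <= 0 || module_strength > 1)
    abort("'module_strength' must be in (0, 1]")
  if (!is_scalar_number(sponge_strength) || sponge_strength <= 0 || sponge_strength > 1)
    abort("'sponge_strength' must be in (0, 1]")
  if (!is_scalar_number(decoy_target_fraction) ||
      decoy_target_fraction < 0 || decoy_target_fraction >= 1)
    abort("'decoy_target_fraction' must be in [0, 1)")
  if (length(base_mean_log_range) != 2 || diff(base_mean_log_range) < 0)
    abort("'base_mean_log_range' must be an ascending pair")
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    abort("'library_size_range' must be an ascending positive pair")
  if (!is_count_scalar(abs(seed))) abort("'seed' must be an integer")

  if (n_cerna_triples > 0) {
    if (n_cerna_triples > n_lncrna || n_cerna_triples > n_mrna)
      abort("cannot place %d ceRNA triples: not enough lncRNAs or mRNAs",
            n_cerna_triples)
    if (2L * n_cerna_triples > n_mirna)
      abort(paste0("cannot place %d ceRNA triples: each needs a primary and ",
                   "a companion miRNA, but only %d miRNAs are available"),
            n_cerna_triples, n_mirna)
  }
  pool <- (n_mrna - n_cerna_triples) + (n_lncrna - n_cerna_triples)
  if (n_modules * module_size > pool)
    abort("module_size x n_modules (%d) exceeds the %d features available",
          n_modules * module_size, pool)

  structure(list(
    n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
    n_mirna = as.integer(n_mirna), n_per_group = as.integer(n_per_group),
    base_mean_log_range = as.numeric(base_mean_log_range),
    dispersion = dispersion, de_fraction = de_fraction,
    de_log2fc = de_log2fc, n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), module_strength = module_strength,
    n_cerna_triples = as.integer(n_cerna_triples),
    sponge_strength = sponge_strength,
    decoy_target_fraction = decoy_target_fraction,
    library_size_range = as.numeric(library_size_range),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

feature_ids <- function(config) {
  list(
    mrna   = sprintf("mRNA_%04d", seq_len(config$n_mrna)),
    lncrna = sprintf("lnc_%03d", seq_len(config$n_lncrna)),
    mirna  = sprintf("miR_%03d", seq_len(config$n_mirna))
  )
}

#' Simulate a two-group expression study with planted structure
#'
#' Draws negative-binomial count matrices for mRNAs, lncRNAs and miRNAs in
#' a control vs condition design, planting (i) differentially expressed
#' features at `de_log2fc`, (ii) latent-factor co-expression modules and
#' (iii) ceRNA triples (see [simulation_config()] for the generative
#' model). The returned study carries the full ground truth so downstream
#' stages can be scored against it.
#'
#' @param config a [simulation_config()].
#' @return An object of class `expression_study`: a list with
#'   `counts` (named list of integer matrices `mrna`, `lncrna`, `mirna`,
#'   features x samples), `samples` (data frame with columns `sample`,
#'   `group`, groups `control`/`condition`), and `truth` (list with
#'   `de_features`, `module_membership`, `cerna_triples`,
#'   `true_target_edges`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ids <- feature_ids(config)
  n <- config$n_per_group
  samples <- data.frame(
    sample = c(sprintf("ctrl_%02d", seq_len(n)), sprintf("cond_%02d", seq_len(n))),
    group = rep(c("control", "condition"), each = n),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)
  cond <- samples$group == "condition"

  # baseline log2 means
  r <- config$base_mean_log_range
  base <- lapply(ids, function(v) stats::runif(length(v), r[1], r[2]))
  logmu <- lapply(names(ids), function(cl) {
    m <- matrix(base[[cl]], nrow = length(ids[[cl]]), ncol = ns)
    dimnames(m) <- list(ids[[cl]], samples$sample)
    m
  })
  names(logmu) <- names(ids)

  # --- plant ceRNA triples -------------------------------------------------
  nt <- config$n_cerna_triples
  triples <- data.frame(lncrna = character(0), mirna = character(0),
                        mrna = character(0), companion = character(0),
                        stringsAsFactors = FALSE)
  if (nt > 0) {
    lnc_idx <- sample.int(config$n_lncrna, nt)
    mrna_idx <- sample.int(config$n_mrna, nt)
    mir_idx <- sample.int(config$n_mirna, 2L * nt)
    triples <- data.frame(
      lncrna = ids$lncrna[lnc_idx],
      mirna = ids$mirna[mir_idx[seq_len(nt)]],
      mrna = ids$mrna[mrna_idx],
      companion = ids$mirna[mir_idx[nt + seq_len(nt)]],
      stringsAsFactors = FALSE
    )
  }
  triple_members <- list(
    mrna = triples$mrna, lncrna = triples$lncrna,
    mirna = c(triples$mirna, triples$companion)
  )

  # --- plant independent DE features --------------------------------------
  de <- data.frame(feature = character(0), class = character(0),
                   direction = character(0), stringsAsFactors = FALSE)
  for (cl in names(ids)) {
    free <- setdiff(ids[[cl]], triple_members[[cl]])
    n_de <- round(config$de_fraction * length(ids[[cl]]))
    n_de <- min(n_de, length(free))
    if (n_de > 0) {
      feats <- sample(free, n_de)
      dirs <- sample(c("up", "down"), n_de, replace = TRUE)
      de <- rbind(de, data.frame(feature = feats, class = class_label(cl),
                                 direction = dirs, stringsAsFactors = FALSE))
      shift <- ifelse(dirs == "up", 1, -1) * config$de_log2fc
      logmu[[cl]][feats, cond] <- logmu[[cl]][feats, cond] + shift
    }
  }
  # companion miRNAs are planted DE up so they survive the DE gate
  if (nt > 0) {
    logmu$mirna[triples$companion, cond] <-
      logmu$mirna[triples$companion, cond] + config$de_log2fc
    de <- rbind(de,
      data.frame(feature = triples$mirna, class = "miRNA", direction = "up",
                 stringsAsFactors = FALSE),
      data.frame(feature = triples$companion, class = "miRNA",
                 direction = "up", stringsAsFactors = FALSE),
      data.frame(feature = triples$lncrna, class = "lncRNA",
                 direction = "down", stringsAsFactors = FALSE),
      data.frame(feature = triples$mrna, class = "mRNA", direction = "down",
                 stringsAsFactors = FALSE))
  }

  # --- plant co-expression modules ----------------------------------------
  module_membership <- character(0)
  if (config$n_modules > 0 && config$module_size > 0) {
    pool <- c(setdiff(ids$mrna, triple_members$mrna),
              setdiff(ids$lncrna, triple_members$lncrna))
    members <- sample(pool, config$n_modules * config$module_size)
    lab <- rep(sprintf("module_%d", seq_len(config$n_modules)),
               each = config$module_size)
    module_membership <- stats::setNames(lab, members)
    z <- matrix(stats::rnorm(config$n_modules * ns), config$n_modules, ns)
    for (m in seq_len(config$n_modules)) {
      feats <- members[lab == sprintf("module_%d", m)]
      for (cl in c("mrna", "lncrna")) {
        f <- intersect(feats, ids[[cl]])
        if (length(f))
          logmu[[cl]][f, ] <- logmu[[cl]][f, ] +
            config$module_strength * matrix(z[m, ], length(f), ns, byrow = TRUE)
      }
    }
  }

  # --- sponge latent factors -----------------------------------------------
  if (nt > 0) {
    s <- config$sponge_strength
    delta <- config$de_log2fc / s  # activity mean shift so the miRNA's log2FC = de_log2fc
    act <- matrix(stats::rnorm(nt * ns), nt, ns) +
      matrix(rep(ifelse(cond, delta, 0), each = nt), nt, ns)
    for (t in seq_len(nt)) {
      logmu$mirna[triples$mirna[t], ] <- logmu$mirna[triples$mirna[t], ] + s * act[t, ]
      logmu$lncrna[triples$lncrna[t], ] <- logmu$lncrna[triples$lncrna[t], ] - s * act[t, ]
      logmu$mrna[triples$mrna[t], ] <- logmu$mrna[triples$mrna[t], ] - s * act[t, ]
    }
    # undo the fixed DE shift that the activity mean already provides to
    # triple lncRNA/mRNA targets is not needed: targets get their whole
    # group effect (-de_log2fc) through the shifted activity mean.
  }

  # --- library sizes and NB sampling ---------------------------------------
  lib <- stats::runif(ns, config$library_size_range[1], config$library_size_range[2])
  counts <- lapply(names(ids), function(cl) {
    mu <- sweep(2^logmu[[cl]], 2, lib, "*")
    cnt <- stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    matrix(as.integer(cnt), nrow = nrow(mu), dimnames = dimnames(mu))
  })
  names(counts) <- names(ids)

  edges <- data.frame(mirna = character(0), target = character(0),
                      stringsAsFactors = FALSE)
  if (nt > 0) {
    edges <- unique(data.frame(
      mirna = rep(c(triples$mirna, triples$companion), times = 2),
      target = rep(c(triples$lncrna, triples$lncrna,
                     triples$mrna, triples$mrna)),
      stringsAsFactors = FALSE
    ))
  }

  truth <- list(
    de_features = unique(de),
    module_membership = module_membership,
    cerna_triples = triples[, c("lncrna", "mirna", "mrna")],
    companion_mirnas = triples$companion,
    true_target_edges = edges
  )
  structure(list(counts = counts, samples = samples, truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:",
      paste(vapply(x$counts, nrow, 1L), names(x$counts), collapse = ", "),
      "|", nrow(x$samples), "samples\n")
  if (!is.null(x$truth))
    cat("  with ground truth:", nrow(x$truth$cerna_triples),
        "planted triples,", nrow(x$truth$de_features), "DE features\n")
  invisible(x)
}

#' Simulate a miRNA-target table
#'
#' Produces the table a sequence-based target predictor would emit: every
#' true miRNA-target edge of the ground truth with an MRE (miRNA response
#' element) count drawn uniformly from 1-3, plus
#' `decoy_target_fraction * n_true` random false edges between miRNA and
#' mRNA/lncRNA pairs not in the truth.
#'
#' @param truth the `truth` element of a simulated [simulate_study()]
#'   result.
#' @param config the [simulation_config()] that generated the study.
#' @return A data frame with columns `mirna`, `target`, `target_class`
#'   (`mRNA`/`lncRNA`) and `mre_count`, unique in (`mirna`, `target`).
#' @export
simulate_target_table <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(truth)) abort("'truth' must be a populated ground-truth list")
  set.seed(config$seed + 10007L)
  ids <- feature_ids(config)
  tab <- truth$true_target_edges
  n_true <- nrow(tab)
  n_decoy <- round(config$decoy_target_fraction * n_true)
  if (n_decoy > 0) {
    seen <- paste(tab$mirna, tab$target)
    decoys <- data.frame(mirna = character(0), target = character(0),
                         stringsAsFactors = FALSE)
    all_targets <- c(ids$mrna, ids$lncrna)
    guard <- 0L
    while (nrow(decoys) < n_decoy) {
      need <- n_decoy - nrow(decoys)
      cand <- data.frame(
        mirna = sample(ids$mirna, need, replace = TRUE),
        target = sample(all_targets, need, replace = TRUE),
        stringsAsFactors = FALSE
      )
      key <- paste(cand$mirna, cand$target)
      keep <- !(key %in% seen) & !duplicated(key)
      decoys <- rbind(decoys, cand[keep, ])
      seen <- c(seen, key[keep])
      guard <- guard + 1L
      if (guard > 1000L) abort("could not place decoy edges (space exhausted)")
    }
    tab <- rbind(tab, decoys)
  }
  tab$target_class <- ifelse(startsWith(tab$target, "lnc_"), "lncRNA", "mRNA")
  tab$mre_count <- sample(1:3, nrow(tab), replace = TRUE)
  rownames(tab) <- NULL
  tab[, c("mirna", "target", "target_class", "mre_count")]
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Emits the three count TSVs, the sample sheet, optionally the target
#' table, and (when present) the ground truth as JSON — all readable back
#' with [read_fixture()].
#'
#' @param study an `expression_study`.
#' @param directory output directory (created if absent).
#' @param targets optional target table from [simulate_target_table()].
#' @return Invisibly, the named character vector of files written.
#' @export
write_fixture <- function(study, directory, targets = NULL) {
  stopifnot(inherits(study, "expression_study"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (cl in names(study$counts)) {
    f <- file.path(directory, paste0(cl, "_counts.tsv"))
    write_counts(study$counts[[cl]], f)
    files[paste0(cl, "_counts")] <- f
  }
  f <- file.path(directory, "samples.tsv")
  utils::write.table(study$samples, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["samples"] <- f
  if (!is.null(targets)) {
    f <- file.path(directory, "target_table.tsv")
    write_target_table(targets, f)
    files["targets"] <- f
  }
  if (!is.null(study$truth)) {
    f <- file.path(directory, "truth.json")
    truth <- study$truth
    truth$module_membership <- as.list(truth$module_membership)
    jsonlite::write_json(truth, f, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
    files["truth"] <- f
  }
  invisible(files)
}

#' Read back a fixture directory written by [write_fixture()]
#'
#' @param directory directory containing the fixture files.
#' @return A list with `study` (an `expression_study`, `truth` NULL when no
#'   truth file is present) and `targets` (NULL when absent).
#' @export
read_fixture <- function(directory) {
  counts <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
                   function(cl) read_counts(file.path(directory, paste0(cl, "_counts.tsv"))))
  samples <- utils::read.delim(file.path(directory, "samples.tsv"),
                               stringsAsFactors = FALSE)
  truth <- NULL
  tf <- file.path(directory, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth$module_membership <- unlist(truth$module_membership) %||% character(0)
    if (!is.character(truth$module_membership))
      truth$module_membership <- character(0)
    truth$de_features <- as.data.frame(truth$de_features)
    truth$cerna_triples <- as.data.frame(truth$cerna_triples)
    truth$true_target_edges <- as.data.frame(truth$true_target_edges)
  }
  targets <- NULL
  gf <- file.path(directory, "target_table.tsv")
  if (file.exists(gf)) targets <- read_target_table(gf)
  list(
    study = structure(list(counts = counts, samples = samples, truth = truth),
                      class = "expression_study"),
    targets = targets
  )
}
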