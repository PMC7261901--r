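# Independent oracles and small fixture factories shared across tests.
# Oracles are deliberately naive (loops, enumeration, closed forms) and
# never call the package functions they check.

# triple-nested-loop topological overlap
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  TOM <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + A[i, u] * A[u, j]
    TOM[i, j] <- (L + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  TOM
}

# upper-tail hypergeometric by full enumeration of all C(N, n) draws:
# K-set is features 1..K; returns P[overlap >= x]
hyper_enum_oracle <- function(N, K, n, x) {
  if (n == 0) return(if (x == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= x)
}

# from-formula Pearson r and two-sided t-based p
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# random valid adjacency matrix: symmetric, [0, 1], zero diagonal
random_adjacency <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# sample from the continuous power-law density p(k) ~ k^-2 on [kmin, kmax]
# by inverse-transform: F(k) = (1/kmin - 1/k) / (1/kmin - 1/kmax)
rpowerlaw2 <- function(n, kmin = 1, kmax = 50) {
  u <- stats::runif(n)
  1 / (1 / kmin - u * (1 / kmin - 1 / kmax))
}

# compact simulation config for fast tests
tiny_config <- function(...) {
  defaults <- list(n_mrna = 60, n_lncrna = 30, n_mirna = 40, n_per_group = 5,
                   n_modules = 1, module_size = 8, n_cerna_triples = 3,
                   seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# null world: no planted structure at all
null_config <- function(n_features = 2000, n_per_group = 10, seed = 1) {
  simulation_config(n_mrna = n_features, n_lncrna = 10, n_mirna = 10,
                    n_per_group = n_per_group, de_fraction = 0,
                    n_modules = 0, module_size = 0, n_cerna_triples = 0,
                    seed = seed)
}

# strong-effect config used by the recovery tests (sizes: see ledger)
recovery_config <- function(seed) {
  simulation_config(n_mrna = 300, n_lncrna = 80, n_mirna = 150,
                    n_per_group = 20, n_cerna_triples = 10,
                    sponge_strength = 0.9, de_log2fc = 1.5,
                    decoy_target_fraction = 0.1, dispersion = 0.05,
                    seed = seed)
}

# planted-triple recovery through the full pipeline stages; returns
# pair-level recall/precision vs ground truth (see ledger for the metric)
run_recovery <- function(seed) {
  cfg <- recovery_config(seed)
  study <- simulate_study(cfg)
  targets <- simulate_target_table(study$truth, cfg)
  de <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
               function(cl) de_test(study, cl))
  def <- lapply(de, apply_de_filter)
  el <- normalized_log_expression(study, "lncrna")
  em <- normalized_log_expression(study, "mrna")
  pairs <- candidate_pairs(el, em, def$lncrna$feature, def$mrna$feature)
  net <- assemble_cerna(de, pairs, targets)
  tr <- study$truth$cerna_triples
  key <- paste(net$pairs$lncrna, net$pairs$mrna)
  tkey <- paste(tr$lncrna, tr$mrna)
  recalled <- mapply(function(l, mi, m) {
    i <- match(paste(l, m), key)
    !is.na(i) && mi %in% strsplit(net$pairs$shared[i], ",", fixed = TRUE)[[1]]
  }, tr$lncrna, tr$mirna, tr$mrna)
  list(recall = mean(recalled),
       precision = if (length(key)) mean(key %in% tkey) else NA_real_,
       network = net, study = study)
}
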