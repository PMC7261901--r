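test_that("pearson_test matches closed forms and the hand-formula oracle", {
  x <- 1:10
  res <- pearson_test(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  x2 <- c(1, 2, 3, 4, 5)
  y2 <- c(1, 2, 3, 5, 4)
  res2 <- pearson_test(x2, y2)
  oracle <- pearson_oracle(x2, y2)
  expect_equal(res2$r, oracle$r, tolerance = 1e-10)
  expect_equal(res2$p, oracle$p, tolerance = 1e-10)

  # r = 0 -> t = 0 -> p = 1 (orthogonal contrast)
  res3 <- pearson_test(c(1, -1, 1, -1, 0), c(1, 1, -1, -1, 0))
  expect_equal(res3$r, 0)
  expect_equal(res3$p, 1)

  expect_error(pearson_test(1:3, 1:3), "n >= 4")
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
  expect_error(pearson_test(1:4, 1:5), "equal length")
})

test_that("hypergeom_shared_test is exact against enumeration", {
  # worked case: N=10, K=5, n=4, x=4 -> C(5,4)/C(10,4) = 5/210
  expect_equal(hypergeom_shared_test(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_shared_test(10, 5, 4, 4),
               hyper_enum_oracle(10, 5, 4, 4), tolerance = 1e-12)
  expect_equal(hypergeom_shared_test(8, 3, 5, 0), 1)
  # symmetry in (K, n)
  expect_equal(hypergeom_shared_test(12, 7, 4, 3),
               hypergeom_shared_test(12, 4, 7, 3), tolerance = 1e-14)
  expect_error(hypergeom_shared_test(5, 6, 2, 1), "universe")
  expect_error(hypergeom_shared_test(10, 2, 3, 4), "n_shared")
  expect_error(hypergeom_shared_test(10, 2.5, 3, 1), "integers")
  # spot enumeration at N = 9
  for (K in c(2, 5, 8)) for (n in c(3, 6)) for (x in 0:min(K, n)) {
    expect_equal(hypergeom_shared_test(9, K, n, x),
                 hyper_enum_oracle(9, K, n, x), tolerance = 1e-12)
  }
})

toy_targets <- function() {
  data.frame(
    mirna = c("miR-a", "miR-a", "miR-b", "miR-b", "miR-c", "miR-d"),
    target = c("L1", "M1", "L1", "M1", "L1", "M2"),
    target_class = c("lncRNA", "mRNA", "lncRNA", "mRNA", "lncRNA", "mRNA"),
    mre_count = c(2L, 1L, 1L, 3L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

test_that("shared_mirnas intersects DE miRNAs targeting both members", {
  tg <- toy_targets()
  de_mir <- c("miR-a", "miR-b", "miR-c", "miR-d")
  sh <- shared_mirnas("L1", "M1", tg, de_mir)
  expect_identical(sh$shared, c("miR-a", "miR-b"))
  expect_equal(sh$mre_lncrna, 3)  # 2 (miR-a) + 1 (miR-b)
  expect_equal(sh$mre_mrna, 4)    # 1 + 3
  # no common miRNA
  expect_length(shared_mirnas("L1", "M2", tg, de_mir)$shared, 0)
  # miRNA not DE is not counted
  expect_identical(shared_mirnas("L1", "M1", tg, "miR-a")$shared, "miR-a")
})

test_that("candidate_pairs applies strict signed thresholds", {
  set.seed(9)
  n <- 12
  base <- rnorm(n)
  expr_lnc <- rbind(L1 = base + 0.1 * rnorm(n),
                    L2 = rnorm(n),
                    L3 = -base + 0.1 * rnorm(n))  # anti-correlated
  expr_mrna <- rbind(M1 = base + 0.1 * rnorm(n), M2 = rnorm(n), M3 = rnorm(n))
  colnames(expr_lnc) <- colnames(expr_mrna) <- sprintf("s%d", 1:n)
  pairs <- candidate_pairs(expr_lnc, expr_mrna, rownames(expr_lnc),
                           rownames(expr_mrna), pcc_min = 0.8, alpha = 0.05)
  expect_identical(paste(pairs$lncrna, pairs$mrna), "L1 M1")
  # anti-correlated pair excluded under the signed rule even though |r| > 0.8
  expect_lt(cor(expr_lnc["L3", ], expr_mrna["M1", ]), -0.8)

  # a pair exactly at the threshold is excluded (strict >)
  r_exact <- cor(expr_lnc["L1", ], expr_mrna["M1", ])
  at <- candidate_pairs(expr_lnc, expr_mrna, "L1", "M1",
                        pcc_min = r_exact, alpha = 0.05)
  expect_equal(nrow(at), 0)

  expect_warning(out <- candidate_pairs(expr_lnc, expr_mrna, character(0),
                                        rownames(expr_mrna)),
                 "empty")
  expect_equal(nrow(out), 0)
})

de_tables_for <- function(features) {
  # minimal DE-table list marking every listed feature as DE
  mk <- function(f, class, call) data.frame(
    feature = f, class = class, base_mean = 10, fold_change = 2, log2fc = 1,
    p_value = 0.001, fdr = 0.01, call = call, stringsAsFactors = FALSE)
  list(mrna = mk(features$mrna, "mRNA", "down"),
       lncrna = mk(features$lncrna, "lncRNA", "down"),
       mirna = mk(features$mirna, "miRNA", "up"))
}

test_that("assemble_cerna reproduces the engineered single-triple network", {
  # triple (L1, miR-a, M1) plus one extra shared miRNA miR-b; 8 further DE
  # miRNAs enlarge the universe so the overlap is significant:
  # K = n = 2, x = 2, N = 10 -> p = 1/C(10,2) = 1/45 < 0.05
  de <- de_tables_for(list(mrna = "M1", lncrna = "L1",
                           mirna = c("miR-a", "miR-b",
                                     sprintf("miR-x%d", 1:8))))
  tg <- data.frame(mirna = c("miR-a", "miR-a", "miR-b", "miR-b"),
                   target = c("L1", "M1", "L1", "M1"),
                   target_class = rep(c("lncRNA", "mRNA"), 2),
                   mre_count = 1L, stringsAsFactors = FALSE)
  pairs <- data.frame(lncrna = "L1", mrna = "M1", pcc = 0.95, pcc_p = 1e-4,
                      stringsAsFactors = FALSE)
  net <- assemble_cerna(de, pairs, tg, alpha = 0.05, min_shared = 2)
  # 1 lncRNA + 2 shared miRNAs + 1 mRNA; 4 target edges + 1 coexp edge
  expect_equal(sum(net$nodes$class == "lncRNA"), 1)
  expect_equal(sum(net$nodes$class == "miRNA"), 2)
  expect_equal(sum(net$nodes$class == "mRNA"), 1)
  expect_equal(nrow(net$edges), 5)
  expect_equal(sum(net$edges$type == "targets"), 4)
  expect_identical(net$nodes$direction[net$nodes$node == "miR-a"], "up")
  expect_identical(net$nodes$direction[net$nodes$node == "L1"], "down")
  expect_equal(net$pairs$hypergeom_p, 1 / 45, tolerance = 1e-12)
})

test_that("exactly one shared miRNA is not enough (strict 'more than 1')", {
  de <- de_tables_for(list(mrna = "M1", lncrna = "L1", mirna = "miR-a"))
  pairs <- data.frame(lncrna = "L1", mrna = "M1", pcc = 0.95, pcc_p = 1e-4,
                      stringsAsFactors = FALSE)
  net <- assemble_cerna(de, pairs, toy_targets(), alpha = 1, min_shared = 2)
  expect_equal(nrow(net$pairs), 0)
  expect_equal(nrow(net$nodes), 0)
})

test_that("alpha = 1 with min_shared = 0 keeps every candidate pair", {
  de <- de_tables_for(list(mrna = c("M1", "M2"), lncrna = c("L1", "L2"),
                           mirna = c("miR-a", "miR-b", "miR-c", "miR-d")))
  pairs <- data.frame(lncrna = c("L1", "L2"), mrna = c("M1", "M2"),
                      pcc = c(0.9, 0.85), pcc_p = c(1e-4, 1e-3),
                      stringsAsFactors = FALSE)
  net <- assemble_cerna(de, pairs, toy_targets(), alpha = 1, min_shared = 0)
  expect_equal(nrow(net$pairs), 2)
})

test_that("filtering is monotone in its thresholds", {
  set.seed(33)
  study <- simulate_study(tiny_config(n_per_group = 10, seed = 33))
  targets <- simulate_target_table(study$truth, tiny_config(seed = 33))
  de <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
               function(cl) de_test(study, cl))
  el <- normalized_log_expression(study, "lncrna")
  em <- normalized_log_expression(study, "mrna")
  all_lnc <- rownames(el); all_mrna <- rownames(em)
  strict <- suppressWarnings(
    candidate_pairs(el, em, all_lnc, all_mrna, pcc_min = 0.9, alpha = 0.01))
  loose <- suppressWarnings(
    candidate_pairs(el, em, all_lnc, all_mrna, pcc_min = 0.7, alpha = 0.1))
  expect_true(all(paste(strict$lncrna, strict$mrna) %in%
                    paste(loose$lncrna, loose$mrna)))
  net_strict <- assemble_cerna(de, strict, targets, alpha = 0.05,
                               min_shared = 2)
  net_loose <- assemble_cerna(de, loose, targets, alpha = 0.5, min_shared = 1)
  expect_true(all(paste(net_strict$pairs$lncrna, net_strict$pairs$mrna) %in%
                    paste(net_loose$pairs$lncrna, net_loose$pairs$mrna)))
})

test_that("networks are tripartite: no within-class edges", {
  res <- run_recovery(seed = 101)
  net <- res$network
  cls <- setNames(net$nodes$class, net$nodes$node)
  expect_true(all(cls[net$edges$from] != cls[net$edges$to]))
  # target edges always start at a miRNA; coexp edges join lncRNA to mRNA
  tgt <- net$edges[net$edges$type == "targets", ]
  expect_true(all(cls[tgt$from] == "miRNA"))
  co <- net$edges[net$edges$type == "coexp", ]
  expect_true(all(cls[co$from] == "lncRNA" & cls[co$to] == "mRNA"))
})

test_that("null worlds retain (almost) no pairs", {
  retained <- tested <- 0
  for (s in 1:3) {
    cfg <- simulation_config(n_mrna = 150, n_lncrna = 40, n_mirna = 30,
                             n_per_group = 10, de_fraction = 0.2,
                             n_modules = 0, module_size = 0,
                             n_cerna_triples = 0, seed = s)
    study <- simulate_study(cfg)
    targets <- simulate_target_table(study$truth, cfg)
    de <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
                 function(cl) de_test(study, cl))
    def <- lapply(de, apply_de_filter)
    el <- normalized_log_expression(study, "lncrna")
    em <- normalized_log_expression(study, "mrna")
    pairs <- suppressWarnings(
      candidate_pairs(el, em, def$lncrna$feature, def$mrna$feature))
    net <- assemble_cerna(de, pairs, targets)
    retained <- retained + nrow(net$pairs)
    tested <- tested + max(1, nrow(def$lncrna) * nrow(def$mrna))
  }
  expect_lte(retained / tested, 0.01)
})

test_that("degree_report ranks by degree then node ID", {
  de <- de_tables_for(list(mrna = sprintf("M%d", 1:6), lncrna = "L1",
                           mirna = "miR-a"))
  tg <- data.frame(mirna = "miR-a", target = c("L1", sprintf("M%d", 1:6)),
                   target_class = c("lncRNA", rep("mRNA", 6)),
                   mre_count = 1L, stringsAsFactors = FALSE)
  pairs <- data.frame(lncrna = rep("L1", 6), mrna = sprintf("M%d", 1:6),
                      pcc = 0.9, pcc_p = 1e-4, stringsAsFactors = FALSE)
  net <- assemble_cerna(de, pairs, tg, alpha = 1, min_shared = 1)
  rep_tab <- degree_report(net)
  # star: miR-a targets L1 and all 6 mRNAs -> degree 7; L1: 6 coexp + 1 = 7
  expect_equal(rep_tab$node[1:2], c("L1", "miR-a"))  # tie broken by ID
  expect_true(all(diff(rep_tab$degree) <= 0))
  empty <- assemble_cerna(de, pairs[0, ], tg)
  expect_equal(nrow(degree_report(empty)), 0)
})

test_that("extract_mirna_subnetwork returns exactly the queried star", {
  de <- de_tables_for(list(mrna = c("M1", "M2", "M3"), lncrna = c("L1", "L2"),
                           mirna = c("miR-x", "miR-y")))
  tg <- data.frame(
    mirna = c("miR-x", "miR-x", "miR-x", "miR-y", "miR-y"),
    target = c("L1", "M1", "M2", "L2", "M3"),
    target_class = c("lncRNA", "mRNA", "mRNA", "lncRNA", "mRNA"),
    mre_count = 1L, stringsAsFactors = FALSE)
  pairs <- data.frame(lncrna = c("L1", "L1", "L2"), mrna = c("M1", "M2", "M3"),
                      pcc = 0.9, pcc_p = 1e-4, stringsAsFactors = FALSE)
  net <- assemble_cerna(de, pairs, tg, alpha = 1, min_shared = 1)
  sub <- extract_mirna_subnetwork(net, "miR-x")
  expect_setequal(sub$nodes$node, c("miR-x", "L1", "M1", "M2"))
  expect_equal(sum(sub$edges$type == "coexp"), 2)  # L1-M1, L1-M2 kept
  expect_false("M3" %in% sub$nodes$node)
  expect_error(extract_mirna_subnetwork(net, "miR-absent"), "miR-absent")
})
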