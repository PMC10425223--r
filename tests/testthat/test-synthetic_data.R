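test_that("config validation names the offending field", {
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(n_enriched = 100, n_depleted = 100,
                          n_features = 150), "n_enriched")
  expect_error(sim_config(n_diff_gene_families = 10, n_gene_families = 5),
               "n_diff_gene_families")
  expect_error(sim_config(gene_flip_rate = 0.5), "gene_flip_rate")
  expect_error(sim_config(cytokine_assoc_rho = 1), "cytokine_assoc_rho")
  expect_error(sim_config(cluster_mixing = 1.2), "cluster_mixing")
  # null planted counts are legal
  expect_s3_class(sim_config(n_enriched = 0, n_depleted = 0), "sim_config")
})

test_that("metadata generation honors counts, cohort structure, determinism", {
  cfg <- sim_config(n_cases = 5, n_controls = 5, seed = 1)
  md <- simulate_metadata(cfg)
  expect_equal(nrow(md), 10)
  expect_equal(as.vector(table(md$cohort)), c(5, 5))
  expect_identical(md, simulate_metadata(cfg))
  # clinical fields present for cases only
  expect_true(all(!is.na(md$cd4_count[md$cohort == "case"])))
  expect_true(all(is.na(md$cd4_count[md$cohort == "control"])))
  expect_true(all(md$read_count > 0))
})

test_that("abundance tables are compositional and deterministic", {
  cfg <- small_sim(seed = 4)
  md <- simulate_metadata(cfg)
  ab <- simulate_abundance(cfg, md)
  expect_lt(max(abs(rowSums(ab$table) - 1)), 1e-9)
  expect_equal(length(ab$truth$enriched_features), 8)
  expect_equal(length(intersect(ab$truth$enriched_features,
                                ab$truth$depleted_features)), 0)
  expect_identical(ab, simulate_abundance(cfg, md))
  # sparsity knob produces zeros without emptying samples
  expect_gt(mean(ab$table == 0), 0.05)
  expect_true(all(rowSums(ab$table) > 0))
})

test_that("null tables have equal group means in expectation", {
  cfg <- small_sim(seed = 9, n_enriched = 0, n_depleted = 0, sparsity = 0)
  diffs <- replicate(20, {
    cfg$seed <- cfg$seed + 1
    md <- simulate_metadata(cfg)
    ab <- simulate_abundance(cfg, md)
    g <- md$cohort == "case"
    mean(colMeans(ab$table[g, ]) - colMeans(ab$table[!g, ]))
  })
  expect_lt(abs(mean(diffs)), 0.005)
})

test_that("planted log2 fold change is recovered in the group mean ratio", {
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_features = 200,
                    n_enriched = 1, n_depleted = 0, effect_log2fc = 1,
                    sparsity = 0, seed = 5)
  md <- simulate_metadata(cfg)
  ab <- simulate_abundance(cfg, md)
  f <- ab$truth$enriched_features
  ratio <- mean(ab$table[md$cohort == "case", f]) /
    mean(ab$table[md$cohort == "control", f])
  # closed-form: the planted shift multiplies the log-normal mean by 2;
  # with one feature in 200 the re-closure distortion is negligible
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("gene-family generator degenerates correctly and is set-exact", {
  cfg <- small_sim(seed = 6, gene_flip_rate = 0, cluster_mixing = 0)
  md <- simulate_metadata(cfg)
  gf <- simulate_gene_families(cfg, md)
  m <- gf$matrix
  cases <- md$sample_id[md$cohort == "case"]
  ctrls <- md$sample_id[md$cohort == "control"]
  expect_equal(length(unique(apply(m[cases, ], 1, paste, collapse = ""))), 1)
  expect_equal(length(unique(apply(m[ctrls, ], 1, paste, collapse = ""))), 1)
  # Jaccard between the archetypes equals |delta| / |union| by set arithmetic
  a <- m[cases[1], ]; b <- m[ctrls[1], ]
  d_expected <- sum(a != b) / sum(a | b)
  expect_equal(jaccard_distance_matrix(m[c(cases[1], ctrls[1]), ])[1, 2],
               d_expected, tolerance = 1e-12)
  expect_equal(sum(a != b), 120)  # exactly the planted differential genes
})

test_that("identical archetypes give label-independent clustering", {
  cfg <- small_sim(seed = 7, n_diff_gene_families = 0, gene_flip_rate = 0.05)
  md <- simulate_metadata(cfg)
  gf <- simulate_gene_families(cfg, md)
  d <- jaccard_distance_matrix(gf$matrix)
  # every pair is statistically exchangeable: between-cohort distances match
  # within-cohort distances
  g <- md$cohort[match(rownames(d), md$sample_id)]
  same <- outer(g, g, "==")
  up <- upper.tri(d)
  expect_lt(abs(mean(d[up & same]) - mean(d[up & !same])), 0.01)
})

test_that("cytokines carry the planted partial correlation and confounding", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_features = 50,
                    n_enriched = 10, n_depleted = 5,
                    cytokine_assoc_rho = 0.9, seed = 21)
  md <- simulate_metadata(cfg)
  ab <- simulate_abundance(cfg, md)
  ck <- simulate_cytokines(cfg, md, ab$table)
  tr <- ck$truth
  est <- adjusted_spearman(ab$table[, tr$feature[1]],
                           ck$cytokines[, tr$phenotype[1]],
                           data.frame(age = md$age, sex = md$sex))
  expect_equal(est$rho, tr$sign[1] * 0.9, tolerance = 0.1)
  expect_true(all(ck$cytokines > 0))
  expect_error(simulate_cytokines(cfg, md[1:10, ], ab$table), "aligned")
})

test_that("zero confounding makes plain and adjusted Spearman agree", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_features = 50,
                    n_enriched = 10, n_depleted = 5,
                    cytokine_assoc_rho = 0.5, confounder_strength = 0,
                    seed = 31)
  md <- simulate_metadata(cfg)
  ab <- simulate_abundance(cfg, md)
  ck <- simulate_cytokines(cfg, md, ab$table)
  tr <- ck$truth
  x <- ab$table[, tr$feature[1]]; y <- ck$cytokines[, tr$phenotype[1]]
  plain <- cor(x, y, method = "spearman")
  adj <- adjusted_spearman(x, y, data.frame(age = md$age,
                                            sex = md$sex))$rho
  expect_equal(adj, plain, tolerance = 0.05)
})

test_that("rho = 0 targets leave cytokines independent of features", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_features = 20,
                    n_enriched = 2, n_depleted = 2,
                    cytokine_assoc_rho = 0, seed = 41)
  md <- simulate_metadata(cfg)
  ab <- simulate_abundance(cfg, md)
  ck <- simulate_cytokines(cfg, md, ab$table)
  expect_equal(nrow(ck$truth), 0)
  rho <- adjusted_spearman(ab$table[, 1], ck$cytokines[, 1],
                           data.frame(age = md$age, sex = md$sex))$rho
  expect_lt(abs(rho), 0.2)
})
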