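test_that("BH step-up matches hand computation and stats::p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(16)
  p <- runif(50)^2
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is monotone: raising any p never lowers any q", {
  set.seed(17)
  for (i in 1:10) {
    p <- runif(12)
    q <- bh_fdr(p)
    j <- sample(12, 1)
    p2 <- p; p2[j] <- min(1, p[j] + runif(1) * (1 - p[j]))
    expect_true(all(bh_fdr(p2) >= q - 1e-12))
  }
})

test_that("differential abundance recovers planted effects with signs", {
  sens <- sapply(1:5, function(s) {
    cfg <- sim_config(n_cases = 150, n_controls = 190, n_features = 200,
                      n_enriched = 20, n_depleted = 10, effect_log2fc = 1,
                      seed = 100 + s)
    md <- simulate_metadata(cfg)
    ab <- simulate_abundance(cfg, md)
    z <- inverse_rank_transform(clr_transform(ab$table))
    da <- differential_abundance(z, md)
    expect_s3_class(da, "da_result")
    expect_true(all(da$q >= da$p - 1e-12))
    expect_true(all((da$direction == "enriched") == (da$beta > 0)))
    planted <- c(ab$truth$enriched_features, ab$truth$depleted_features)
    hits <- da$feature_id[da$q < 0.05]
    found <- intersect(hits, planted)
    expect_true(all(sign(da$beta[match(found, da$feature_id)]) ==
                      ifelse(found %in% ab$truth$enriched_features, 1, -1)))
    length(found) / length(planted)
  })
  expect_gte(mean(sens), 0.8)
})

test_that("differential abundance flags constants and rank deficiency", {
  cfg <- small_sim(seed = 18)
  md <- simulate_metadata(cfg)
  ab <- simulate_abundance(cfg, md)
  z <- inverse_rank_transform(clr_transform(ab$table))
  z[, 3] <- 0
  da <- suppressWarnings(differential_abundance(z, md))
  expect_true(da$constant[3])
  expect_equal(da$p[3], 1)
  md$bmi2 <- md$bmi  # exact copy -> collinear design
  expect_error(differential_abundance(z, md,
                                      covariates = c("bmi", "bmi2")),
               "collinear")
})

test_that("fold change follows the arithmetic-mean contract", {
  x <- rbind(c1 = c(0.008, 0.992), c2 = c(0.008, 0.992),
             k1 = c(0.001, 0.999), k2 = c(0.001, 0.999))
  colnames(x) <- c("f1", "f2")
  g <- c("case", "case", "control", "control")
  fc <- fold_change(x, g, pseudocount = 1e-12)
  expect_equal(unname(fc["f1"]), 8, tolerance = 1e-6)
  # identical group means give 1; swapping labels inverts
  swapped <- fold_change(x, rev(g), pseudocount = 1e-12)
  expect_lt(max(abs(fc * swapped - 1)), 1e-12)
  xx <- toy_table(8, 5)
  g8 <- rep(c("case", "control"), 4)
  expect_lt(max(abs(fold_change(xx, g8) *
                      fold_change(xx, ifelse(g8 == "case", "control",
                                             "case")) - 1)), 1e-12)
})

test_that("feature sets partition hits by sign and warn when empty", {
  da <- data.frame(feature_id = c("a", "b", "c"),
                   beta = c(1, -1, 2), q = c(0.01, 0.02, 0.9))
  sets <- define_feature_sets(da, 0.05)
  expect_equal(sets$enriched, "a")
  expect_equal(sets$depleted, "b")
  expect_warning(expect_warning(define_feature_sets(da, 1e-6),
                                "no enriched"), "no depleted")
})

test_that("P/B ratio aggregates genera with pseudocount protection", {
  x <- rbind(s1 = c(0.2, 0.1, 0.1, 0.6), s2 = c(0.3, 0.3, 0.3, 0.1))
  colnames(x) <- c("g__Prevotella|s__P_copri", "g__Prevotella|s__P_sp",
                   "g__Bacteroides|s__B_dorei", "g__Alistipes|s__A_put")
  pb <- pb_ratio(x, pseudocount = 1e-12)
  expect_equal(unname(pb["s1"]), 3, tolerance = 1e-9)
  expect_equal(unname(pb["s2"]), 2, tolerance = 1e-9)
  y <- x[, 1:2]; y <- y / rowSums(y)
  expect_true(all(is.finite(pb_ratio(y))))  # zero Bacteroides, pc > 0
  z <- x[, 4, drop = FALSE]; z <- z / z
  expect_error(pb_ratio(z), "Prevotella")
})

test_that("dysbiosis score matches the direct-formula oracle exactly", {
  set.seed(19)
  x <- toy_table(10, 8, seed = 19)
  colnames(x) <- paste0("f", 1:8)
  en <- c("f1", "f3", "f5"); de <- c("f2", "f8")
  pc <- table_pseudocount(x)
  expect_lt(max(abs(dysbiosis_score(x, en, de) -
                      oracle_di(x, en, de, pc))), 1e-10)
  # antisymmetry; identical sets give zero; 2a vs a gives exactly 1
  expect_equal(dysbiosis_score(x, en, de), -dysbiosis_score(x, de, en))
  expect_equal(unname(dysbiosis_score(x, en, en)), rep(0, 10))
  w <- matrix(rep(c(0.4, 0.4, 0.1, 0.1), 3), 3, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
  expect_equal(unname(dysbiosis_score(w, c("f1", "f2"), c("f3", "f4"),
                                      pseudocount = 1e-15)),
               rep(2, 3), tolerance = 1e-6)
  expect_error(dysbiosis_score(x, character(0), de), "nonempty")
  expect_message(dysbiosis_score(x, c(en, "missing"), de), "skipping")
})

test_that("case-minus-control DI difference tracks planted enrichment", {
  diffs <- sapply(1:8, function(s) {
    cfg <- small_sim(seed = 300 + s)
    md <- simulate_metadata(cfg)
    ab <- simulate_abundance(cfg, md)
    di <- dysbiosis_score(ab$table, ab$truth$enriched_features,
                          ab$truth$depleted_features)
    mean(di[md$cohort == "case"]) - mean(di[md$cohort == "control"])
  })
  expect_true(all(diffs > 0))
})

test_that("replication check counts concordant secondary hits", {
  da <- data.frame(feature_id = paste0("f", 1:6),
                   beta = c(1, -1, 2, -2, 0.5, 1),
                   q = c(0.01, 0.01, 0.2, 0.03, 0.04, 0.8))
  same <- replication_check(da, da, 0.05)
  expect_equal(same$fraction, 1)
  flip <- da; flip$beta <- -flip$beta
  expect_equal(replication_check(da, flip, 0.05)$fraction, 0)
  other <- da; other$feature_id <- paste0("x", 1:6)
  expect_error(replication_check(da, other), "overlap")
})

test_that("two simulated cohorts sharing planted effects replicate", {
  # one generated world split into two independent sample halves: both
  # halves share the planted feature sets but carry independent noise
  cfg <- sim_config(n_cases = 240, n_controls = 240, n_features = 100,
                    n_enriched = 10, n_depleted = 5, effect_log2fc = 1.5,
                    seed = 401)
  md <- simulate_metadata(cfg)
  ab <- simulate_abundance(cfg, md)
  half <- rep(c(TRUE, FALSE), length.out = nrow(md))
  run <- function(keep) {
    differential_abundance(
      inverse_rank_transform(clr_transform(ab$table[keep, ])),
      md[keep, ])
  }
  rc <- replication_check(run(half), run(!half), 0.05)
  expect_gt(rc$n_hits, 0)
  expect_gte(rc$fraction, 0.8)
})
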