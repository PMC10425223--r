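test_that("Jaccard distance matches set arithmetic and ignores joint absences", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 0, 0),
             d = c(0, 0, 1, 1))
  colnames(m) <- paste0("g", 1:4)
  jd <- jaccard_distance_matrix(m)
  expect_equal(jd["a", "b"], 2 / 3)   # intersection 1, union 3
  expect_equal(jd["a", "c"], 0)
  expect_equal(jd["b", "d"], 2 / 3)
  e <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  colnames(e) <- paste0("g", 1:4)
  expect_equal(jaccard_distance_matrix(e)["a", "b"], 1)  # disjoint
  # appending all-absent gene families changes nothing
  m2 <- cbind(m, g5 = 0, g6 = 0)
  expect_equal(jaccard_distance_matrix(m2), jaccard_distance_matrix(m),
               ignore_attr = TRUE)
  bad <- m; bad[1, 1] <- 0.5
  expect_error(jaccard_distance_matrix(bad), "0/1")
})

test_that("cluster_and_cut separates blocks and applies exclusion policy", {
  # two blocks of identical profiles; intersection 1 / union 5 -> d = 0.8
  m <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), 5), 5, byrow = TRUE),
             matrix(rep(c(1, 0, 0, 1, 1, 0), 5), 5, byrow = TRUE))
  dimnames(m) <- list(paste0("s", 1:10), paste0("g", 1:6))
  jd <- jaccard_distance_matrix(m)
  expect_equal(unname(unique(as.vector(jd[1:5, 6:10]))), 0.8)
  cl <- cluster_and_cut(jd, 0.3, min_cluster_size = 2)
  expect_equal(length(cl$sizes), 2)
  truth <- rep(c("x", "y"), each = 5)
  expect_equal(oracle_ari(cl$cluster_labels, truth), 1)
  # cut above the root: one cluster; cut below every merge: all excluded
  expect_equal(length(cluster_and_cut(jd, 0.99, 2)$sizes), 1)
  jd2 <- jd + 0.01; diag(jd2) <- 0  # make all merges strictly positive
  expect_error(cluster_and_cut(jd2, 1e-6, 2), "excluded")
  cl3 <- cluster_and_cut(jd2, 1e-6, 1)
  expect_equal(length(cl3$sizes), 10)  # singletons retained at min size 1
  # merge heights nondecreasing
  expect_true(all(diff(cl$tree$height) >= 0))
})

test_that("planted strain clusters are recovered exactly at cut 0.3", {
  aris <- sapply(1:20, function(s) {
    cfg <- small_sim(seed = 600 + s, n_gene_families = 1000,
                     n_diff_gene_families = 520)
    md <- simulate_metadata(cfg)
    gf <- simulate_gene_families(cfg, md)
    jd <- jaccard_distance_matrix(gf$matrix)
    truth <- gf$truth$true_strain_labels
    within <- max(jd[truth == "case_strain", truth == "case_strain"])
    between <- min(jd[truth == "case_strain", truth == "control_strain"])
    if (within >= 0.15 || between <= 0.5) return(NA_real_)
    cl <- cluster_and_cut(jd, 0.3, min_cluster_size = 5)
    oracle_ari(cl$cluster_labels[names(truth)], truth)
  })
  expect_true(all(!is.na(aris)))  # the stated geometry condition holds
  expect_true(all(aris == 1))
})

test_that("Fisher cluster-cohort enrichment matches full enumeration", {
  mk <- function(tab) {
    labels <- c(rep("cluster1", sum(tab[1, ])), rep("cluster2", sum(tab[2, ])))
    cohorts <- c(rep(c("case", "control"), tab[1, ]),
                 rep(c("case", "control"), tab[2, ]))
    names(labels) <- names(cohorts) <- paste0("s", seq_along(labels))
    cl <- list(cluster_labels = labels)
    cluster_cohort_enrichment(cl, cohorts)
  }
  perfect <- mk(rbind(c(10, 0), c(0, 10)))
  expect_equal(perfect$tests$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(mk(rbind(c(5, 5), c(5, 5)))$tests$p, 1)
  # oracle equality across random small tables
  set.seed(26)
  for (i in 1:25) {
    repeat {
      tab <- matrix(rpois(4, 4) + c(1, 0, 0, 1), 2)
      if (sum(tab) <= 30 && all(rowSums(tab) > 0)) break
    }
    expect_equal(mk(tab)$tests$p, oracle_fisher_p(tab), tolerance = 1e-9)
  }
  # zero margin -> degenerate flag
  one_cohort <- mk(rbind(c(5, 0), c(7, 0)))
  expect_true(one_cohort$tests$degenerate)
  expect_equal(one_cohort$tests$p, 1)
})

test_that("differential gene families: recovery, constants, separation", {
  cfg <- small_sim(seed = 27, gene_flip_rate = 0.08)
  md <- simulate_metadata(cfg)
  gf <- simulate_gene_families(cfg, md)
  jd <- jaccard_distance_matrix(gf$matrix)
  cl <- cluster_and_cut(jd, 0.3, min_cluster_size = 5)
  dg <- differential_gene_families(gf$matrix, cl, md)
  hits <- dg$gene_family[dg$q < 0.05]
  planted <- gf$truth$diff_gene_families
  # precision: recovered hits are overwhelmingly planted
  expect_gte(mean(hits %in% planted), 0.95)
  expect_gte(length(intersect(hits, planted)) / length(planted), 0.8)
  # a gene present everywhere is excluded as constant
  m2 <- gf$matrix; m2[, 1] <- 1
  dg2 <- differential_gene_families(m2, cl, md)
  expect_true(colnames(m2)[1] %in% attr(dg2, "excluded_constant"))
  # flip rate 0 makes every differential gene perfectly separated
  cfg0 <- small_sim(seed = 28, gene_flip_rate = 0, cluster_mixing = 0.1)
  md0 <- simulate_metadata(cfg0)
  gf0 <- simulate_gene_families(cfg0, md0)
  cl0 <- cluster_and_cut(jaccard_distance_matrix(gf0$matrix), 0.3, 5)
  dg0 <- differential_gene_families(gf0$matrix, cl0, md0)
  sep_genes <- dg0$gene_family[dg0$separation]
  expect_gte(mean(gf0$truth$diff_gene_families %in% sep_genes), 0.99)
})

test_that("differential gene families are calibrated under the null", {
  rates <- sapply(1:5, function(s) {
    cfg <- small_sim(seed = 700 + s, n_diff_gene_families = 0,
                     gene_flip_rate = 0.3)
    md <- simulate_metadata(cfg)
    gf <- simulate_gene_families(cfg, md)
    # no structure: split samples arbitrarily in half
    labels <- rep(c("cluster1", "cluster2"), length.out = nrow(gf$matrix))
    names(labels) <- rownames(gf$matrix)
    cl <- list(cluster_labels = labels,
               sizes = table(labels))
    dg <- differential_gene_families(gf$matrix, cl, md)
    mean(dg$q < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(rates), 0.05)
})

test_that("Pfam enrichment matches hypergeometric closed forms", {
  map <- data.frame(gene_family = paste0("g", 1:10),
                    pfam = rep(c("PF1", "PF2"), each = 5))
  # draw 5, category 5, overlap 5 in a universe of 10: p = 1/252
  res <- pfam_enrichment(paste0("g", 1:5), map)
  expect_equal(res$p[res$pfam == "PF1"], 1 / 252, tolerance = 1e-12)
  expect_equal(res$p[res$pfam == "PF1"],
               oracle_hyper_p(5, 5, 5, 10), tolerance = 1e-12)
  # zero overlap is never enriched one-sidedly
  expect_equal(res$p[res$pfam == "PF2"], 1)
  # drawing the whole universe: every Pfam p = 1
  all_in <- pfam_enrichment(paste0("g", 1:10), map)
  expect_true(all(all_in$p == 1))
  expect_warning(empty <- pfam_enrichment(character(0), map), "empty")
  expect_equal(nrow(empty), 0)
  # random-case oracle equality
  set.seed(29)
  map2 <- data.frame(gene_family = paste0("g", 1:30),
                     pfam = sample(c("A", "B", "C"), 30, TRUE))
  hits <- sample(map2$gene_family, 12)
  res2 <- pfam_enrichment(hits, map2)
  for (i in seq_len(nrow(res2)))
    expect_equal(res2$p[i],
                 oracle_hyper_p(res2$k_hits[i], res2$category_size[i],
                                res2$draw_size[i], res2$universe_size[i]),
                 tolerance = 1e-12)
})

test_that("planted Pfam concentration is detected end to end", {
  cfg <- small_sim(seed = 30)
  md <- simulate_metadata(cfg)
  gf <- simulate_gene_families(cfg, md)
  cl <- cluster_and_cut(jaccard_distance_matrix(gf$matrix), 0.3, 5)
  dg <- differential_gene_families(gf$matrix, cl, md)
  hits <- dg$gene_family[dg$q < 0.05]
  enr <- pfam_enrichment(hits, gf$pfam_map)
  top <- enr$pfam[enr$q < 0.05]
  expect_gt(length(intersect(top, gf$truth$hot_pfams)), 0)
  expect_true(all(top %in% gf$truth$hot_pfams))
})

test_that("strain-phenotype association recovers a planted slope", {
  set.seed(31)
  hits <- replicate(10, {
    n <- 120
    labels <- rep(c("cluster1", "cluster2"), each = n / 2)
    names(labels) <- paste0("s", 1:n)
    cl <- list(cluster_labels = labels)
    phen <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(names(labels), paste0("p", 1:3)))
    phen[, 1] <- phen[, 1] + (labels == "cluster1")  # planted cluster shift
    cov_df <- data.frame(age = rnorm(n, 50, 10), row.names = names(labels))
    res <- strain_phenotype_association(cl, phen, cov_df)
    row <- res[res$strain == "cluster1" & res$phenotype_id == "p1", ]
    row$significant && row$beta > 0
  })
  expect_gte(mean(hits), 0.9)
  # null calibration
  set.seed(32)
  fp <- replicate(30, {
    n <- 80
    labels <- rep(c("cluster1", "cluster2"), each = n / 2)
    names(labels) <- paste0("s", 1:n)
    cl <- list(cluster_labels = labels)
    phen <- matrix(rnorm(n * 5), n, 5,
                   dimnames = list(names(labels), paste0("p", 1:5)))
    mean(strain_phenotype_association(cl, phen)$significant)
  })
  expect_lte(mean(fp), 0.1)
})
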