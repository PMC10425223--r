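#' Synthetic case/control metagenomic cohorts with planted ground truth
#'
#' The generator emulates the statistical structure a case/control
#' gut-microbiome analysis assumes: two cohorts sharing a species pool,
#' log-normal compositional abundances with a planted enriched/depleted
#' feature split, a binary gene-family matrix carrying two strain archetypes
#' with cohort-biased membership, and cytokine phenotypes with planted
#' taxon associations plus age/sex confounding. Defaults mirror a cohort of
#' 143 treated cases and 190 matched controls (ages ~51, mostly male, with
#' smoking, BMI, sexual-behavior and read-depth covariates) and a species
#' panel of 123 features of which 57 are enriched and 19 depleted in cases.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_cases,n_controls samples per arm (>= 1).
#' @param n_features number of abundance features (>= 1).
#' @param n_enriched,n_depleted planted case-enriched / case-depleted feature
#'   counts (>= 0; 0 gives a null simulation).
#' @param effect_log2fc log2 fold change planted on the mean abundance of
#'   affected features.
#' @param base_logmean_sd spread of per-feature baseline log-means
#'   (heavy-tailed, t with 3 df scaled by this value).
#' @param overdispersion_sd per-entry log-normal noise sd.
#' @param sparsity fraction of table entries zeroed (smallest entries first).
#' @param n_gene_families,n_diff_gene_families pangenome size and number of
#'   gene families differing between the two strain archetypes.
#' @param gene_flip_rate per-gene Bernoulli flip rate away from a sample's
#'   archetype, in [0, 0.5).
#' @param cluster_mixing probability that a sample carries the other cohort's
#'   typical strain, in [0, 1].
#' @param cytokine_assoc_rho planted partial correlation between target
#'   (feature, cytokine) pairs, |rho| < 1.
#' @param confounder_strength weight of the age/sex confounding terms added
#'   to every cytokine.
#' @param seed integer master seed; every stage derives its stream from it.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_cases = 143, n_controls = 190,
                       n_features = 123, n_enriched = 57, n_depleted = 19,
                       effect_log2fc = 1, base_logmean_sd = 2,
                       overdispersion_sd = 1, sparsity = 0.3,
                       n_gene_families = 4998, n_diff_gene_families = 2821,
                       gene_flip_rate = 0.02, cluster_mixing = 0.16,
                       cytokine_assoc_rho = 0.5, confounder_strength = 0.5,
                       seed = 1) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_features = n_features, n_enriched = n_enriched,
              n_depleted = n_depleted, effect_log2fc = effect_log2fc,
              base_logmean_sd = base_logmean_sd,
              overdispersion_sd = overdispersion_sd, sparsity = sparsity,
              n_gene_families = n_gene_families,
              n_diff_gene_families = n_diff_gene_families,
              gene_flip_rate = gene_flip_rate,
              cluster_mixing = cluster_mixing,
              cytokine_assoc_rho = cytokine_assoc_rho,
              confounder_strength = confounder_strength, seed = seed)
  .check_count <- function(field, min) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v != round(v) || v < min)
      stop("invalid config: ", field, " must be an integer >= ", min,
           call. = FALSE)
  }
  for (f in c("n_cases", "n_controls", "n_features", "n_gene_families"))
    .check_count(f, 1)
  for (f in c("n_enriched", "n_depleted", "n_diff_gene_families"))
    .check_count(f, 0)
  .check_count("seed", 0)
  if (cfg$seed > 2^31 - 1000)
    stop("invalid config: seed too large (must stay below 2^31)",
         call. = FALSE)
  if (cfg$n_enriched + cfg$n_depleted > cfg$n_features)
    stop("invalid config: n_enriched + n_depleted exceeds n_features",
         call. = FALSE)
  if (cfg$n_diff_gene_families > cfg$n_gene_families)
    stop("invalid config: n_diff_gene_families exceeds n_gene_families",
         call. = FALSE)
  .check_real <- function(field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[field]]
    bad <- !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
      (if (lo_open) v <= lo else v < lo) ||
      (if (hi_open) v >= hi else v > hi)
    if (bad) stop("invalid config: ", field, " out of range", call. = FALSE)
  }
  .check_real("gene_flip_rate", 0, 0.5, hi_open = TRUE)
  .check_real("cluster_mixing", 0, 1)
  .check_real("cytokine_assoc_rho", -1, 1, lo_open = TRUE, hi_open = TRUE)
  .check_real("sparsity", 0, 1, hi_open = TRUE)
  .check_real("base_logmean_sd", 0, Inf)
  .check_real("overdispersion_sd", 0, Inf)
  if (!is.numeric(cfg$effect_log2fc) || !is.finite(cfg$effect_log2fc))
    stop("invalid config: effect_log2fc must be finite", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Each module draws from its own stream derived from the master seed, so any
# stage can be regenerated without replaying the ones before it.
.sim_seed <- function(cfg, offset) {
  (cfg$seed + offset) %% (2^31 - 1)
}

#' Simulate per-sample metadata
#'
#' One row per sample with cohort label, demographic and technical covariates
#' (age, sex, BMI, smoking, read count), sexual-behavior variables (MSM
#' status, receptive anal intercourse, partner count) and, for cases only,
#' clinical variables (CD4 count and nadir, cell-associated HIV DNA/RNA).
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with row names = sample ids.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, 101))
  n1 <- config$n_cases; n0 <- config$n_controls
  ids <- c(sprintf("CASE%03d", seq_len(n1)), sprintf("CTRL%03d", seq_len(n0)))
  cohort <- rep(c("case", "control"), c(n1, n0))
  is_case <- cohort == "case"
  age <- ifelse(is_case, stats::rnorm(n1 + n0, 51.5, 10.7),
                stats::rnorm(n1 + n0, 50.7, 11.1))
  sex <- ifelse(stats::runif(n1 + n0) < ifelse(is_case, 130 / 143, 166 / 190),
                "male", "female")
  bmi <- ifelse(is_case, stats::rnorm(n1 + n0, 24.5, 3.5),
                stats::rnorm(n1 + n0, 25.5, 3.14))
  smoking <- stats::rbinom(n1 + n0, 1, ifelse(is_case, 0.28, 0.10))
  msm <- as.integer(sex == "male" &
                      stats::runif(n1 + n0) < ifelse(is_case, 0.67 / (130 / 143),
                                                     0.005))
  rai <- as.integer(is_case & msm == 1 & stats::runif(n1 + n0) < 0.365)
  num_partners <- stats::rnbinom(n1 + n0, size = 1,
                                 mu = ifelse(msm == 1, 3, 0.8))
  read_count <- round(stats::rlnorm(n1 + n0,
                                    meanlog = ifelse(is_case, log(26.8e6),
                                                     log(23.1e6)),
                                    sdlog = 0.25))
  qn <- function(med, lo, hi, n) # log-normal from a median and IQR
    stats::rlnorm(n, meanlog = log(med),
                  sdlog = (log(hi) - log(lo)) / (2 * stats::qnorm(0.75)))
  nn <- n1 + n0
  cd4_count <- ifelse(is_case, qn(650, 465, 810, nn), NA_real_)
  cd4_nadir <- ifelse(is_case, qn(260, 120, 370, nn), NA_real_)
  ca_hiv_dna <- ifelse(is_case, stats::rlnorm(nn, log(150), 1), NA_real_)
  ca_hiv_rna <- ifelse(is_case, stats::rlnorm(nn, log(40), 1), NA_real_)
  out <- data.frame(sample_id = ids, cohort = cohort, age = age, sex = sex,
                    bmi = bmi, smoking = smoking, msm = msm, rai = rai,
                    num_partners = num_partners, read_count = read_count,
                    cd4_count = cd4_count, cd4_nadir = cd4_nadir,
                    ca_hiv_dna = ca_hiv_dna, ca_hiv_rna = ca_hiv_rna,
                    stringsAsFactors = FALSE)
  rownames(out) <- ids
  out
}

.feature_labels <- function(n, style = c("species", "pathway")) {
  style <- match.arg(style)
  if (style == "pathway")
    return(sprintf("PWY-%04d: synthetic_pathway_%d", 6000 + seq_len(n),
                   seq_len(n)))
  genera <- c("Prevotella", "Bacteroides", "Alistipes", "Faecalibacterium",
              "Roseburia", "Blautia", "Megasphaera", "Ruminococcus",
              "Eubacterium", "Akkermansia", "Dialister", "Coprococcus")
  g <- genera[(seq_len(n) - 1) %% length(genera) + 1]
  sprintf("g__%s|s__%s_sp_%03d", g, g, seq_len(n))
}

#' Simulate a relative-abundance table with planted effects
#'
#' Abundances are built as \code{exp(feature log-mean + group shift + noise)};
#' the shift \code{effect_log2fc * ln 2} is added for cases on enriched
#' features and subtracted on depleted ones. The smallest entries (a
#' \code{sparsity} fraction of the table) are zeroed to emulate detection
#' limits, then rows are re-closed to sum to 1.
#'
#' @param config a \code{\link{sim_config}}.
#' @param metadata output of \code{\link{simulate_metadata}} (or any
#'   data.frame with matching \code{sample_id}).
#' @param label_style "species" (lineage-style labels, default) or "pathway".
#' @param seed_offset internal stream offset; change it to draw an
#'   independent table (e.g. a pathway panel) from the same config.
#' @return list with \code{table} (samples x features relative matrix) and
#'   \code{truth} (list with \code{enriched_features},
#'   \code{depleted_features}).
#' @export
simulate_abundance <- function(config, metadata, label_style = "species",
                               seed_offset = 202) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("sample_id", "cohort") %in% names(metadata)))
    stop("metadata must carry sample_id and cohort", call. = FALSE)
  set.seed(.sim_seed(config, seed_offset))
  n <- nrow(metadata); m <- config$n_features
  feats <- .feature_labels(m, label_style)
  mu <- config$base_logmean_sd * stats::rt(m, df = 3)
  idx <- sample.int(m, config$n_enriched + config$n_depleted)
  enriched <- idx[seq_len(config$n_enriched)]
  depleted <- setdiff(idx, enriched)
  shift <- numeric(m)
  shift[enriched] <- config$effect_log2fc * log(2)
  shift[depleted] <- -config$effect_log2fc * log(2)
  is_case <- metadata$cohort == "case"
  logx <- matrix(mu, n, m, byrow = TRUE) +
    outer(as.numeric(is_case), shift) +
    matrix(stats::rnorm(n * m, sd = config$overdispersion_sd), n, m)
  x <- exp(logx)
  if (config$sparsity > 0) {
    thr <- stats::quantile(x, config$sparsity)
    keep_max <- cbind(seq_len(n), max.col(x))  # never empty out a sample
    zero <- x < thr
    zero[keep_max] <- FALSE
    x[zero] <- 0
  }
  dimnames(x) <- list(metadata$sample_id, feats)
  x <- close_rows(x)
  list(table = x,
       truth = list(enriched_features = feats[enriched],
                    depleted_features = feats[depleted]))
}

#' Simulate a binary gene-family matrix with two strain archetypes
#'
#' Two archetype profiles differ at \code{n_diff_gene_families} positions;
#' each sample receives its cohort's typical archetype (switched with
#' probability \code{cluster_mixing}) and every gene is flipped independently
#' with probability \code{gene_flip_rate}. A Pfam annotation map is generated
#' with the differential genes concentrated in a small set of "hot" Pfams.
#'
#' @param config a \code{\link{sim_config}}.
#' @param metadata output of \code{\link{simulate_metadata}}.
#' @return list with \code{matrix} (samples x gene families, 0/1),
#'   \code{pfam_map} (data.frame gene_family / pfam) and \code{truth}
#'   (true strain label per sample, differential gene ids, hot Pfams).
#' @export
simulate_gene_families <- function(config, metadata) {
  stopifnot(inherits(config, "sim_config"))
  if (config$gene_flip_rate < 0 || config$gene_flip_rate >= 0.5)
    stop("gene_flip_rate must lie in [0, 0.5)", call. = FALSE)
  set.seed(.sim_seed(config, 303))
  n <- nrow(metadata); g <- config$n_gene_families
  genes <- sprintf("GF%05d", seq_len(g))
  arch_control <- stats::rbinom(g, 1, 0.7)
  diff_idx <- sort(sample.int(g, config$n_diff_gene_families))
  arch_case <- arch_control
  arch_case[diff_idx] <- 1 - arch_case[diff_idx]
  is_case <- metadata$cohort == "case"
  switched <- stats::runif(n) < config$cluster_mixing
  strain <- ifelse(xor(is_case, switched), "case_strain", "control_strain")
  base <- rbind(case_strain = arch_case, control_strain = arch_control)
  prof <- base[strain, , drop = FALSE]
  flips <- matrix(stats::runif(n * g) < config$gene_flip_rate, n, g)
  m <- abs(prof - flips * 1)
  dimnames(m) <- list(metadata$sample_id, genes)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping sample(s) with no gene families present: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
    strain <- strain[!empty]
  }
  n_pfam <- 40
  pfams <- sprintf("PFSYN%03d", seq_len(n_pfam))
  hot <- pfams[1:7]
  assign <- character(g)
  is_diff <- seq_len(g) %in% diff_idx
  take_hot <- is_diff & stats::runif(g) < 0.6
  assign[take_hot] <- sample(hot, sum(take_hot), replace = TRUE)
  assign[!take_hot] <- sample(pfams, sum(!take_hot), replace = TRUE)
  list(matrix = m,
       pfam_map = data.frame(gene_family = genes, pfam = assign,
                             stringsAsFactors = FALSE),
       truth = list(true_strain_labels = stats::setNames(strain, rownames(m)),
                    diff_gene_families = genes[diff_idx],
                    hot_pfams = hot))
}

#' Simulate cytokine production phenotypes
#'
#' Builds an 8-cytokine x 3-stimulus panel of positive measurements. Target
#' phenotypes receive \code{sign * rho * INT(feature)} plus scaled noise so
#' the planted partial correlation given age and sex is approximately
#' \code{cytokine_assoc_rho}; every phenotype (target or not) receives
#' age/sex confounding with weight \code{confounder_strength}. Values are
#' exponentiated so they resemble concentrations.
#'
#' @param config a \code{\link{sim_config}}.
#' @param metadata output of \code{\link{simulate_metadata}}.
#' @param table abundance matrix aligned with \code{metadata} (row names
#'   must equal \code{metadata$sample_id}).
#' @param target_features feature ids to plant associations on; default the
#'   two highest-prevalence features of \code{table} (a near-absent target
#'   cannot carry a rank correlation). Signs alternate -1, +1, ...
#' @return list with \code{cytokines} (samples x phenotypes positive matrix)
#'   and \code{truth} (data.frame feature / phenotype / sign / rho).
#' @export
simulate_cytokines <- function(config, metadata, table,
                               target_features = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(target_features))
    target_features <- colnames(table)[order(-colMeans(table > 0),
                                             -colMeans(table))[1:2]]
  if (!identical(rownames(table), metadata$sample_id))
    stop("abundance table is not aligned with metadata", call. = FALSE)
  rho <- config$cytokine_assoc_rho
  if (abs(rho) >= 1) stop("cytokine_assoc_rho must satisfy |rho| < 1",
                          call. = FALSE)
  set.seed(.sim_seed(config, 404))
  cyt <- c("IL1b", "IL6", "IL10", "TNF", "IFNy", "IL17", "IL22", "IL1Ra")
  stim <- c("Pam3Cys", "LPS", "C.albicans")
  phen <- as.vector(outer(cyt, stim, function(a, b) paste(b, a, sep = "_")))
  n <- nrow(metadata)
  conf <- config$confounder_strength *
    (as.numeric(scale(metadata$age)) + (metadata$sex == "male"))
  y <- matrix(stats::rnorm(n * length(phen)), n, length(phen),
              dimnames = list(metadata$sample_id, phen)) + conf
  target_features <- target_features[!is.na(target_features)]
  truth <- data.frame(feature = character(0), phenotype = character(0),
                      sign = numeric(0), rho = numeric(0))
  if (length(target_features) > 0 && rho != 0) {
    tp <- phen[seq_along(target_features)]
    sg <- rep(c(-1, 1), length.out = length(target_features))
    for (i in seq_along(target_features)) {
      z <- inverse_rank_transform(table[, target_features[i]])
      y[, tp[i]] <- sg[i] * rho * z +
        sqrt(1 - rho^2) * stats::rnorm(n) + conf
    }
    truth <- data.frame(feature = target_features, phenotype = tp,
                        sign = sg, rho = rho, stringsAsFactors = FALSE)
  }
  list(cytokines = exp(y), truth = truth)
}

#' Simulate a complete cohort bundle
#'
#' Convenience wrapper running every generator off one config: metadata, a
#' species panel, an independent pathway panel (87 enriched / 76 depleted
#' of 331 features by default, scaled proportionally for smaller configs),
#' the strain gene-family matrix, and cytokines targeted at the first two
#' planted enriched species.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{metadata}, \code{species}, \code{pathways},
#'   \code{genes}, \code{cytokines}, \code{truth} (per component).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  meta <- simulate_metadata(config)
  sp <- simulate_abundance(config, meta, "species", seed_offset = 202)
  scale_f <- config$n_features / 123
  pw_cfg <- config
  pw_cfg$n_features <- max(2, round(331 * scale_f))
  pw_cfg$n_enriched <- min(round(87 * scale_f),
                           if (config$n_enriched > 0) pw_cfg$n_features else 0)
  pw_cfg$n_depleted <- min(round(76 * scale_f),
                           pw_cfg$n_features - pw_cfg$n_enriched)
  if (config$n_enriched == 0) pw_cfg$n_enriched <- 0
  if (config$n_depleted == 0) pw_cfg$n_depleted <- 0
  pw <- simulate_abundance(pw_cfg, meta, "pathway", seed_offset = 505)
  gf <- simulate_gene_families(config, meta)
  cand <- sp$truth$enriched_features
  if (length(cand) < 2) cand <- colnames(sp$table)
  targets <- cand[order(-colMeans(sp$table[, cand, drop = FALSE] > 0),
                        -colMeans(sp$table[, cand, drop = FALSE]))[1:2]]
  ck <- simulate_cytokines(config, meta, sp$table, targets)
  list(metadata = meta, species = sp$table, pathways = pw$table,
       genes = gf$matrix, pfam_map = gf$pfam_map, cytokines = ck$cytokines,
       truth = list(species = sp$truth, pathways = pw$truth,
                    strains = gf$truth, cytokines = ck$truth))
}
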