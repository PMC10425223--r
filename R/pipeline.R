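#' End-to-end pipeline configuration
#'
#' Bundles either input file paths (abundance tables, gene matrix, metadata,
#' Pfam map) or a simulation block, together with the per-stage thresholds
#' and the master seed. Defaults follow the analysis conventions: prevalence
#' 0.2 (mode "any"), differential-abundance FDR 0.05, association FDR 0.1,
#' cytokine FDR 0.05, strain tree cut 0.3, minimum cluster size 20, 9999
#' permutations.
#'
#' @param simulation a \code{\link{sim_config}} (used when no input paths
#'   are given).
#' @param species_path,pathway_path,gene_path,metadata_path,pfam_path,cytokine_path
#'   optional TSV input paths replacing the simulation block.
#' @param group_var metadata column holding the cohort label.
#' @param da_covariates,assoc_covariates,cytokine_covariates,strain_covariates
#'   covariate column names per stage.
#' @param prevalence_threshold,prevalence_mode prevalence filter settings.
#' @param da_fdr,assoc_fdr,cytokine_fdr,strain_fdr FDR thresholds in (0, 1].
#' @param cut_height,min_cluster_size strain clustering settings.
#' @param n_permutations PERMANOVA permutations.
#' @param seed integer master seed (mandatory; flows into the simulation
#'   block when one is used).
#' @param out_dir output directory.
#' @return validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(simulation = sim_config(seed = seed),
                            species_path = NULL, pathway_path = NULL,
                            gene_path = NULL, metadata_path = NULL,
                            pfam_path = NULL, cytokine_path = NULL,
                            group_var = "cohort",
                            da_covariates = c("bmi", "smoking",
                                              "read_count"),
                            assoc_covariates = c("age", "sex",
                                                 "read_count"),
                            cytokine_covariates = c("age", "sex"),
                            strain_covariates = c("age", "sex",
                                                  "read_count"),
                            prevalence_threshold = 0.2,
                            prevalence_mode = "any",
                            da_fdr = 0.05, assoc_fdr = 0.1,
                            cytokine_fdr = 0.05, strain_fdr = 0.1,
                            cut_height = 0.3, min_cluster_size = 20,
                            n_permutations = 9999, seed = 1,
                            out_dir = tempfile("dysbiome_run_")) {
  cfg <- as.list(environment())
  for (f in c("prevalence_threshold", "da_fdr", "assoc_fdr", "cytokine_fdr",
              "strain_fdr", "cut_height")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1)
      stop("invalid config: ", f, " must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(seed) || seed != round(seed) || seed < 0)
    stop("invalid config: seed must be a nonnegative integer", call. = FALSE)
  if (n_permutations < 99)
    stop("invalid config: n_permutations must be >= 99", call. = FALSE)
  if (!prevalence_mode %in% c("any", "all"))
    stop("invalid config: prevalence_mode must be 'any' or 'all'",
         call. = FALSE)
  if (!is.null(cfg$simulation) && !inherits(cfg$simulation, "sim_config"))
    stop("invalid config: simulation must be a sim_config", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(config) {
  plain <- lapply(unclass(config), function(v)
    if (inherits(v, "sim_config")) unclass(v) else v)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> transform -> diversity -> differential
#' abundance -> scores -> associations -> strain typing, writing every stage
#' result as TSV with a provenance header, a JSON copy of the effective
#' config, a run log and a plain-text summary. A stage failure aborts its
#' downstream dependents; independent stages still run.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages subset of stages to run (dependencies are not re-run; their
#'   in-memory results must come from a full run). Default: all.
#' @return (invisibly) list with the in-memory stage results, the summary
#'   lines, and \code{failures} (named character vector of stage errors,
#'   empty on success).
#' @export
run_pipeline <- function(config,
                         stages = c("data", "transform", "diversity", "da",
                                    "scores", "assoc", "strain")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logmsg <- function(...) {
    line <- paste0(...)
    writeLines(line, log_con)
    message(line)
  }
  res <- list()
  failures <- character(0)
  summary_lines <- character(0)
  note <- function(...) summary_lines <<- c(summary_lines, paste0(...))
  run_stage <- function(name, deps, fun) {
    if (!name %in% stages) return(invisible(NULL))
    if (any(deps %in% names(failures))) {
      failures[name] <<- paste("skipped: upstream failure in",
                               paste(intersect(deps, names(failures)),
                                     collapse = ", "))
      logmsg("[", name, "] ", failures[name])
      return(invisible(NULL))
    }
    logmsg("[", name, "] running")
    out <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        writeLines(paste0("[", name, "] warning: ",
                          conditionMessage(w)), log_con)
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        failures[name] <<- conditionMessage(e)
        logmsg("[", name, "] FAILED: ", conditionMessage(e))
        NULL
      })
    if (!is.null(out)) res[[name]] <<- out
    invisible(NULL)
  }
  od <- function(f) file.path(config$out_dir, f)
  jsonlite::write_json(lapply(unclass(config), function(v)
    if (inherits(v, "sim_config")) unclass(v) else v),
    od("effective_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)

  run_stage("data", character(0), function() {
    if (is.null(config$species_path)) {
      sim <- simulate_cohort(config$simulation)
      write_metadata(sim$metadata, od("metadata.tsv"))
      write_abundance(sim$species, od("species.tsv"),
                      seed = config$seed, config_hash = hash)
      write_abundance(sim$pathways, od("pathways.tsv"),
                      seed = config$seed, config_hash = hash)
      write_gene_matrix(sim$genes, od("gene_families.tsv"),
                        seed = config$seed, config_hash = hash)
      write_result(sim$pfam_map, od("pfam_map.tsv"), "pfam_map")
      write_result(data.frame(sample_id = rownames(sim$cytokines),
                              sim$cytokines, check.names = FALSE),
                   od("cytokines.tsv"), "cytokines")
      sim
    } else {
      meta <- read_metadata(config$metadata_path)
      cyt <- NULL
      if (!is.null(config$cytokine_path)) {
        cdf <- read_metadata(config$cytokine_path)
        cyt <- as.matrix(cdf[, setdiff(names(cdf), "sample_id"),
                             drop = FALSE])
      }
      list(metadata = meta,
           species = read_abundance(config$species_path),
           pathways = if (!is.null(config$pathway_path))
             read_abundance(config$pathway_path),
           genes = if (!is.null(config$gene_path))
             read_gene_matrix(config$gene_path, binarize = TRUE),
           pfam_map = if (!is.null(config$pfam_path))
             utils::read.delim(config$pfam_path, comment.char = "#",
                               stringsAsFactors = FALSE),
           cytokines = cyt, truth = NULL)
    }
  })

  transform_one <- function(x, meta) {
    cohorts <- meta[[config$group_var]][match(rownames(x),
                                              meta$sample_id)]
    kept <- prevalence_filter(x, cohorts, config$prevalence_threshold,
                              config$prevalence_mode)
    z <- clr_transform(x)[, colnames(kept), drop = FALSE]
    attr(z, "transform") <- "CLR"
    inverse_rank_transform(z)
  }
  run_stage("transform", "data", function() {
    d <- res$data
    sp <- transform_one(d$species, d$metadata)
    pw <- if (!is.null(d$pathways)) transform_one(d$pathways, d$metadata)
    .write_matrix_tsv(sp, od("species_clr_int.tsv"), "sample_id",
                      "transform:CLR+INT", config$seed, hash)
    if (!is.null(pw))
      .write_matrix_tsv(pw, od("pathways_clr_int.tsv"), "sample_id",
                        "transform:CLR+INT", config$seed, hash)
    list(species = sp, pathways = pw)
  })

  run_stage("diversity", "data", function() {
    d <- res$data
    g <- d$metadata[[config$group_var]]
    sh <- shannon_index(d$species)
    bc <- bray_curtis(d$species)
    pc <- pcoa(bc, k = 2)
    cov_df <- d$metadata[, intersect(config$da_covariates,
                                     names(d$metadata)), drop = FALSE]
    pm <- permanova(bc, g, covariates = cov_df,
                    n_perm = config$n_permutations, seed = config$seed)
    wt <- wilcoxon_rank_sum(sh, g)
    write_result(data.frame(sample_id = names(sh), shannon = sh),
                 od("shannon.tsv"), "diversity", config$seed, hash)
    .write_matrix_tsv(bc, od("bray_curtis.tsv"), "sample_id", "diversity",
                      config$seed, hash)
    write_result(data.frame(sample_id = rownames(pc$coordinates),
                            pc$coordinates,
                            check.names = FALSE),
                 od("pcoa.tsv"), "diversity", config$seed, hash)
    write_result(as.data.frame(pm), od("permanova.tsv"), "diversity",
                 config$seed, hash)
    note("shannon case-vs-control wilcoxon p: ", format(wt$p, digits = 3))
    note("permanova group R2: ",
         format(pm$r_squared[pm$term == "group"], digits = 3),
         " (p = ", format(pm$p[pm$term == "group"], digits = 3), ")")
    list(shannon = sh, bray_curtis = bc, pcoa = pc, permanova = pm,
         shannon_test = wt)
  })

  run_stage("da", c("data", "transform"), function() {
    d <- res$data
    meta <- d$metadata
    g <- meta[[config$group_var]]
    one <- function(z, raw, label) {
      da <- differential_abundance(z, meta, config$group_var,
                                   config$da_covariates)
      fc <- fold_change(raw[, da$feature_id, drop = FALSE], g)
      da$fold_change <- unname(fc)
      da$log2_fold_change <- log2(da$fold_change)
      sets <- suppressWarnings(define_feature_sets(da, config$da_fdr))
      write_result(da, od(paste0("da_", label, ".tsv")), "da",
                   config$seed, hash)
      write_result(data.frame(
        feature_id = c(sets$enriched, sets$depleted),
        direction = rep(c("enriched", "depleted"),
                        c(length(sets$enriched), length(sets$depleted)))),
        od(paste0("feature_sets_", label, ".tsv")), "da", config$seed, hash)
      note(label, ": ", sum(da$q < config$da_fdr, na.rm = TRUE),
           " differential of ", nrow(da), " (",
           length(sets$enriched), " enriched, ",
           length(sets$depleted), " depleted)")
      list(da = da, sets = sets)
    }
    out <- list(species = one(res$transform$species, d$species, "species"))
    if (!is.null(res$transform$pathways))
      out$pathways <- one(res$transform$pathways, d$pathways, "pathways")
    out
  })

  run_stage("scores", c("data", "da"), function() {
    d <- res$data
    sets <- res$da$species$sets
    panel <- data.frame(sample_id = rownames(d$species),
                        shannon = shannon_index(d$species),
                        pb_ratio = tryCatch(pb_ratio(d$species),
                                            error = function(e) NA_real_))
    if (length(sets$enriched) > 0 && length(sets$depleted) > 0)
      panel$di_score <- dysbiosis_score(d$species, sets$enriched,
                                        sets$depleted)
    if (!is.null(res$da$pathways)) {
      ps <- res$da$pathways$sets
      if (length(ps$enriched) > 0 && length(ps$depleted) > 0)
        panel$fi_score <- dysbiosis_score(d$pathways, ps$enriched,
                                          ps$depleted)
    }
    write_result(panel, od("score_panel.tsv"), "scores", config$seed, hash)
    if (!is.null(panel$di_score)) {
      g <- d$metadata[[config$group_var]]
      wt <- wilcoxon_rank_sum(panel$di_score, g)
      note("DI score case-vs-control wilcoxon p: ",
           format(wt$p, digits = 3))
    }
    panel
  })

  run_stage("assoc", c("data", "scores"), function() {
    d <- res$data
    if (is.null(d$cytokines)) {
      note("assoc: no cytokine data; skipped")
      return(list())
    }
    meta <- d$metadata
    cov_df <- meta[, intersect(config$assoc_covariates, names(meta)),
                   drop = FALSE]
    feats <- as.matrix(res$scores[, setdiff(names(res$scores),
                                            "sample_id"), drop = FALSE])
    rownames(feats) <- res$scores$sample_id
    scan <- association_scan(feats, d$cytokines, cov_df, config$assoc_fdr)
    write_result(scan, od("associations.tsv"), "assoc", config$seed, hash)
    cg <- cytokine_group_comparison(
      d$cytokines, meta[[config$group_var]],
      meta[, intersect(config$cytokine_covariates, names(meta)),
           drop = FALSE],
      config$cytokine_fdr)
    write_result(cg, od("cytokine_group_comparison.tsv"), "assoc",
                 config$seed, hash)
    note("associations at FDR < ", config$assoc_fdr, ": ",
         sum(scan$significant), " of ", nrow(scan))
    note("cytokines different between groups at FDR < ",
         config$cytokine_fdr, ": ", sum(cg$significant))
    list(scan = scan, cytokine_comparison = cg)
  })

  run_stage("strain", "data", function() {
    d <- res$data
    if (is.null(d$genes)) {
      note("strain: no gene-family matrix; skipped")
      return(list())
    }
    jd <- jaccard_distance_matrix(d$genes)
    cl <- cluster_and_cut(jd, config$cut_height, config$min_cluster_size)
    coh <- stats::setNames(d$metadata[[config$group_var]],
                           d$metadata$sample_id)
    enr <- cluster_cohort_enrichment(cl, coh)
    dg <- differential_gene_families(
      d$genes, cl, d$metadata,
      intersect(config$strain_covariates, names(d$metadata)))
    hits <- dg$gene_family[!is.na(dg$q) & dg$q < config$da_fdr]
    pf <- if (!is.null(d$pfam_map))
      suppressWarnings(pfam_enrichment(hits, d$pfam_map,
                                       universe = colnames(d$genes)))
    spa <- NULL
    if (!is.null(d$cytokines)) {
      cov_df <- d$metadata[, intersect(config$strain_covariates,
                                       names(d$metadata)), drop = FALSE]
      rownames(cov_df) <- d$metadata$sample_id
      spa <- suppressWarnings(strain_phenotype_association(
        cl, d$cytokines, cov_df, fdr_threshold = config$strain_fdr))
      write_result(spa, od("strain_phenotype.tsv"), "strain",
                   config$seed, hash)
    }
    write_result(data.frame(sample_id = names(cl$cluster_labels),
                            cluster = cl$cluster_labels),
                 od("strain_clusters.tsv"), "strain", config$seed, hash)
    write_result(data.frame(merge_height = cl$tree$height),
                 od("strain_tree_heights.tsv"), "strain", config$seed, hash)
    write_result(dg, od("differential_gene_families.tsv"), "strain",
                 config$seed, hash)
    if (!is.null(pf))
      write_result(pf, od("pfam_enrichment.tsv"), "strain", config$seed,
                   hash)
    note("strain clusters: ", paste(names(cl$sizes), cl$sizes,
                                    sep = "=", collapse = ", "),
         "; excluded ", length(cl$excluded_samples))
    note("differential gene families at FDR < ", config$da_fdr, ": ",
         length(hits), " of ", nrow(dg))
    list(distance = jd, clustering = cl, enrichment = enr,
         diff_genes = dg, pfam = pf, phenotype = spa)
  })

  if (length(failures) > 0)
    note("FAILED stages: ", paste(names(failures), collapse = ", "))
  writeLines(c(paste0("# dysbiome pipeline summary (seed ", config$seed,
                      ", config ", hash, ")"), summary_lines),
             od("summary.txt"))
  invisible(c(res, list(summary = summary_lines, failures = failures)))
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{transform}, \code{diversity},
#' \code{da}, \code{scores}, \code{assoc}, \code{strain}, \code{all}. Flags:
#' \code{--config=<json>}, \code{--seed=<int>}, \code{--out=<dir>}. Flag
#' values override the config file. A JSON config may carry any
#' \code{\link{pipeline_config}} field; a \code{simulation} sub-object is
#' passed to \code{\link{sim_config}}.
#'
#' @param args character vector (default: the command line).
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- if (length(args) >= 1 && !startsWith(args[1], "--")) args[1]
         else "all"
  flags <- args[startsWith(args, "--")]
  getflag <- function(name) {
    hit <- grep(paste0("^--", name, "="), flags, value = TRUE)
    if (length(hit) == 0) NULL else sub(paste0("^--", name, "="), "",
                                        hit[1])
  }
  cfg_args <- list()
  cfg_file <- getflag("config")
  if (!is.null(cfg_file)) {
    raw <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
    if (!is.null(raw$simulation)) {
      raw$simulation <- do.call(sim_config, as.list(raw$simulation))
    }
    cfg_args <- raw
  }
  if (!is.null(getflag("seed"))) {
    cfg_args$seed <- as.integer(getflag("seed"))
    if (!is.null(cfg_args$simulation))
      cfg_args$simulation$seed <- cfg_args$seed
  }
  if (!is.null(getflag("out"))) cfg_args$out_dir <- getflag("out")
  config <- do.call(pipeline_config, cfg_args)
  stage_map <- list(simulate = "data",
                    transform = c("data", "transform"),
                    diversity = c("data", "diversity"),
                    da = c("data", "transform", "da"),
                    scores = c("data", "transform", "da", "scores"),
                    assoc = c("data", "transform", "da", "scores", "assoc"),
                    strain = c("data", "strain"),
                    all = c("data", "transform", "diversity", "da",
                            "scores", "assoc", "strain"))
  if (!sub %in% names(stage_map))
    stop("unknown subcommand: ", sub, " (expected one of ",
         paste(names(stage_map), collapse = ", "), ")", call. = FALSE)
  out <- run_pipeline(config, stages = stage_map[[sub]])
  status <- if (length(out$failures) > 0) 1L else 0L
  invisible(status)
}
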