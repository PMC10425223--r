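#' Strain typing from gene-family presence/absence profiles
#'
#' @name strain_typing
NULL

.check_binary <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || !all(m %in% c(0, 1)))
    stop("gene-family matrix must be numeric 0/1 (samples in rows)",
         call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("gene-family matrix needs sample row names and gene column names",
         call. = FALSE)
  invisible(m)
}

#' Jaccard distance between binary gene-repertoire profiles
#'
#' \eqn{d(a, b) = 1 - |a \cap b| / |a \cup b|} over present genes; joint
#' absences are ignored. All-absent samples are dropped with a warning.
#'
#' @param m samples x gene-families 0/1 matrix.
#' @return symmetric distance matrix with attribute \code{metric="jaccard"}.
#' @export
jaccard_distance_matrix <- function(m) {
  .check_binary(m)
  if (nrow(m) < 2) stop("need >= 2 samples", call. = FALSE)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping all-absent sample(s): ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  inter <- m %*% t(m)
  r <- rowSums(m)
  uni <- outer(r, r, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  attr(d, "metric") <- "jaccard"
  d
}

#' Complete-linkage strain clustering with a height cut
#'
#' Agglomerates the distance matrix with complete linkage, cuts the tree at
#' \code{cut_height}, and moves clusters smaller than
#' \code{min_cluster_size} to an excluded-sample list. Retained clusters are
#' renumbered by decreasing size ("cluster1" largest).
#'
#' @param d square symmetric distance matrix (e.g.
#'   \code{\link{jaccard_distance_matrix}}).
#' @param cut_height tree height at which to cut (default 0.3).
#' @param min_cluster_size clusters below this size are excluded
#'   (default 20).
#' @return object of class \code{"strain_clustering"}: \code{tree} (hclust),
#'   \code{cut_height}, \code{cluster_labels} (named character, retained
#'   samples only), \code{excluded_samples}, \code{sizes}.
#' @export
cluster_and_cut <- function(d, cut_height = 0.3, min_cluster_size = 20) {
  .check_distance(d)
  if (!is.numeric(cut_height) || cut_height <= 0)
    stop("cut_height must be positive", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep_ids <- names(sizes)[sizes >= min_cluster_size]
  if (length(keep_ids) == 0)
    stop("all samples excluded: largest cluster has ", max(sizes),
         " sample(s), below min_cluster_size = ", min_cluster_size,
         call. = FALSE)
  keep_ids <- keep_ids[order(-sizes[keep_ids])]
  labels <- rep(NA_character_, length(raw))
  for (i in seq_along(keep_ids))
    labels[raw == as.integer(keep_ids[i])] <- paste0("cluster", i)
  names(labels) <- names(raw)
  excluded <- names(raw)[is.na(labels)]
  structure(list(tree = hc, cut_height = cut_height,
                 cluster_labels = labels[!is.na(labels)],
                 excluded_samples = excluded,
                 sizes = table(labels[!is.na(labels)])),
            class = "strain_clustering")
}

#' @export
print.strain_clustering <- function(x, ...) {
  cat("Strain clustering (complete linkage, cut at", x$cut_height, ")\n")
  print(x$sizes)
  if (length(x$excluded_samples) > 0)
    cat(length(x$excluded_samples), "sample(s) excluded (small clusters)\n")
  invisible(x)
}

#' Cluster-by-cohort enrichment (Fisher exact)
#'
#' With two retained clusters, one exact two-sided Fisher test on the 2 x 2
#' cluster-by-cohort table. With more, each cluster is tested against the
#' rest and BH-corrected. A zero margin gives p = 1 with a flag.
#'
#' @param clustering a \code{\link{cluster_and_cut}} result.
#' @param cohorts named cohort label per sample (names = sample ids), or an
#'   unnamed vector aligned with the clustering's retained samples.
#' @return list: \code{contingency} (clusters x cohorts), \code{tests}
#'   (data.frame cluster, p, q, degenerate).
#' @export
cluster_cohort_enrichment <- function(clustering, cohorts) {
  lab <- clustering$cluster_labels
  if (!is.null(names(cohorts))) cohorts <- cohorts[names(lab)]
  if (length(cohorts) != length(lab))
    stop("cohorts must cover every retained sample", call. = FALSE)
  if (length(unique(lab)) < 2)
    stop("need >= 2 retained clusters", call. = FALSE)
  tab <- table(cluster = lab, cohort = as.character(cohorts))
  cl <- rownames(tab)
  tests <- lapply(cl, function(cc) {
    two <- rbind(tab[cc, ], colSums(tab[rownames(tab) != cc, , drop = FALSE]))
    if (ncol(tab) < 2 || any(rowSums(two) == 0) || any(colSums(two) == 0))
      return(data.frame(cluster = cc, p = 1, degenerate = TRUE))
    data.frame(cluster = cc, p = min(1, stats::fisher.test(two)$p.value),
               degenerate = FALSE)
  })
  tests <- do.call(rbind, tests)
  if (length(cl) == 2) tests <- tests[1, , drop = FALSE]  # one 2x2 test
  tests$q <- bh_fdr(tests$p)
  rownames(tests) <- NULL
  list(contingency = tab, tests = tests[, c("cluster", "p", "q",
                                            "degenerate")])
}

#' Differential gene families between two strain clusters
#'
#' Per gene family, logistic regression of presence on the cluster indicator
#' plus covariates, Wald p, BH across gene families. Gene families constant
#' across the analyzed samples are excluded and listed. Perfect separation
#' is detected and assigned a Fisher-exact fallback p with a flag.
#'
#' @param m samples x gene-families 0/1 matrix.
#' @param clustering a \code{\link{cluster_and_cut}} result; exactly two
#'   retained clusters are compared (pick with \code{clusters}).
#' @param metadata optional data.frame carrying the covariate columns
#'   (matched by sample id).
#' @param covariates covariate column names in \code{metadata}; default
#'   \code{c("age", "sex", "read_count")} (ignored when metadata is NULL).
#' @param clusters length-2 cluster labels to compare; default the two
#'   largest.
#' @return data.frame: gene_family, beta (second cluster vs first), se, p,
#'   q, separation; excluded constant genes in attribute
#'   \code{"excluded_constant"}.
#' @export
differential_gene_families <- function(m, clustering, metadata = NULL,
                                       covariates = c("age", "sex",
                                                      "read_count"),
                                       clusters = NULL) {
  .check_binary(m)
  lab <- clustering$cluster_labels
  if (is.null(clusters)) clusters <- names(sort(clustering$sizes,
                                                decreasing = TRUE))[1:2]
  if (length(clusters) != 2) stop("pick exactly two clusters", call. = FALSE)
  use <- names(lab)[lab %in% clusters]
  use <- intersect(use, rownames(m))
  g <- factor(lab[use], levels = clusters)
  mm <- m[use, , drop = FALSE]
  cov_df <- NULL
  if (!is.null(metadata) && length(covariates) > 0) {
    md <- .align_metadata(metadata, use)
    cov_df <- md[, covariates, drop = FALSE]
  }
  X <- if (is.null(cov_df)) stats::model.matrix(~ g)
       else stats::model.matrix(~ g + ., data = cbind(g = g, cov_df))
  const <- colnames(mm)[apply(mm, 2, function(v) length(unique(v)) == 1)]
  genes <- setdiff(colnames(mm), const)
  res <- lapply(genes, function(gf) {
    y <- mm[, gf]
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    beta <- fit$coefficients[2]
    se <- tryCatch(
      sqrt(chol2inv(chol(crossprod(sqrt(fit$weights) * X)))[2, 2]),
      error = function(e) NA_real_)
    if (sep || !is.finite(beta) || !is.finite(se) || se > 50) {
      p <- stats::fisher.test(table(factor(y, levels = 0:1), g))$p.value
      sep <- TRUE
    } else {
      p <- 2 * stats::pnorm(-abs(beta / se))
    }
    data.frame(gene_family = gf, beta = unname(beta), se = unname(se),
               p = p, separation = sep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out <- out[, c("gene_family", "beta", "se", "p", "q", "separation")]
  attr(out, "excluded_constant") <- const
  out
}

#' Pfam over-representation of a gene-family hit set
#'
#' One-sided hypergeometric over-representation test per Pfam:
#' \eqn{P(X \ge k)} with the universe the annotated gene families of the
#' analyzed matrix; BH across Pfams.
#'
#' @param hits character vector of gene-family ids (e.g. significant
#'   differential genes).
#' @param pfam_map data.frame with columns \code{gene_family}, \code{pfam}.
#' @param universe optional gene-family ids limiting the universe (e.g. the
#'   columns of the analyzed matrix); default all annotated genes in the map.
#' @return data.frame: pfam, k_hits, category_size, draw_size,
#'   universe_size, p, q.
#' @export
pfam_enrichment <- function(hits, pfam_map, universe = NULL) {
  if (!all(c("gene_family", "pfam") %in% names(pfam_map)))
    stop("pfam_map needs columns gene_family and pfam", call. = FALSE)
  map <- pfam_map[!is.na(pfam_map$pfam) & pfam_map$pfam != "", ]
  if (!is.null(universe)) map <- map[map$gene_family %in% universe, ]
  uni <- unique(map$gene_family)
  hits <- intersect(unique(hits), uni)
  if (length(hits) == 0) {
    warning("empty hit set after matching to the annotated universe")
    return(data.frame(pfam = character(0), k_hits = integer(0),
                      category_size = integer(0), draw_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      q = numeric(0)))
  }
  N <- length(uni); n_draw <- length(hits)
  per <- split(map$gene_family, map$pfam)
  out <- do.call(rbind, lapply(names(per), function(pf) {
    cat_genes <- unique(per[[pf]])
    k <- length(intersect(cat_genes, hits))
    K <- length(cat_genes)
    data.frame(pfam = pf, k_hits = k, category_size = K,
               draw_size = n_draw, universe_size = N,
               p = stats::phyper(k - 1, K, N - K, n_draw,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out$q <- bh_fdr(out$p)
  out[order(out$p), ]
}

#' Strain-phenotype association
#'
#' Least squares of the inverse-rank-transformed phenotype on a strain
#' exposure plus covariates, BH-corrected across the (strain, phenotype)
#' block. Two exposure encodings are supported: \code{"indicator"} (1 for
#' samples in the strain, 0 for samples in the other retained clusters) and
#' \code{"abundance"} (a per-sample abundance restricted to the strain's
#' carriers). Strains with fewer than \code{covariates + 3} usable samples
#' are skipped with a warning.
#'
#' @param clustering a \code{\link{cluster_and_cut}} result.
#' @param phenotypes samples x phenotypes matrix (row names = sample ids).
#' @param covariates optional data.frame with row names = sample ids.
#' @param encoding "indicator" (default) or "abundance".
#' @param abundance named per-sample numeric vector (required for the
#'   abundance encoding; typically the species relative abundance).
#' @param fdr_threshold FDR level annotated on the result (default 0.1).
#' @return data.frame: strain, phenotype_id, beta, se, p, q, n_used,
#'   significant, encoding.
#' @export
strain_phenotype_association <- function(clustering, phenotypes,
                                         covariates = NULL,
                                         encoding = c("indicator",
                                                      "abundance"),
                                         abundance = NULL,
                                         fdr_threshold = 0.1) {
  encoding <- match.arg(encoding)
  if (encoding == "abundance" && is.null(abundance))
    stop("abundance encoding requires the abundance vector", call. = FALSE)
  lab <- clustering$cluster_labels
  phenotypes <- as.matrix(phenotypes)
  rows <- list()
  for (st in unique(lab)) {
    ids <- if (encoding == "indicator") names(lab) else names(lab)[lab == st]
    ids <- intersect(ids, rownames(phenotypes))
    expo <- if (encoding == "indicator") as.numeric(lab[ids] == st)
            else abundance[ids]
    cv <- if (is.null(covariates)) NULL
          else as.data.frame(covariates)[ids, , drop = FALSE]
    ncov <- if (is.null(cv)) 0 else ncol(cv)
    for (ph in colnames(phenotypes)) {
      y <- phenotypes[ids, ph]
      ok <- !is.na(y) & !is.na(expo)
      if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
      if (sum(ok) < ncov + 3 || stats::var(expo[ok]) == 0) {
        warning("skipping strain ", st, " / ", ph,
                ": too few usable samples")
        next
      }
      yi <- inverse_rank_transform(y[ok])
      dat <- data.frame(.y = yi, .x = expo[ok])
      if (!is.null(cv)) dat <- cbind(dat, cv[ok, , drop = FALSE])
      sm <- summary(stats::lm(.y ~ ., data = dat))$coefficients
      rows[[length(rows) + 1]] <-
        data.frame(strain = st, phenotype_id = ph, beta = sm[".x", 1],
                   se = sm[".x", 2], p = sm[".x", 4],
                   n_used = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(strain = character(0), phenotype_id = character(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      q = numeric(0), n_used = integer(0),
                      significant = logical(0), encoding = character(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_threshold
  out$encoding <- encoding
  rownames(out) <- NULL
  out
}
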