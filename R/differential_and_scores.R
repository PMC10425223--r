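#' Differential abundance, FDR, fold changes and log-ratio scores
#'
#' @name differential_and_scores
NULL

#' Benjamini-Hochberg step-up FDR
#'
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, mapped back to input order
#' and capped at 1.
#'
#' @param p vector of p-values in [0, 1] (NA passed through).
#' @return vector of q-values, \code{q >= p} elementwise.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m > 0) {
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(pp[o] * m / seq(m, 1)))[ro]
  }
  q
}

#' Covariate-adjusted differential abundance
#'
#' Per feature, ordinary least squares of the (CLR+INT-transformed) abundance
#' on the group indicator plus covariates; two-sided t p-value for the group
#' coefficient; BH q-values across the feature family. Samples with missing
#' covariates are dropped (reported via message). Constant features get
#' \code{p = 1} and a flag.
#'
#' @param transformed samples x features matrix of transformed abundances.
#' @param metadata data.frame with row names (or \code{sample_id}) matching
#'   the table's rows.
#' @param group_var name of the two-level grouping column; the coefficient
#'   reported is for the SECOND level against the first (set factor levels
#'   accordingly; for case/control labels, "control" < "case" alphabetically
#'   is re-leveled so beta > 0 means case-enriched).
#' @param covariates character vector of covariate column names.
#' @return data.frame of class \code{"da_result"}: feature_id, beta, se, t,
#'   p, q, direction, constant flag.
#' @export
differential_abundance <- function(transformed, metadata,
                                   group_var = "cohort",
                                   covariates = c("bmi", "smoking",
                                                  "read_count")) {
  if (!is.matrix(transformed) || !is.numeric(transformed))
    stop("transformed must be a numeric matrix", call. = FALSE)
  meta <- .align_metadata(metadata, rownames(transformed))
  g <- meta[[group_var]]
  if (is.null(g)) stop("metadata lacks column ", group_var, call. = FALSE)
  g <- as.factor(g)
  if ("case" %in% levels(g)) g <- stats::relevel(g, ref = setdiff(levels(g),
                                                                  "case")[1])
  if (nlevels(droplevels(g)) != 2)
    stop("group must have exactly 2 levels", call. = FALSE)
  cov_df <- meta[, covariates, drop = FALSE]
  complete <- stats::complete.cases(cov_df) & !is.na(g)
  if (!all(complete))
    message("dropping ", sum(!complete), " sample(s) with missing covariates")
  Y <- transformed[complete, , drop = FALSE]
  X <- stats::model.matrix(~ g + ., data = cbind(g = droplevels(g[complete]),
                                                 cov_df[complete, ,
                                                        drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)
  n <- nrow(X); pdim <- ncol(X)
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  sigma2 <- colSums(res^2) / (n - pdim)
  xtx_inv <- chol2inv(qr.R(qrX))
  gi <- 2L  # group indicator is the first term after the intercept
  beta <- coefs[gi, ]
  se <- sqrt(sigma2 * xtx_inv[gi, gi])
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - pdim)
  const <- apply(Y, 2, function(v) stats::var(v) == 0)
  p[const] <- 1; beta[const] <- 0; se[const] <- NA_real_
  tstat[const] <- NA_real_
  out <- data.frame(feature_id = colnames(Y), beta = beta, se = se,
                    t = tstat, p = p, q = bh_fdr(p),
                    direction = ifelse(beta > 0, "enriched", "depleted"),
                    constant = const, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("da_result", "data.frame")
  out
}

# Match metadata rows (by rownames or sample_id column) to a vector of ids.
.align_metadata <- function(metadata, ids) {
  key <- if (!is.null(metadata$sample_id)) as.character(metadata$sample_id)
         else rownames(metadata)
  idx <- match(ids, key)
  if (anyNA(idx))
    stop("metadata is missing sample(s): ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  metadata[idx, , drop = FALSE]
}

#' Per-feature fold change between two groups
#'
#' \code{(mean_case + pc) / (mean_control + pc)} with arithmetic group means
#' of relative abundance (geometric means by flag) and the table pseudocount.
#'
#' @param table relative abundance matrix, samples in rows.
#' @param groups two-level factor; fold change is second level over first
#'   ("case" re-leveled on top as in \code{\link{differential_abundance}}).
#' @param pseudocount default \code{table_pseudocount(table)}.
#' @param geometric use geometric instead of arithmetic group means.
#' @return named vector of positive fold changes.
#' @export
fold_change <- function(table, groups, pseudocount = NULL,
                        geometric = FALSE) {
  .check_abundance(table)
  g <- as.factor(groups)
  if ("case" %in% levels(g)) g <- stats::relevel(g, ref = setdiff(levels(g),
                                                                  "case")[1])
  g <- droplevels(g)
  if (nlevels(g) != 2) stop("fold_change needs exactly 2 groups",
                            call. = FALSE)
  if (is.null(pseudocount)) pseudocount <- table_pseudocount(table)
  avg <- function(m) {
    if (geometric) exp(colMeans(log(m + pseudocount))) - pseudocount
    else colMeans(m)
  }
  a <- avg(table[g == levels(g)[2], , drop = FALSE])
  b <- avg(table[g == levels(g)[1], , drop = FALSE])
  (a + pseudocount) / (b + pseudocount)
}

#' Split differential-abundance results into enriched/depleted feature sets
#'
#' @param da a \code{\link{differential_abundance}} result.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return list with character vectors \code{enriched} and \code{depleted}
#'   (q < threshold split by the sign of beta). Warns when a side is empty.
#' @export
define_feature_sets <- function(da, fdr_threshold = 0.05) {
  hit <- !is.na(da$q) & da$q < fdr_threshold
  enriched <- da$feature_id[hit & da$beta > 0]
  depleted <- da$feature_id[hit & da$beta < 0]
  if (length(enriched) == 0) warning("no enriched features at FDR < ",
                                     fdr_threshold)
  if (length(depleted) == 0) warning("no depleted features at FDR < ",
                                     fdr_threshold)
  list(enriched = enriched, depleted = depleted)
}

#' Prevotella-to-Bacteroides ratio
#'
#' Sums the relative abundances of all features whose lineage carries the
#' genus, per sample, and returns
#' \code{(Prevotella + pc) / (Bacteroides + pc)}.
#'
#' @param table relative abundance matrix with lineage-style feature names
#'   containing \code{g__<Genus>} tokens.
#' @param pseudocount default \code{table_pseudocount(table)}.
#' @return named positive vector, one ratio per sample.
#' @export
pb_ratio <- function(table, pseudocount = NULL) {
  .check_abundance(table)
  prev <- grepl("g__Prevotella(\\||$)", colnames(table))
  bact <- grepl("g__Bacteroides(\\||$)", colnames(table))
  if (!any(prev) && !any(bact))
    stop("neither genus Prevotella nor Bacteroides found in the table",
         call. = FALSE)
  if (is.null(pseudocount)) pseudocount <- table_pseudocount(table)
  num <- rowSums(table[, prev, drop = FALSE])
  den <- rowSums(table[, bact, drop = FALSE])
  (num + pseudocount) / (den + pseudocount)
}

#' Dysbiosis / function-imbalance score
#'
#' Per sample, the log2 ratio of the geometric mean abundance (plus
#' pseudocount) over the enriched set to that over the depleted set. With
#' species sets this is the dysbiosis index (DI); with pathway sets, the
#' function-imbalance (FI) score. Applying sets derived from one cohort
#' comparison to another cohort's table transfers the score.
#'
#' @param table relative abundance matrix, samples in rows.
#' @param enriched,depleted character vectors of feature ids (nonempty;
#'   features absent from the table are skipped with a message).
#' @param pseudocount default \code{table_pseudocount(table)}.
#' @return named numeric vector of per-sample scores.
#' @export
dysbiosis_score <- function(table, enriched, depleted, pseudocount = NULL) {
  .check_abundance(table)
  if (length(enriched) == 0 || length(depleted) == 0)
    stop("enriched and depleted sets must be nonempty", call. = FALSE)
  miss <- setdiff(c(enriched, depleted), colnames(table))
  if (length(miss) > 0)
    message("skipping ", length(miss), " feature(s) absent from the table")
  enriched <- intersect(enriched, colnames(table))
  depleted <- intersect(depleted, colnames(table))
  if (length(enriched) == 0 || length(depleted) == 0)
    stop("a feature set is empty after matching to the table", call. = FALSE)
  if (is.null(pseudocount)) pseudocount <- table_pseudocount(table)
  ge <- rowMeans(log2(table[, enriched, drop = FALSE] + pseudocount))
  gd <- rowMeans(log2(table[, depleted, drop = FALSE] + pseudocount))
  ge - gd
}

#' Cross-cohort replication of differential-abundance hits
#'
#' A primary hit (q < threshold) replicates when the same feature is
#' significant in the secondary comparison with a concordant effect sign.
#'
#' @param primary,secondary \code{\link{differential_abundance}} results with
#'   overlapping feature ids.
#' @param fdr_threshold cutoff applied to both (default 0.05).
#' @return list: \code{table} (per primary hit: feature_id, replicated flag),
#'   \code{n_hits}, \code{n_replicated}, \code{fraction}.
#' @export
replication_check <- function(primary, secondary, fdr_threshold = 0.05) {
  common <- intersect(primary$feature_id, secondary$feature_id)
  if (length(common) == 0) stop("no overlapping features", call. = FALSE)
  p1 <- primary[match(common, primary$feature_id), ]
  p2 <- secondary[match(common, secondary$feature_id), ]
  hit <- !is.na(p1$q) & p1$q < fdr_threshold
  rep_flag <- hit & !is.na(p2$q) & p2$q < fdr_threshold &
    sign(p1$beta) == sign(p2$beta)
  tab <- data.frame(feature_id = common[hit],
                    replicated = rep_flag[hit],
                    stringsAsFactors = FALSE)
  list(table = tab, n_hits = sum(hit), n_replicated = sum(rep_flag),
       fraction = if (sum(hit) > 0) sum(rep_flag) / sum(hit) else NA_real_)
}
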