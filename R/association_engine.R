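#' Covariate-adjusted association scans and heterogeneity testing
#'
#' @name association_engine
NULL

# Least-squares residuals of v on a covariate data.frame (intercept always).
.residualize <- function(v, covariates) {
  if (is.null(covariates) || ncol(covariates) == 0) return(v - mean(v))
  X <- stats::model.matrix(~ ., data = covariates)
  stats::lm.fit(X, v)$residuals
}

#' Covariate-adjusted Spearman correlation
#'
#' Both variables are inverse-rank normal transformed, residualized on the
#' covariates by least squares, and the Spearman correlation of the
#' residuals is computed. The p-value uses the t approximation with
#' \code{n - 2 - n_covariates} degrees of freedom. With no covariates this
#' equals the plain Spearman rho exactly.
#'
#' @param x,y numeric vectors (missing values removed pairwise, together
#'   with covariate missingness).
#' @param covariates optional data.frame aligned with x and y.
#' @return list: rho, p, n_used.
#' @export
adjusted_spearman <- function(x, y, covariates = NULL) {
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ncov <- if (is.null(cov_df)) 0L else ncol(cov_df)
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(cov_df)) ok <- ok & stats::complete.cases(cov_df)
  n <- sum(ok)
  if (n < ncov + 3)
    stop("too few complete cases (", n, ") for ", ncov, " covariate(s)",
         call. = FALSE)
  xi <- inverse_rank_transform(x[ok])
  yi <- inverse_rank_transform(y[ok])
  cv <- if (is.null(cov_df)) NULL else cov_df[ok, , drop = FALSE]
  rx <- .residualize(xi, cv)
  ry <- .residualize(yi, cv)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("degenerate (constant) variable; returning NA")
    return(list(rho = NA_real_, p = NA_real_, n_used = n))
  }
  rho <- stats::cor(rx, ry, method = "spearman")
  df <- n - 2 - ncov
  tt <- rho * sqrt(df / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tt), df)
  list(rho = rho, p = p, n_used = n)
}

#' Association scan between features/scores and phenotypes
#'
#' Runs \code{\link{adjusted_spearman}} for every (feature, phenotype) pair
#' and applies Benjamini-Hochberg correction across the whole block.
#' Missingness is handled pairwise: samples are dropped per pair, never
#' listwise across the scan. Phenotypes that are entirely missing (or
#' constant) are skipped with a warning.
#'
#' @param features samples x features numeric matrix (per-sample scores are
#'   one-column matrices).
#' @param phenotypes samples x phenotypes numeric matrix, rows aligned.
#' @param covariates optional data.frame aligned with the rows.
#' @param fdr_threshold FDR level annotated on the result (default 0.1).
#' @return data.frame: feature_id, phenotype_id, rho, p, q, n_used,
#'   significant, covariate_set.
#' @export
association_scan <- function(features, phenotypes, covariates = NULL,
                             fdr_threshold = 0.1) {
  features <- as.matrix(features)
  phenotypes <- as.matrix(phenotypes)
  if (nrow(features) != nrow(phenotypes))
    stop("features and phenotypes must have aligned rows", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature", seq_len(ncol(features)))
  if (is.null(colnames(phenotypes)))
    colnames(phenotypes) <- paste0("phenotype", seq_len(ncol(phenotypes)))
  cov_set <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    "none" else paste(colnames(as.data.frame(covariates)), collapse = "+")
  usable <- vapply(colnames(phenotypes), function(ph) {
    v <- phenotypes[, ph]
    sum(!is.na(v)) >= 3 && stats::var(v, na.rm = TRUE) > 0
  }, logical(1))
  if (any(!usable))
    warning("skipping phenotype(s) with no usable data: ",
            paste(colnames(phenotypes)[!usable], collapse = ", "))
  grid <- expand.grid(feature_id = colnames(features),
                      phenotype_id = colnames(phenotypes)[usable],
                      stringsAsFactors = FALSE)
  res <- mapply(function(f, ph) {
    as <- adjusted_spearman(features[, f], phenotypes[, ph], covariates)
    c(as$rho, as$p, as$n_used)
  }, grid$feature_id, grid$phenotype_id)
  grid$rho <- res[1, ]
  grid$p <- res[2, ]
  grid$q <- bh_fdr(grid$p)
  grid$n_used <- as.integer(res[3, ])
  grid$significant <- !is.na(grid$q) & grid$q < fdr_threshold
  grid$covariate_set <- cov_set
  grid
}

#' Cytokine group comparison
#'
#' Per phenotype, least squares of the inverse-rank-transformed cytokine on
#' the group indicator plus covariates (age and sex by default, supplied as
#' a data.frame); BH correction across the panel. Constant cytokines are
#' flagged with \code{p = 1}.
#'
#' @param cytokines samples x phenotypes positive matrix.
#' @param group two-level factor ("case" re-leveled on top when present).
#' @param covariates data.frame aligned with rows (e.g. age, sex).
#' @param fdr_threshold FDR level annotated on the result (default 0.05).
#' @return data.frame: phenotype_id, beta, se, p, q, significant, constant.
#' @export
cytokine_group_comparison <- function(cytokines, group, covariates = NULL,
                                      fdr_threshold = 0.05) {
  cytokines <- as.matrix(cytokines)
  g <- as.factor(group)
  if ("case" %in% levels(g)) g <- stats::relevel(g, ref = setdiff(levels(g),
                                                                  "case")[1])
  g <- droplevels(g)
  if (nlevels(g) != 2) stop("group must have exactly 2 levels",
                            call. = FALSE)
  cov_df <- if (is.null(covariates)) data.frame(row.names = seq_along(g))
            else as.data.frame(covariates)
  out <- lapply(colnames(cytokines), function(ph) {
    y <- cytokines[, ph]
    ok <- !is.na(y) & (ncol(cov_df) == 0 | stats::complete.cases(cov_df))
    if (stats::var(y[ok]) == 0)
      return(data.frame(phenotype_id = ph, beta = 0, se = NA_real_, p = 1,
                        constant = TRUE, stringsAsFactors = FALSE))
    yi <- inverse_rank_transform(y[ok])
    dat <- cbind(data.frame(.y = yi, .g = g[ok]),
                 cov_df[ok, , drop = FALSE])
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- summary(fit)$coefficients
    row <- grep("^\\.g", rownames(sm))
    data.frame(phenotype_id = ph, beta = sm[row, 1], se = sm[row, 2],
               p = sm[row, 4], constant = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- bh_fdr(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr_threshold
  rownames(out) <- NULL
  out[, c("phenotype_id", "beta", "se", "p", "q", "significant", "constant")]
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum w_i (\beta_i - \bar\beta_w)^2} with inverse-variance
#' weights \eqn{w_i = 1/se_i^2}; p from the chi-square upper tail on
#' \code{k - 1} degrees of freedom.
#'
#' @param betas per-cohort effect estimates (length >= 2).
#' @param ses positive standard errors, same length.
#' @return list: q_statistic, df, p, weighted_mean, betas, ses.
#' @export
cochran_q <- function(betas, ses) {
  if (length(betas) < 2 || length(betas) != length(ses))
    stop("need >= 2 (beta, se) pairs of equal length", call. = FALSE)
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  bw <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - bw)^2)
  df <- length(betas) - 1
  list(q_statistic = q, df = df,
       p = stats::pchisq(q, df, lower.tail = FALSE),
       weighted_mean = bw, betas = betas, ses = ses)
}

#' Fisher z effect for correlation-based heterogeneity input
#'
#' Converts a correlation and sample size to \code{atanh(rho)} with standard
#' error \code{1/sqrt(n - 3)}, suitable for \code{\link{cochran_q}}.
#'
#' @param rho correlation in (-1, 1).
#' @param n sample size (> 3).
#' @return list: beta, se.
#' @export
fisher_z <- function(rho, n) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  if (any(n <= 3)) stop("n must exceed 3", call. = FALSE)
  list(beta = atanh(rho), se = 1 / sqrt(n - 3))
}
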