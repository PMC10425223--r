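#' Diversity, ordination and permutational ANOVA
#'
#' @name community_stats
NULL

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \ln p_i} over the nonzero entries of each sample after
#' row closure. Natural logarithm.
#'
#' @param x abundance matrix, samples in rows.
#' @return named numeric vector, one value per sample.
#' @export
shannon_index <- function(x) {
  .check_abundance(x)
  p <- close_rows(x)
  apply(p, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log(r))
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' [0, 1] for nonnegative profiles. Not a metric (no triangle inequality).
#'
#' @param x abundance matrix, samples in rows.
#' @return symmetric matrix with zero diagonal and attribute
#'   \code{metric = "bray_curtis"}.
#' @export
bray_curtis <- function(x) {
  .check_abundance(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - x[j, ])) / sum(xi + x[j, ])
    }
  }
  attr(d, "metric") <- "bray_curtis"
  d
}

.check_distance <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square distance matrix", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0))
    stop("d must be symmetric with a zero diagonal", call. = FALSE)
  invisible(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared-distance matrix and eigendecomposes it. Axes
#' are ordered by eigenvalue; negative eigenvalues are reported, not dropped.
#'
#' @param d square symmetric distance matrix.
#' @param k number of axes to return (k < n).
#' @return list: \code{coordinates} (n x k), \code{eigenvalues} (all n - 1),
#'   \code{explained} (fractions of the positive-eigenvalue total for the k
#'   returned axes), \code{negative_eigenvalues} flag.
#' @export
pcoa <- function(d, k = 2) {
  .check_distance(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of samples",
                   call. = FALSE)
  sc <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  co <- sc$points
  if (ncol(co) < k) {  # degenerate geometry: pad zero axes
    co <- cbind(co, matrix(0, n, k - ncol(co)))
  }
  colnames(co) <- paste0("PCo", seq_len(k))
  rownames(co) <- rownames(d)
  ev <- sc$eig
  pos <- ev[ev > 0]
  list(coordinates = co,
       eigenvalues = ev,
       explained = pmax(ev[seq_len(k)], 0) / sum(pos),
       negative_eigenvalues = any(ev < -1e-8 * max(abs(ev))))
}

# trace of H %*% G where H is the projection onto the column space of X
.trace_hat <- function(X, G) {
  q <- qr.Q(qr(X))
  sum((G %*% q) * q)
}

#' PERMANOVA (permutational multivariate analysis of variance)
#'
#' Partitions the Gower-centered distance-matrix variance by sequential
#' (Type I) sums of squares with covariates entered before the group term,
#' which always comes last. Significance of the group term comes from
#' permuting the group labels while holding covariates fixed.
#'
#' @param d square symmetric distance matrix.
#' @param group factor (>= 2 levels, each with >= 2 samples).
#' @param covariates optional data.frame of covariates, rows aligned with
#'   \code{d}.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed, mandatory for reproducibility.
#' @return data.frame of class \code{"permanova"} with one row per term plus
#'   Residual and Total: df, sums of squares, R2, pseudo-F, and the
#'   permutation p-value for the group term.
#' @export
permanova <- function(d, group, covariates = NULL, n_perm = 999, seed) {
  .check_distance(d)
  if (missing(seed)) stop("seed is mandatory for permanova", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("group needs >= 2 levels", call. = FALSE)
  if (any(table(group) < 2))
    stop("every group level needs >= 2 samples", call. = FALSE)
  n <- nrow(d)
  if (length(group) != n) stop("group length must match d", call. = FALSE)
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  cov_mm <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  full_mm <- function(g) cbind(cov_mm, stats::model.matrix(~ g)[, -1,
                                                               drop = FALSE])
  tr_cov <- .trace_hat(cov_mm, G) - .trace_hat(matrix(1, n, 1), G)
  stat_group <- function(g) {
    X <- full_mm(g)
    ss_group <- .trace_hat(X, G) - .trace_hat(cov_mm, G)
    ss_res <- ss_total - .trace_hat(X, G) + .trace_hat(matrix(1, n, 1), G)
    df_group <- nlevels(g) - 1
    df_res <- n - qr(X)$rank
    list(ss = ss_group, f = (ss_group / df_group) / (ss_res / df_res),
         ss_res = ss_res, df_res = df_res)
  }
  obs <- stat_group(group)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    fb <- stat_group(group[sample.int(n)])$f
    if (fb >= obs$f) exceed <- exceed + 1L
  }
  p <- (exceed + 1) / (n_perm + 1)

  df_cov <- qr(cov_mm)$rank - 1
  terms <- data.frame(
    term = c(if (df_cov > 0) "covariates", "group", "Residual", "Total"),
    df = c(if (df_cov > 0) df_cov, nlevels(group) - 1, obs$df_res, n - 1),
    sum_sq = c(if (df_cov > 0) tr_cov, obs$ss, obs$ss_res, ss_total),
    stringsAsFactors = FALSE)
  terms$r_squared <- terms$sum_sq / ss_total
  terms$pseudo_F <- NA_real_
  terms$pseudo_F[terms$term == "group"] <- obs$f
  terms$p <- NA_real_
  terms$p[terms$term == "group"] <- p
  structure(terms, class = c("permanova", "data.frame"),
            n_permutations = n_perm, seed = seed)
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", attr(x, "n_permutations"), " permutations, seed ",
      attr(x, "seed"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact null enumeration for small untied samples, tie-corrected normal
#' approximation otherwise (the behavior of \code{stats::wilcox.test}).
#'
#' @param values numeric vector.
#' @param groups two-level factor aligned with \code{values}.
#' @return list: \code{statistic} (Mann-Whitney U of the first level),
#'   \code{p}.
#' @export
wilcoxon_rank_sum <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2)
    stop("wilcoxon_rank_sum requires exactly 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(values[groups == levels(groups)[1]],
                       values[groups == levels(groups)[2]],
                       exact = NULL, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Dunn's test for pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on the shared ranks of the pooled sample, with the
#' usual tie correction, two-sided p-values, and Benjamini-Hochberg
#' adjustment across the pairs.
#'
#' @param values numeric vector.
#' @param groups factor with >= 3 levels.
#' @return data.frame: group1, group2, z, p, q.
#' @export
dunn_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 3) stop("dunn_test requires >= 3 groups",
                                call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  n <- length(values)
  r <- rank(values, ties.method = "average")
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
    z <- unname((mean_r[i] - mean_r[j]) / se)
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
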