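#' Compositional transforms and prevalence filtering
#'
#' Abundance tables are plain numeric matrices with samples in rows and
#' features in columns; row names are sample ids, column names are feature
#' labels (taxonomic lineage strings or pathway ids). A table flagged
#' "relative" has rows summing to 1.
#'
#' @name transforms
NULL

# Internal: validate a samples-by-features abundance matrix.
.check_abundance <- function(x, relative = FALSE, arg = "table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix (samples in rows)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(arg, " must have sample row names and feature column names",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(arg, ": duplicated sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(arg, ": duplicated feature ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop(arg, " must contain finite nonnegative values", call. = FALSE)
  if (relative) {
    rs <- rowSums(x)
    if (any(abs(rs - 1) > 1e-6))
      stop(arg, " is not relative: row sums deviate from 1 (max deviation ",
           format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  invisible(x)
}

#' Close rows to relative abundances
#'
#' Divides each sample row by its total so rows sum to one.
#'
#' @param x numeric matrix, samples in rows.
#' @return matrix of the same shape with unit row sums.
#' @export
close_rows <- function(x) {
  .check_abundance(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "), call. = FALSE)
  x / rs
}

#' Table-wide pseudocount
#'
#' Half the smallest nonzero value in the table — the default zero-replacement
#' policy shared by the CLR transform, fold changes and log-ratio scores.
#'
#' @param x numeric matrix with at least one positive entry.
#' @return a single positive number.
#' @export
table_pseudocount <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0) stop("table has no positive entries", call. = FALSE)
  min(pos) / 2
}

#' Prevalence filter
#'
#' Keeps features that are present (abundance > 0) in at least a given
#' fraction of the samples of a cohort. Two readings are supported:
#' \code{mode = "any"} keeps a feature when it meets the threshold in at
#' least one cohort; \code{mode = "all"} requires every cohort.
#'
#' @param x abundance matrix, samples in rows.
#' @param cohorts cohort label per sample (length \code{nrow(x)}).
#' @param threshold prevalence fraction in (0, 1]; default 0.2.
#' @param mode "any" (default) or "all".
#' @return the matrix restricted to kept features, column order preserved.
#'   Emits a warning (not an error) when no feature survives.
#' @export
prevalence_filter <- function(x, cohorts, threshold = 0.2,
                              mode = c("any", "all")) {
  mode <- match.arg(mode)
  .check_abundance(x)
  if (length(cohorts) != nrow(x))
    stop("cohorts must have one label per sample", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  cohorts <- as.factor(cohorts)
  prev <- vapply(levels(cohorts), function(g) {
    colMeans(x[cohorts == g, , drop = FALSE] > 0)
  }, numeric(ncol(x)))
  prev <- matrix(prev, ncol = length(levels(cohorts)))  # features x cohorts
  keep <- if (mode == "any") apply(prev >= threshold, 1, any)
          else apply(prev >= threshold, 1, all)
  if (!any(keep))
    warning("prevalence_filter: no feature passed the threshold")
  x[, keep, drop = FALSE]
}

#' Centered log-ratio transform
#'
#' Per sample, zeros are replaced by a pseudocount (default: half the smallest
#' nonzero value of the whole table), the row is re-closed, and
#' \eqn{clr(x)_i = \log(x_i / g(x))} with \eqn{g} the geometric mean.
#' Every output row sums to zero.
#'
#' @param x relative abundance matrix, samples in rows.
#' @param pseudocount zero replacement value; \code{NULL} (default) uses
#'   \code{table_pseudocount(x)}.
#' @return matrix of CLR values with attribute \code{transform} = "CLR".
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  .check_abundance(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("CLR undefined for all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "), call. = FALSE)
  if (is.null(pseudocount)) pseudocount <- table_pseudocount(x)
  x <- x / rs
  x[x == 0] <- pseudocount
  x <- x / rowSums(x)
  lx <- log(x)
  out <- lx - rowMeans(lx)
  attr(out, "transform") <- "CLR"
  out
}

#' Rank-based inverse normal transform
#'
#' Blom-style transform \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))} with average
#' ranks for ties. Missing values are passed through; \code{n} counts the
#' non-missing entries. Applied per column when given a matrix.
#'
#' @param x numeric vector, or matrix (samples in rows; transformed
#'   feature-wise).
#' @return object of the same shape; for a matrix the attribute
#'   \code{transform} records "INT" (or "CLR+INT" when the input was CLR).
#' @export
inverse_rank_transform <- function(x) {
  if (is.matrix(x)) {
    tag <- attr(x, "transform")
    out <- apply(x, 2, .int_vector)
    dimnames(out) <- dimnames(x)
    attr(out, "transform") <- if (identical(tag, "CLR")) "CLR+INT" else "INT"
    return(out)
  }
  .int_vector(x)
}

.int_vector <- function(v) {
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2) stop("inverse_rank_transform needs >= 2 non-missing values",
                  call. = FALSE)
  out <- rep(NA_real_, length(v))
  vv <- v[ok]
  if (length(unique(vv)) == 1) {
    warning("all values identical; inverse-rank transform maps them to 0")
    out[ok] <- 0
    return(out)
  }
  r <- rank(vv, ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}
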