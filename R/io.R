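#' TSV readers and writers for abundance tables, gene matrices and metadata
#'
#' On disk, abundance tables follow the MetaPhlAn-style merged-table dialect
#' (features in rows with lineage labels, header row of sample ids) and gene
#' matrices the PanPhlAn-style dialect (gene families in rows, samples in
#' columns, 0/1). Internally everything is samples-in-rows; the readers
#' transpose. Writers prepend provenance comment lines ("# key: value").
#'
#' @name io
NULL

.provenance_lines <- function(stage, seed = NULL, config_hash = NULL) {
  c(paste0("# stage: ", stage),
    paste0("# package: dysbiome ",
           as.character(utils::packageVersion("dysbiome"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config_hash)) paste0("# config_hash: ", config_hash))
}

.write_matrix_tsv <- function(m, path, id_col, stage, seed = NULL,
                              config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(stage, seed, config_hash), con)
  df <- data.frame(rownames(m), format(m, digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_matrix_tsv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(what, ": no sample columns in ", path,
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(what, ": duplicated row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  heads <- colnames(df)[-1]
  if (anyDuplicated(heads))
    stop(what, ": duplicated sample id(s): ",
         paste(unique(heads[duplicated(heads)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 2,
                        function(v) all(!is.na(suppressWarnings(
                          as.numeric(v))) | is.na(v))))
    stop(what, ": non-numeric cells in column(s): ",
         paste(heads[bad], collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write / read an abundance table (MetaPhlAn-style dialect)
#'
#' @param x samples x features relative abundance matrix.
#' @param path TSV path; features are written in rows under a
#'   \code{clade_name} column.
#' @param seed,config_hash optional provenance fields for the header.
#' @return \code{read_abundance} returns the samples-in-rows matrix.
#' @export
write_abundance <- function(x, path, seed = NULL, config_hash = NULL) {
  .check_abundance(x)
  .write_matrix_tsv(t(x), path, "clade_name", "abundance", seed, config_hash)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  m <- t(.read_matrix_tsv(path, "abundance table"))
  .check_abundance(m)
  m
}

#' Write / read a binary gene-family matrix (PanPhlAn-style dialect)
#'
#' @param m samples x gene-families 0/1 matrix (written transposed: gene
#'   families in rows).
#' @param path TSV path.
#' @param binarize when reading, threshold numeric entries at > 0 to 0/1
#'   (default FALSE: entries must already be 0/1).
#' @param seed,config_hash optional provenance fields.
#' @return \code{read_gene_matrix} returns the samples-in-rows 0/1 matrix.
#' @export
write_gene_matrix <- function(m, path, seed = NULL, config_hash = NULL) {
  .check_binary(m)
  .write_matrix_tsv(t(m), path, "gene_family", "gene_matrix", seed,
                    config_hash)
  invisible(path)
}

#' @rdname write_gene_matrix
#' @export
read_gene_matrix <- function(path, binarize = FALSE) {
  m <- t(.read_matrix_tsv(path, "gene-family matrix"))
  if (binarize) m <- (m > 0) * 1
  .check_binary(m)
  m
}

#' Write / read per-sample metadata
#'
#' Plain TSV with a leading \code{sample_id} column; all other columns kept
#' as-is (numeric where parseable).
#'
#' @param metadata data.frame with a \code{sample_id} column (or row names).
#' @param path TSV path.
#' @return \code{read_metadata} returns a data.frame with row names set to
#'   the sample ids.
#' @export
write_metadata <- function(metadata, path) {
  if (is.null(metadata$sample_id))
    metadata <- cbind(sample_id = rownames(metadata), metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines("metadata"), con)
  utils::write.table(metadata, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(df$sample_id))
    stop("metadata file lacks a sample_id column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("metadata: duplicated sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  rownames(df) <- df$sample_id
  df
}

#' Write a result data.frame as TSV with a provenance header
#'
#' @param df data.frame.
#' @param path TSV path.
#' @param stage short stage name recorded in the header.
#' @param seed,config_hash optional provenance fields.
#' @export
write_result <- function(df, path, stage = "result", seed = NULL,
                         config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(stage, seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse the genus token out of lineage-style feature labels
#'
#' @param labels character vector like \code{"g__Prevotella|s__P_copri"}.
#' @return character vector of genus names (NA when no genus token).
#' @export
lineage_genus <- function(labels) {
  m <- regmatches(labels, regexpr("g__[^|]+", labels))
  out <- rep(NA_character_, length(labels))
  out[grepl("g__", labels)] <- sub("^g__", "", m)
  out
}
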