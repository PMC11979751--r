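#' Read an expression matrix from delimited text
#'
#' Reads a tab-delimited matrix (genes as rows by default, header row of
#' observation identifiers). Duplicate gene rows are collapsed by their mean
#' with a warning; duplicate observation identifiers and non-numeric cells
#' are hard errors with located messages.
#'
#' @param path File path.
#' @param orientation `"genes_rows"` (canonical) or `"observations_rows"`
#'   (transposed on load).
#' @param value_space `"logTPM"` or `"TPM"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, orientation = c("genes_rows",
                                                  "observations_rows"),
                            value_space = c("logTPM", "TPM")) {
  orientation <- match.arg(orientation)
  value_space <- match.arg(value_space)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header))
    stop("duplicate column identifiers in ", path, ": ",
         header[which(duplicated(header))[1]])
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  suppressWarnings(num <- vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body))
  dimnames(num) <- list(NULL, header)
  bad <- which(is.na(num) & !(toupper(as.matrix(body)) %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell at row ", bad[1, 1] + 1, ", column ",
         bad[1, 2] + 1, " of ", path)
  rownames(num) <- NULL
  x <- num
  if (anyDuplicated(ids)) {
    if (orientation == "observations_rows")
      stop("duplicate observation identifiers in ", path, ": ",
           ids[which(duplicated(ids))[1]])
    warning("duplicate gene rows collapsed by mean: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    x <- rowsum(num, group = ids)           # sorts groups lexicographically
    tab <- table(ids)
    x <- x / as.vector(tab[rownames(x)])
  } else {
    rownames(x) <- ids
  }
  if (orientation == "observations_rows") x <- t(x)
  expression_matrix(x, space = value_space)
}

#' Write an expression matrix as tab-delimited text
#'
#' Genes as rows, header row of observation identifiers; the paired reader
#' is [read_expression()].
#'
#' @param matrix An [expression_matrix()] or genes x observations matrix.
#' @param path Output path.
#' @param id_column Name of the first (gene identifier) column.
#' @export
write_expression <- function(matrix, path, id_column = "gene") {
  x <- em_values(matrix)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from sparse triplet text
#'
#' Three tab-separated columns with header `gene`, `observation`, `value`;
#' unmentioned (gene, observation) entries are zero. The full gene and
#' observation universes default to those mentioned in the file but can be
#' supplied to include all-zero rows/columns.
#'
#' @param path File path.
#' @param genes,observations Optional identifier universes.
#' @param value_space `"logTPM"` or `"TPM"`.
#' @return An [expression_matrix()].
#' @export
read_expression_sparse <- function(path, genes = NULL, observations = NULL,
                                   value_space = c("logTPM", "TPM")) {
  value_space <- match.arg(value_space)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "observation", "value") %in% colnames(df)))
    stop("sparse triplet file must have columns gene, observation, value")
  if (!is.numeric(df$value))
    stop("non-numeric value in sparse triplet file ", path)
  if (is.null(genes)) genes <- sort(unique(df$gene))
  if (is.null(observations)) observations <- sort(unique(df$observation))
  m <- Matrix::sparseMatrix(i = match(df$gene, genes),
                            j = match(df$observation, observations),
                            x = df$value,
                            dims = c(length(genes), length(observations)),
                            dimnames = list(genes, observations))
  expression_matrix(as.matrix(m), space = value_space)
}

#' Write an expression matrix as sparse triplet text
#'
#' @param matrix An [expression_matrix()] or matrix.
#' @param path Output path.
#' @export
write_expression_sparse <- function(matrix, path) {
  x <- em_values(matrix)
  nz <- which(x != 0, arr.ind = TRUE)
  df <- data.frame(gene = rownames(x)[nz[, 1]],
                   observation = colnames(x)[nz[, 2]],
                   value = x[nz], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' Standard GMT: one set per line — name, description, then member genes,
#' tab-separated.
#'
#' @param path File path.
#' @return A [gene_set_collection()]; descriptions kept as the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gsc <- gene_set_collection(sets)
  attr(gsc, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  gsc
}

#' Write gene sets as GMT
#'
#' @param sets A [gene_set_collection()] or named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a marker set as GMT (one set per state)
#'
#' @param markers A `marker_set`.
#' @param path Output path.
#' @export
write_markers_gmt <- function(markers, path) {
  sets <- lapply(markers$markers, `[[`, "gene")
  write_gmt(sets, path,
            descriptions = rep("state markers", length(sets)))
}

#' Write a ranked gene list in the 2-column RNK convention
#'
#' @param ranked Data frame with columns `gene` and a numeric score column
#'   (default `rho`), ordered most positive to most negative.
#' @param path Output path.
#' @param score_column Name of the score column.
#' @export
write_rnk <- function(ranked, path, score_column = "rho") {
  utils::write.table(ranked[, c("gene", score_column)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-gene repressive tendency scores
#'
#' Two-column tab-delimited text: gene identifier, score. No header is
#' expected; a header line is detected and skipped if the second field is
#' non-numeric.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_rts <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]
  scores <- as.numeric(df[[2]])
  if (anyNA(scores)) stop("non-numeric score in ", path)
  stats::setNames(scores, df[[1]])
}

#' Write gene pairs with concordance as tab-delimited text
#'
#' @param pairs Two-column pair matrix (concordance may be attached as the
#'   `concordance` attribute or passed separately).
#' @param path Output path.
#' @param concordance Optional per-pair concordance vector.
#' @export
write_pairs <- function(pairs, path, concordance = NULL) {
  if (is.null(concordance)) concordance <- attr(pairs, "concordance")
  df <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                   stringsAsFactors = FALSE)
  if (!is.null(concordance)) df$concordance <- concordance
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene pairs written by [write_pairs()]
#'
#' @param path File path.
#' @return Two-column character matrix with `concordance` attribute if
#'   present in the file.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- cbind(first = df$gene_a, second = df$gene_b)
  if ("concordance" %in% colnames(df))
    attr(out, "concordance") <- df$concordance
  out
}
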