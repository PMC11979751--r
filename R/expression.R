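#' Expression matrix container
#'
#' A thin wrapper around a numeric genes x observations matrix that records
#' the value space of the entries: `"logTPM"` for log2(TPM+1) or `"TPM"` for
#' linear transcripts-per-million. Most functions in the package accept
#' either an `expr_matrix` or a bare numeric matrix (assumed `"logTPM"`).
#'
#' @param values Numeric matrix, genes as rows (rownames = gene identifiers),
#'   observations (cells or bulk samples) as columns.
#' @param space Value space of the entries, `"logTPM"` or `"TPM"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, space = c("logTPM", "TPM")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("'values' must have gene identifiers as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in expression matrix: ",
         rownames(values)[which(duplicated(rownames(values)))[1]])
  if (is.null(colnames(values)))
    colnames(values) <- paste0("obs", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate observation identifiers: ",
         colnames(values)[which(duplicated(colnames(values)))[1]])
  structure(list(values = values, space = space), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d observations [%s]\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Accept expr_matrix or bare numeric matrix; return the numeric matrix.
em_values <- function(x) {
  if (inherits(x, "expr_matrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an expr_matrix or numeric matrix")
}

em_space <- function(x, default = "logTPM") {
  if (inherits(x, "expr_matrix")) x$space else default
}

#' Log2(TPM+1) transform and its inverse
#'
#' `log_tpm()` maps linear TPM values to log2(TPM+1); `unlog_tpm()` is the
#' exact inverse, 2^x - 1. Both operate elementwise and update the value
#' space tag when given an `expr_matrix`.
#'
#' @param x Numeric matrix/vector or `expr_matrix`.
#' @return Transformed object of the same kind as the input.
#' @export
log_tpm <- function(x) {
  if (inherits(x, "expr_matrix")) {
    if (x$space == "logTPM") stop("matrix is already in logTPM space")
    return(expression_matrix(log_tpm(x$values), space = "logTPM"))
  }
  if (any(x < 0)) stop("log_tpm: negative input values")
  log2(x + 1)
}

#' @rdname log_tpm
#' @export
unlog_tpm <- function(x) {
  if (inherits(x, "expr_matrix")) {
    if (x$space == "TPM") stop("matrix is already in TPM space")
    return(expression_matrix(unlog_tpm(x$values), space = "TPM"))
  }
  if (any(x < 0)) stop("unlog_tpm: negative input values")
  2^x - 1
}

# Return matrix values converted to the requested space.
em_as_space <- function(x, space) {
  v <- em_values(x)
  have <- em_space(x)
  if (have == space) return(v)
  if (space == "TPM") unlog_tpm(v) else log_tpm(v)
}
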