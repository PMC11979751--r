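# Linear-kernel nu-SVR solved exactly as a quadratic program (the LIBSVM
# dual: box constraints at C, sum(alpha + alpha*) = C * l * nu). Returns the
# primal weight vector and intercept. l = number of response rows (here,
# marker genes); validated against libsvm-based implementations.
nusvr_fit <- function(X, y, nu = 0.5, C = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  l <- nrow(X)
  if (length(y) != l) stop("X and y are not aligned")
  K <- X %*% t(X)
  D <- rbind(cbind(K, -K), cbind(-K, K))
  ridge <- 1e-8 * max(diag(K), 1)
  diag(D) <- diag(D) + ridge
  d <- c(y, -y)
  ub <- C
  A <- cbind(c(rep(1, l), rep(-1, l)),     # sum(a) - sum(a*) = 0
             rep(1, 2 * l),                # sum(a) + sum(a*) = C * l * nu
             diag(2 * l),                  # a, a* >= 0
             -diag(2 * l))                 # a, a* <= C
  b0 <- c(0, C * l * nu, rep(0, 2 * l), rep(-ub, 2 * l))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 2)
  a <- sol$solution[seq_len(l)]
  as_ <- sol$solution[l + seq_len(l)]
  w <- drop(t(X) %*% (a - as_))
  resid <- y - drop(X %*% w)
  tol <- 1e-6 * ub
  fplus <- a > tol & a < ub - tol
  fminus <- as_ > tol & as_ < ub - tol
  b <- if (any(fplus) && any(fminus))
    (mean(resid[fplus]) + mean(resid[fminus])) / 2
  else stats::median(resid)
  list(w = w, b = b)
}

#' Build a marker signature matrix
#'
#' Mean expression of every marker gene in every state of a labelled
#' single-cell matrix — the regression design for deconvolution.
#'
#' @param matrix [expression_matrix()] or genes x cells matrix.
#' @param labels Per-cell state labels.
#' @param markers A `marker_set` from [select_markers()], or a character
#'   vector of marker genes.
#' @return A `signature_matrix`: list with `values` (marker genes x states),
#'   `space` (value space of the means), `marker_source`.
#' @export
build_signature <- function(matrix, labels, markers) {
  x <- em_values(matrix)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x))
    stop("labels length does not match number of cells")
  genes <- if (inherits(markers, "marker_set")) marker_genes(markers)
           else as.character(markers)
  missing <- setdiff(genes, rownames(x))
  if (length(missing)) stop("marker gene missing from matrix: ", missing[1])
  if (nlevels(labels) < 2) stop("need at least 2 states")
  vals <- matrix(NA_real_, length(genes), nlevels(labels),
                 dimnames = list(genes, levels(labels)))
  for (s in levels(labels))
    vals[, s] <- rowMeans(x[genes, labels == s, drop = FALSE])
  if (any(rowSums(abs(vals)) == 0))
    warning("signature contains all-zero gene rows")
  structure(list(values = vals, space = em_space(matrix),
                 marker_source = if (inherits(markers, "marker_set"))
                   "marker_set" else "gene list"),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d marker genes x %d states [%s]\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' Deconvolve one bulk profile by nu-SVR
#'
#' Regresses the bulk expression of the signature's marker genes on the
#' per-state signature columns with linear-kernel nu-SVR, once per value of
#' the Nu grid. The Nu whose fitted values have the smallest mean squared
#' error against the observed profile wins; its coefficients are clipped at
#' zero and normalised to sum to one to give the state proportions.
#'
#' @param bulk_profile Named numeric vector of expression over (at least)
#'   the signature genes, in the same value space as the signature.
#' @param signature A `signature_matrix`.
#' @param nu_grid Values of Nu to try (default 0.25, 0.5, 0.75).
#' @param C SVR cost parameter.
#' @return List with `proportions` (named, sums to 1), `chosen_nu`, `mse`,
#'   and `raw_coefficients`.
#' @export
deconvolve_sample <- function(bulk_profile, signature,
                              nu_grid = c(0.25, 0.5, 0.75), C = 1) {
  X <- signature$values
  if (!is.null(names(bulk_profile))) {
    missing <- setdiff(rownames(X), names(bulk_profile))
    if (length(missing)) stop("bulk profile missing gene: ", missing[1])
    y <- bulk_profile[rownames(X)]
  } else {
    if (length(bulk_profile) != nrow(X))
      stop("unnamed bulk profile must align with signature genes")
    y <- bulk_profile
  }
  # The response is scaled to unit RMS before fitting and the coefficients
  # scaled back, so C acts relative to the profile's magnitude and the
  # estimate is exactly equivariant under positive rescaling of the profile.
  s <- sqrt(mean(y^2))
  if (s == 0) stop("bulk profile is all zero over the signature genes")
  best <- NULL
  for (nu in nu_grid) {
    fit <- nusvr_fit(X, y / s, nu = nu, C = C)
    w <- fit$w * s
    mse <- mean((drop(X %*% w) + fit$b * s - y)^2)
    if (is.null(best) || mse < best$mse)
      best <- list(w = w, mse = mse, nu = nu)
  }
  w <- best$w
  clipped <- pmax(w, 0)
  if (sum(clipped) <= 0)
    stop("all deconvolution coefficients non-positive: unresolvable mixture")
  props <- clipped / sum(clipped)
  names(props) <- colnames(X)
  list(proportions = props, chosen_nu = best$nu, mse = best$mse,
       raw_coefficients = stats::setNames(w, colnames(X)))
}

#' Deconvolve a bulk matrix sample by sample
#'
#' Applies [deconvolve_sample()] independently to every column of the bulk
#' matrix, in input order.
#'
#' @param bulk [expression_matrix()] or genes x samples matrix.
#' @param signature A `signature_matrix`.
#' @inheritParams deconvolve_sample
#' @return A `proportion_estimate`: list with `proportions` (samples x
#'   states, rows sum to 1), `chosen_nu`, `fit_mse`, `raw_coefficients`.
#' @export
deconvolve_matrix <- function(bulk, signature, nu_grid = c(0.25, 0.5, 0.75),
                              C = 1) {
  x <- em_values(bulk)
  if (em_space(bulk) != signature$space)
    warning("bulk value space (", em_space(bulk),
            ") differs from signature space (", signature$space, ")")
  missing <- setdiff(rownames(signature$values), rownames(x))
  if (length(missing)) stop("bulk matrix missing gene: ", missing[1])
  n <- ncol(x); S <- ncol(signature$values)
  props <- matrix(NA_real_, n, S,
                  dimnames = list(colnames(x), colnames(signature$values)))
  raw <- props
  nus <- mses <- stats::setNames(numeric(n), colnames(x))
  for (i in seq_len(n)) {
    fit <- tryCatch(
      deconvolve_sample(x[rownames(signature$values), i], signature,
                        nu_grid = nu_grid, C = C),
      error = function(e) stop("sample '", colnames(x)[i], "': ",
                               conditionMessage(e), call. = FALSE))
    props[i, ] <- fit$proportions
    raw[i, ] <- fit$raw_coefficients
    nus[i] <- fit$chosen_nu
    mses[i] <- fit$mse
  }
  structure(list(proportions = props, chosen_nu = nus, fit_mse = mses,
                 raw_coefficients = raw, nu_grid = nu_grid),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("<proportion_estimate> %d samples x %d states (mean mse %.4g)\n",
              nrow(x$proportions), ncol(x$proportions), mean(x$fit_mse)))
  invisible(x)
}

#' Impute state-specific expression by positive lasso
#'
#' For each gene independently, regresses its expression across bulk samples
#' on the estimated state proportions with L1-penalised regression, no
#' intercept, coefficients constrained non-negative. The coefficient vector
#' is the imputed per-state expression of the gene. Physically, bulk
#' abundance is a proportion-weighted average of state abundances in linear
#' TPM space, so supplying TPM values yields interpretable coefficients.
#'
#' @param bulk [expression_matrix()] or genes x samples matrix.
#' @param proportions A `proportion_estimate` or samples x states matrix.
#' @param alpha L1 penalty (lasso lambda; default 1e-4).
#' @return An `imputed_expression`: list with `values` (genes x states,
#'   all entries >= 0) and `alpha`.
#' @export
impute_state_expression <- function(bulk, proportions, alpha = 1e-4) {
  x <- em_values(bulk)
  P <- if (inherits(proportions, "proportion_estimate"))
    proportions$proportions else as.matrix(proportions)
  if (nrow(P) != ncol(x))
    stop("proportions rows must align with bulk samples")
  if (qr(P)$rank < ncol(P))
    warning("proportion matrix is rank deficient; coefficients may be unstable")
  lam <- alpha * c(100, 10, 1)
  out <- matrix(0, nrow(x), ncol(P),
                dimnames = list(rownames(x), colnames(P)))
  for (g in seq_len(nrow(x))) {
    fit <- glmnet::glmnet(P, x[g, ], family = "gaussian", lambda = lam,
                          lower.limits = 0, intercept = FALSE,
                          standardize = FALSE)
    out[g, ] <- as.numeric(stats::coef(fit, s = alpha))[-1]
  }
  out[out < 0] <- 0
  structure(list(values = out, alpha = alpha), class = "imputed_expression")
}

#' @export
print.imputed_expression <- function(x, ...) {
  cat(sprintf("<imputed_expression> %d genes x %d states (alpha %.2g)\n",
              nrow(x$values), ncol(x$values), x$alpha))
  invisible(x)
}
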