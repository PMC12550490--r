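## Phylogenetic generalized least squares of heterozygosity and mean Ne on
## conservation status and habitat area, with Tukey HSD contrasts.

#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j (tip
#' variances on the diagonal); symmetric positive semidefinite.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return The tips-by-tips covariance matrix.
#' @export
brownian_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ape::vcv.phylo(tree)
}

#' Fit a phylogenetic generalized least squares regression
#'
#' Closed-form GLS with Brownian residual covariance `sigma^2 * C`:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, with
#' `sigma^2 = r' C^-1 r / (n - p)` and standard errors from
#' `sigma^2 (X' C^-1 X)^-1`. On a star tree (C proportional to the identity)
#' this reproduces ordinary least squares exactly.
#'
#' @param formula Model formula (variables taken from `data`).
#' @param data Data frame with one row per species and a `species` column
#'   matching the tree's tip labels.
#' @param tree A rooted [ape::phylo]; only tips present in `data` are used.
#' @return A `pgls_fit`: `coefficients` table (estimate, SE, t, p),
#'   `sigma2`, `df.residual`, `residuals`, `fitted`, `vcov`, plus the
#'   inputs.
#' @export
pgls_fit <- function(formula, data, tree) {
  stopifnot(is.data.frame(data), "species" %in% names(data))
  miss <- setdiff(data$species, tree$tip.label)
  if (length(miss)) stop("species not in tree: ", paste(miss, collapse = ", "))
  tree <- ape::keep.tip(tree, data$species)
  C <- brownian_covariance(tree)[data$species, data$species]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more species than parameters")
  Li <- solve(t(chol(C)))        # whitening: Li %*% y has iid errors
  yw <- Li %*% y; Xw <- Li %*% X
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12) stop("singular design matrix")
  beta <- solve(XtX, crossprod(Xw, yw))
  r <- yw - Xw %*% beta
  sigma2 <- sum(r^2) / (n - p)
  V <- sigma2 * solve(XtX)
  se <- sqrt(diag(V))
  tval <- drop(beta) / se
  coefs <- data.frame(estimate = drop(beta), se = se, t = tval,
                      p = 2 * pt(-abs(tval), n - p),
                      row.names = colnames(X))
  structure(list(coefficients = coefs, sigma2 = sigma2, df.residual = n - p,
                 residuals = drop(y - X %*% beta),
                 fitted = drop(X %*% beta), vcov = V, formula = formula,
                 data = data, tree = tree, C = C, X = X),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  cat("sigma^2 =", signif(x$sigma2, 4), " df =", x$df.residual, "\n")
  invisible(x)
}

#' Tukey honestly-significant-difference contrasts on a PGLS factor
#'
#' Pairwise differences of adjusted group means (non-factor covariates held
#' at their mean), with studentized-range adjusted p-values computed from
#' the GLS coefficient covariance.
#'
#' @param fit A [pgls_fit()] result.
#' @param factor Name of a factor/character predictor in the fitted model.
#' @return Data frame `contrast`, `difference`, `se`, `p_adj`.
#' @export
tukey_hsd <- function(fit, factor = "status") {
  stopifnot(inherits(fit, "pgls_fit"))
  vals <- fit$data[[factor]]
  if (is.null(vals)) stop("no column '", factor, "' in the model data")
  lev <- sort(unique(as.character(vals)))
  k <- length(lev)
  if (k < 2L) stop("factor has a single level")
  cn <- colnames(fit$X)
  # contrast vector of the adjusted mean for each level
  mean_row <- colMeans(fit$X)
  rows <- lapply(lev, function(l) {
    v <- mean_row
    hit <- paste0(factor, lev)       # dummy-coded columns for this factor
    v[cn %in% hit] <- 0
    own <- paste0(factor, l)
    if (own %in% cn) v[cn == own] <- 1
    v
  })
  out <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    cvec <- rows[[j]] - rows[[i]]
    diffhat <- drop(cvec %*% fit$coefficients$estimate)
    se <- drop(sqrt(t(cvec) %*% fit$vcov %*% cvec))
    q <- sqrt(2) * abs(diffhat) / se
    out[[length(out) + 1L]] <- data.frame(
      contrast = paste(lev[j], "-", lev[i]), difference = diffhat, se = se,
      p_adj = ptukey(q, nmeans = k, df = fit$df.residual,
                     lower.tail = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the standard comparative model set
#'
#' Three PGLS model classes: (1) `H ~ status + current area` and
#' `mean Ne ~ status + mean past area` on all species; (2) the same models
#' restricted to at-risk species; (3) the status/habitat-availability
#' relationship, fit as area (current, and past mean) regressed on the
#' binary status.
#'
#' @param table Per-species data frame with `species`, `H`, `mean_Ne`,
#'   `status`, `current_area_km2`, `mean_past_area_km2`.
#' @param tree A rooted [ape::phylo] covering the species.
#' @return Named list of [pgls_fit()] objects (entries NULL when a subset is
#'   too small to fit).
#' @export
run_pgls_models <- function(table, tree) {
  safe <- function(f, d) tryCatch(pgls_fit(f, d, tree),
                                  error = function(e) NULL)
  at_risk <- table[table$status == "At risk", , drop = FALSE]
  list(
    m1_H = safe(H ~ status + current_area_km2, table),
    m1_Ne = safe(mean_Ne ~ status + mean_past_area_km2, table),
    m2_H = safe(H ~ current_area_km2, at_risk),
    m2_Ne = safe(mean_Ne ~ mean_past_area_km2, at_risk),
    m3_current = safe(current_area_km2 ~ status, table),
    m3_past = safe(mean_past_area_km2 ~ status, table))
}
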