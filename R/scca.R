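#' The nine-cytokine analysis panel
#'
#' @return Character vector of the cytokines retained for integrative
#'   analysis (fewer than 30% out-of-range readings in the study design this
#'   package targets).
#' @export
cytokine_panel <- function() {
  c("IL-1b", "IL-6", "IL-8", "eotaxin", "TNF-a", "IL-17A", "MIP-1b",
    "IP-10", "RANTES")
}

#' Select cytokines and impute out-of-range values
#'
#' Cytokines whose fraction of out-of-range (below/above limit of detection)
#' readings reaches `max_oor` are dropped; remaining out-of-range values are
#' imputed at the corresponding LOD bound.
#'
#' @param values Samples x cytokines matrix of concentrations (pg/ml).
#' @param flags Character matrix of the same shape: `"in"`, `"below"` or
#'   `"above"`.
#' @param lod_bounds Data.frame or matrix with one row per cytokine and
#'   columns `lo`, `hi` (rownames = cytokine names).
#' @param max_oor Exclusion threshold on the out-of-range fraction
#'   (default 0.30; a cytokine must have FEWER than 30% out-of-range values
#'   to be retained).
#' @return List with `values` (imputed matrix of retained cytokines),
#'   `flags`, and `dropped` (names of excluded cytokines).
#' @export
select_cytokines <- function(values, flags, lod_bounds, max_oor = 0.30) {
  stopifnot(all(dim(values) == dim(flags)))
  oor <- colMeans(flags != "in")
  keep <- oor < max_oor
  dropped <- colnames(values)[!keep]
  v <- values[, keep, drop = FALSE]
  f <- flags[, keep, drop = FALSE]
  for (j in colnames(v)) {
    v[f[, j] == "below", j] <- lod_bounds[j, "lo"]
    v[f[, j] == "above", j] <- lod_bounds[j, "hi"]
  }
  list(values = v, flags = f, dropped = dropped)
}

#' Earliest sample per subject per trimester
#'
#' Trimester boundaries (a documented convention): T1 < 98 days, T2 98-195
#' days, T3 > 195 days. Within each subject-trimester the earliest
#' gestational age is kept, ties broken by lexicographic `sample_id`.
#'
#' @param records Records data.frame.
#' @return Subset of `records`, at most three rows per subject, with an
#'   added `trimester` column (1, 2, 3).
#' @export
trimester_earliest <- function(records) {
  validate_records(records)
  tri <- cut(records$gestational_age, c(-Inf, 97.5, 195.5, Inf),
             labels = FALSE)
  r <- cbind(records, trimester = tri)
  r <- r[order(r$subject_id, r$trimester, r$gestational_age, r$sample_id), ,
         drop = FALSE]
  out <- r[!duplicated(r[, c("subject_id", "trimester")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## soft-threshold toward an l1 constraint: u = S(a, delta)/||S(a, delta)||_2
## with delta >= 0 the smallest value achieving ||u||_1 <= c (binary search)
l1_project <- function(a, c1) {
  soft <- function(d) {
    s <- sign(a) * pmax(abs(a) - d, 0)
    n2 <- sqrt(sum(s^2))
    if (n2 == 0) s else s / n2
  }
  u <- soft(0)
  if (sum(abs(u)) <= c1 + 1e-12) return(u)
  lo <- 0; hi <- max(abs(a))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(abs(soft(mid))) > c1) lo <- mid else hi <- mid
  }
  soft(hi)
}

#' Sparse canonical correlation analysis of two blocks
#'
#' Penalized matrix decomposition of the cross-covariance: per component,
#' alternating soft-thresholded power iterations maximize `u' X'Y v` subject
#' to `||u||_2 <= 1`, `||v||_2 <= 1`, `||u||_1 <= cx`, `||v||_1 <= cy`.
#' Subsequent components are computed on the deflated cross-covariance.
#' Columns are standardized internally (zero-variance columns dropped with a
#' warning); the objective is asserted non-decreasing across iterations, and
#' the sign convention makes the largest-magnitude Y-block (taxa) weight of
#' each component positive.
#'
#' @param X Samples x variables matrix (e.g. log cytokines).
#' @param Y Samples x variables matrix (e.g. log taxa), same rows.
#' @param penalties Length-2 numeric `c(cx, cy)`, l1 bounds on the canonical
#'   vectors (default `c(2, 2)`; the unconstrained bound for a block with p
#'   columns is `sqrt(p)`).
#' @param n_components Number of components (default 2).
#' @param tol Convergence threshold on the successive weight change
#'   (default 1e-7).
#' @param max_iter Iteration cap per component (default 1000).
#' @return An `scca_result`: `x_weights`, `y_weights` (columns per
#'   component, unit l2 norm), `canonical_correlations`, `x_variates`,
#'   `y_variates`, and the retained column names.
#' @export
sparse_cca <- function(X, Y, penalties = c(2, 2), n_components = 2,
                       tol = 1e-7, max_iter = 1000) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must have the same samples")
  if (nrow(X) < 3) stopf("fewer than 3 samples")
  drop0 <- function(M, lab) {
    sdv <- apply(M, 2, stats::sd)
    if (any(sdv == 0)) {
      warnf("dropping zero-variance %s column(s): %s", lab,
            paste(colnames(M)[sdv == 0], collapse = ", "))
      M <- M[, sdv > 0, drop = FALSE]
    }
    scale(M)
  }
  Xs <- drop0(X, "X"); Ys <- drop0(Y, "Y")
  K <- crossprod(Xs, Ys) / (nrow(Xs) - 1)
  px <- ncol(Xs); py <- ncol(Ys)
  U <- matrix(0, px, n_components, dimnames = list(colnames(Xs), NULL))
  V <- matrix(0, py, n_components, dimnames = list(colnames(Ys), NULL))
  for (comp in seq_len(n_components)) {
    sv <- svd(K, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    obj_prev <- -Inf
    for (it in seq_len(max_iter)) {
      u_new <- l1_project(drop(K %*% v), penalties[1])
      v_new <- l1_project(drop(crossprod(K, u_new)), penalties[2])
      obj <- drop(t(u_new) %*% K %*% v_new)
      if (obj < obj_prev - 1e-9)
        stopf("internal error: sCCA objective decreased (%.3g -> %.3g)",
              obj_prev, obj)
      delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
      u <- u_new; v <- v_new; obj_prev <- obj
      if (delta < tol) break
    }
    ## deterministic sign: largest-magnitude taxa (Y-block) weight positive
    sgn <- sign(v[which.max(abs(v))])
    if (sgn < 0) { u <- -u; v <- -v }
    U[, comp] <- u; V[, comp] <- v
    K <- K - drop(t(u) %*% K %*% v) * tcrossprod(u, v)
  }
  xv <- Xs %*% U; yv <- Ys %*% V
  cors <- vapply(seq_len(n_components), function(j) {
    if (stats::sd(xv[, j]) == 0 || stats::sd(yv[, j]) == 0) return(0)
    stats::cor(xv[, j], yv[, j])
  }, numeric(1))
  structure(list(x_weights = U, y_weights = V,
                 canonical_correlations = cors,
                 x_variates = xv, y_variates = yv,
                 x_names = colnames(Xs), y_names = colnames(Ys)),
            class = "scca_result")
}

#' @export
print.scca_result <- function(x, ...) {
  cat(sprintf("scca_result: %d components, canonical correlations %s\n",
              ncol(x$x_weights),
              paste(signif(x$canonical_correlations, 3), collapse = ", ")))
  invisible(x)
}

#' Correlation-circle coordinates
#'
#' Each variable is plotted at (Pearson correlation with its own block's
#' component-1 variate, correlation with the component-2 variate), so
#' strongly positively correlated variables project close together and
#' anticorrelated variables project opposite each other; coordinates lie in
#' the unit disk. `flip_axis1` negates the first coordinate (used to align
#' component orientations across separately fitted groups).
#'
#' @param result An `scca_result`.
#' @param X,Y The (unstandardized) data blocks used for the fit.
#' @param flip_axis1 Negate component-1 coordinates (default FALSE).
#' @return Data.frame with `variable`, `block` ("X"/"Y"), `comp1`, `comp2`.
#' @export
correlation_circle <- function(result, X, Y, flip_axis1 = FALSE) {
  coords <- function(M, variates, block, keep) {
    M <- as.matrix(M)[, keep, drop = FALSE]
    data.frame(variable = colnames(M), block = block,
               comp1 = apply(M, 2, stats::cor, y = variates[, 1]),
               comp2 = apply(M, 2, stats::cor, y = variates[, 2]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(coords(X, result$x_variates, "X", result$x_names),
               coords(Y, result$y_variates, "Y", result$y_names))
  if (flip_axis1) out$comp1 <- -out$comp1
  rownames(out) <- NULL
  out
}
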