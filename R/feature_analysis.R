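#' Trajectory matrix from a fitted parameter table
#'
#' Integrates the fitted efficacy model of every row of a parameter table
#' and samples it on a common time grid (default: 51 uniform points over
#' the 10--60 min post-tetanus window), producing the n x m matrix on
#' which the trajectory PCA operates. Rows whose integration fails are
#' dropped with a warning.
#'
#' @param fits Parameter table as returned by [fit_all_sites()] (columns
#'   `alpha`, `tau`, `gamma_d`, `rho_U`, `rho_0` plus identifiers).
#' @param sample_times Strictly increasing sampling grid in seconds
#'   covering the post-tetanus window.
#' @return Numeric matrix (one row per fitted series) with the surviving
#'   row indices in attribute `row_index` and condition labels in
#'   attribute `labels`.
#' @export
trajectory_matrix <- function(fits,
                              sample_times = seq(600, 3600,
                                                 length.out = 51)) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1L)
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    p <- efficacy_params(fits$alpha[i], fits$tau[i], fits$gamma_d[i],
                         fits$rho_U[i], fits$rho_0[i])
    tryCatch(simulate_efficacy(p, sample_times)$rho, error = function(e) NULL)
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (!all(ok))
    warning("trajectory_matrix: dropped ", sum(!ok),
            " rows with failed integration")
  if (!any(ok)) stop("trajectory_matrix: no row could be integrated")
  m <- do.call(rbind, rows[ok])
  attr(m, "row_index") <- which(ok)
  attr(m, "labels") <- if ("condition" %in% names(fits))
    fits$condition[ok] else rep(NA_character_, sum(ok))
  m
}

#' Principal-component embedding
#'
#' Standard PCA of a feature matrix: columns are mean-centred (no variance
#' scaling -- trajectory columns share units) and the data are projected on
#' the top `n_components` components.
#'
#' @param x Numeric matrix, n >= 3 rows.
#' @param n_components Number of components retained (default 2).
#' @param labels Optional per-row condition labels; defaults to the
#'   `labels` attribute of `x` if present.
#' @return An object of class `feature_embedding`: list with `coordinates`
#'   (n x `n_components`), `loadings` (orthonormal column vectors),
#'   `explained_variance_ratio` (fractions for the retained components,
#'   non-increasing), `sdev` (all singular standard deviations), `center`,
#'   and `labels`.
#' @export
pca_embed <- function(x, n_components = 2L, labels = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 3L) stop("pca_embed: need at least 3 rows")
  if (n_components > min(dim(x)))
    stop("pca_embed: n_components (", n_components,
         ") exceeds min(n, m) = ", min(dim(x)))
  if (is.null(labels)) labels <- attr(x, "labels")
  if (is.null(labels)) labels <- rep(NA_character_, nrow(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  evr <- var_all / sum(var_all)
  structure(list(coordinates = pc$x[, seq_len(n_components), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 explained_variance_ratio = evr[seq_len(n_components)],
                 sdev = pc$sdev, center = pc$center,
                 labels = as.character(labels)),
            class = "feature_embedding")
}

#' @export
print.feature_embedding <- function(x, ...) {
  cat(sprintf("Feature embedding: %d rows, %d components (%.1f%% + %.1f%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$explained_variance_ratio[1],
              100 * ifelse(length(x$explained_variance_ratio) > 1,
                           x$explained_variance_ratio[2], 0)))
  invisible(x)
}

#' PCA of fitted parameter vectors
#'
#' Projects the 4-dimensional coefficient vectors
#' \eqn{q = (\alpha, \gamma_d, \rho_U, \rho_0)} of all fitted series to
#' two dimensions. `tau` is excluded: its magnitude (seconds, up to 3600)
#' would dominate the dimensionless coefficients.
#'
#' @param fits Parameter table (see [fit_all_sites()]).
#' @param n_components Number of components retained.
#' @return A `feature_embedding` (see [pca_embed()]).
#' @export
param_pca <- function(fits, n_components = 2L) {
  stopifnot(is.data.frame(fits),
            all(c("alpha", "gamma_d", "rho_U", "rho_0") %in% names(fits)))
  q <- as.matrix(fits[, c("alpha", "gamma_d", "rho_U", "rho_0")])
  if (any(!is.finite(q))) stop("param_pca: non-finite coefficients")
  labels <- if ("condition" %in% names(fits)) fits$condition else NULL
  pca_embed(q, n_components, labels = labels)
}

#' Angle between two vectors
#'
#' \eqn{\theta = \cos^{-1}\!\big(x y^t / \sqrt{(x x^t)(y y^t)}\big)} in
#' degrees, in \[0, 180\].
#'
#' @param x,y Numeric vectors of equal length, both non-zero.
#' @return Angle in degrees, or `NA` if either vector has zero length.
#' @export
angle_between <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  acos(pmin(pmax(sum(x * y) / (nx * ny), -1), 1)) * 180 / pi
}

#' Per-condition centroids, control distances and angles
#'
#' Computes the arithmetic-mean centroid of each condition's 2-D
#' embedding coordinates, the Euclidean distance
#' \eqn{d_i = \sqrt{(c_{i1}-c_{01})^2 + (c_{i2}-c_{02})^2}} of every drug
#' condition's centroid from the control centroid, and the pairwise angles
#' between the control-relative centroid vectors. A condition whose
#' centroid coincides with the control's has a zero-length relative vector;
#' its angles are reported as missing, not zero.
#'
#' @param embedding A `feature_embedding` with condition labels.
#' @param control_label Label of the control condition (default
#'   `"control"`).
#' @return An object of class `centroid_summary`: list with `centroids`
#'   (data frame `condition`, `c1`, `c2`), `control_centroid`, `distances`
#'   (data frame `condition`, `d`, sorted decreasing), and `angles`
#'   (symmetric matrix of pairwise angles in degrees between relative
#'   centroid vectors of the non-control conditions).
#' @export
centroid_summary <- function(embedding, control_label = "control") {
  stopifnot(inherits(embedding, "feature_embedding"))
  labs <- embedding$labels
  if (!control_label %in% labs)
    stop("centroid_summary: control label '", control_label,
         "' not present")
  conds <- unique(labs)
  cent <- t(vapply(conds, function(cc)
    colMeans(embedding$coordinates[labs == cc, , drop = FALSE]),
    numeric(ncol(embedding$coordinates))))
  c0 <- cent[conds == control_label, ]
  drug <- setdiff(conds, control_label)
  rel <- cent[match(drug, conds), , drop = FALSE] -
    matrix(c0, nrow = length(drug), ncol = length(c0), byrow = TRUE)
  d <- sqrt(rowSums(rel^2))
  ang <- matrix(NA_real_, length(drug), length(drug),
                dimnames = list(drug, drug))
  for (i in seq_along(drug)) for (j in seq_along(drug))
    if (i != j) ang[i, j] <- angle_between(rel[i, ], rel[j, ])
  dist_df <- data.frame(condition = drug, d = d, stringsAsFactors = FALSE)
  dist_df <- dist_df[order(-dist_df$d), ]
  rownames(dist_df) <- NULL
  structure(list(centroids = data.frame(condition = conds,
                                        c1 = cent[, 1], c2 = cent[, 2],
                                        stringsAsFactors = FALSE,
                                        row.names = NULL),
                 control_centroid = c0, distances = dist_df,
                 relative = rel, angles = ang),
            class = "centroid_summary")
}

#' @export
print.centroid_summary <- function(x, ...) {
  cat("Centroid summary (distances from control, decreasing):\n")
  print(transform(x$distances, d = signif(d, 4)))
  invisible(x)
}

#' Linear SVM boundary between receptor superclasses
#'
#' Trains a soft-margin linear support vector machine (cost = 1) on the
#' 2-D embedding coordinates to separate the glutamatergic from the
#' GABAergic drug conditions. Control rows are excluded from training.
#'
#' @param embedding A `feature_embedding` with condition labels.
#' @param superclass_map Named character vector mapping condition label to
#'   superclass (`"glutamatergic"`, `"GABAergic"`, or `"control"`;
#'   conditions mapped to `"control"` or absent are excluded). Defaults to
#'   the generator's condition table.
#' @return An object of class `svm_boundary`: list with `weights` (w, the
#'   normal of the decision line `w . x + b = 0`), `bias` (b),
#'   `training_accuracy`, `n` (training rows) and the fitted `e1071::svm`
#'   model.
#' @export
svm_boundary <- function(embedding,
                         superclass_map = NULL) {
  stopifnot(inherits(embedding, "feature_embedding"))
  if (is.null(superclass_map)) {
    tab <- condition_table()
    superclass_map <- stats::setNames(tab$superclass, tab$label)
  }
  super <- superclass_map[embedding$labels]
  keep <- !is.na(super) & super %in% c("glutamatergic", "GABAergic")
  if (length(unique(super[keep])) < 2L)
    stop("svm_boundary: need both glutamatergic and GABAergic rows")
  x <- embedding$coordinates[keep, , drop = FALSE]
  y <- factor(super[keep], levels = c("GABAergic", "glutamatergic"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  acc <- mean(stats::predict(fit, x) == y)
  structure(list(weights = w, bias = b, training_accuracy = acc,
                 n = nrow(x), model = fit),
            class = "svm_boundary")
}

#' @export
print.svm_boundary <- function(x, ...) {
  cat(sprintf("Linear SVM boundary: w = (%.4g, %.4g), b = %.4g, training accuracy %.3f (n = %d)\n",
              x$weights[1], x$weights[2], x$bias, x$training_accuracy, x$n))
  invisible(x)
}

#' Spatial parameter dispersion per condition
#'
#' For each condition, the sample standard deviation of the fitted
#' `gamma_d` and `rho_U` across its electrode sites (the spatial scatter
#' of the depression rate and of the basin separation), and the Pearson
#' correlation between the two dispersion vectors across conditions.
#' Conditions with fewer than two sites have undefined dispersion (`NA`)
#' and are excluded from the correlation.
#'
#' @param fits Parameter table (see [fit_all_sites()]).
#' @return An object of class `dispersion_summary`: list with `table`
#'   (data frame `condition`, `n_sites`, `delta_gamma_d`, `delta_rho_U`)
#'   and `correlation_r` (Pearson r).
#' @export
dispersion_summary <- function(fits) {
  stopifnot(is.data.frame(fits),
            all(c("condition", "gamma_d", "rho_U") %in% names(fits)))
  conds <- unique(fits$condition)
  tab <- do.call(rbind, lapply(conds, function(cc) {
    sub <- fits[fits$condition == cc, ]
    n <- nrow(sub)
    data.frame(condition = cc, n_sites = n,
               delta_gamma_d = if (n >= 2L) stats::sd(sub$gamma_d) else NA_real_,
               delta_rho_U = if (n >= 2L) stats::sd(sub$rho_U) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ok <- stats::complete.cases(tab[, c("delta_gamma_d", "delta_rho_U")])
  r <- if (sum(ok) >= 3L)
    stats::cor(tab$delta_gamma_d[ok], tab$delta_rho_U[ok],
               method = "pearson") else NA_real_
  structure(list(table = tab, correlation_r = r),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat("Per-condition parameter dispersion across sites:\n")
  print(transform(x$table, delta_gamma_d = signif(delta_gamma_d, 4),
                  delta_rho_U = signif(delta_rho_U, 4)))
  cat(sprintf("Pearson r(delta_gamma_d, delta_rho_U) = %.3f\n",
              x$correlation_r))
  invisible(x)
}
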