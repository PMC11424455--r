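# Minimal embedding constructor for geometry tests.
fake_embedding <- function(coords, labels) {
  structure(list(coordinates = coords,
                 loadings = diag(ncol(coords)),
                 explained_variance_ratio = rep(NA_real_, ncol(coords)),
                 labels = labels),
            class = "feature_embedding")
}

fit_row <- function(alpha, tau, gamma_d, rho_U, rho_0, condition = "c") {
  data.frame(condition = condition, slice_id = "s", site_row = 0L,
             site_col = 1L, alpha = alpha, tau = tau, gamma_d = gamma_d,
             rho_U = rho_U, rho_0 = rho_0, stringsAsFactors = FALSE)
}

test_that("trajectory matrices sample the fitted models on a common grid", {
  one <- trajectory_matrix(fit_row(0.3, 601, 0.5, 1.2, 0.5))
  expect_equal(dim(one), c(1L, 51L))
  expect_equal(one[1, 1], 0.5)
  two <- trajectory_matrix(rbind(fit_row(0.3, 601, 0.5, 1.2, 0.5),
                                 fit_row(0.3, 601, 0.5, 1.2, 0.5)))
  expect_equal(two[1, ], two[2, ])
  # fast monostable relaxation approaches alpha along the row
  fast <- trajectory_matrix(fit_row(0.3, 301, 3.0, 1.0, 1.2))
  expect_lt(abs(fast[1, 51] - 0.3), 1e-3)
  expect_true(all(diff(fast[1, ]) <= 1e-12))
})

test_that("the PCA embedding has the standard algebraic properties", {
  withr::with_seed(31, {
    # rank-1 data: one component carries all variance
    v <- rnorm(20)
    x1 <- outer(rnorm(8), v) + matrix(rnorm(20), 8, 20, byrow = TRUE) * 0
    emb1 <- pca_embed(x1)
    expect_equal(emb1$explained_variance_ratio[1], 1.0, tolerance = 1e-10)

    x <- matrix(rnorm(9 * 12), 9, 12)
    x[5, ] <- x[2, ]  # duplicated rows map to identical coordinates
    emb <- pca_embed(x)
    expect_equal(emb$coordinates[5, ], emb$coordinates[2, ])
    expect_true(all(diff(emb$explained_variance_ratio) <= 1e-12))
    expect_true(all(emb$explained_variance_ratio >= 0 &
                      emb$explained_variance_ratio <= 1))
    # loadings are orthonormal; all components reconstruct the data
    full <- pca_embed(x, n_components = 9)
    expect_equal(crossprod(full$loadings), diag(9), tolerance = 1e-10,
                 ignore_attr = TRUE)
    recon <- full$coordinates %*% t(full$loadings)
    centered <- sweep(x, 2, colMeans(x))
    expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sum(full$sdev^2 / sum(full$sdev^2)), 1)
    expect_error(pca_embed(x, n_components = 13), "n_components")
    expect_error(pca_embed(x[1:2, ]), "3 rows")

    # row order only permutes coordinates, up to component sign
    perm <- sample(nrow(x))
    emb_p <- pca_embed(x[perm, ])
    for (j in 1:2) {
      s <- sign(sum(emb_p$coordinates[, j] * emb$coordinates[perm, j]))
      expect_equal(s * emb_p$coordinates[, j], emb$coordinates[perm, j],
                   tolerance = 1e-8)
    }
  })
})

test_that("centroid geometry matches hand-computed distances and angles", {
  coords <- rbind(c(0, 0), c(0, 0),    # control at origin
                  c(3, 4), c(3, 4),    # drug A at (3, 4)
                  c(1, 0), c(0, 1),    # drug B centroid (0.5, 0.5)
                  c(0, 0))             # drug C on the control centroid
  labs <- c("control", "control", "A", "A", "B", "B", "C")
  cs <- centroid_summary(fake_embedding(coords, labs))
  expect_equal(cs$control_centroid, c(0, 0), ignore_attr = TRUE)
  expect_equal(cs$distances$d[cs$distances$condition == "A"], 5)   # 3-4-5
  expect_equal(cs$distances$d[cs$distances$condition == "C"], 0)
  # zero-length relative vector: angle undefined, not zero
  expect_true(all(is.na(cs$angles["C", ])))
  expect_equal(angle_between(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_between(c(2, 0), c(1, 0)), 0)
  expect_equal(angle_between(c(1, 0), c(-2, 0)), 180)
  expect_true(is.na(angle_between(c(0, 0), c(1, 0))))
  expect_error(centroid_summary(fake_embedding(coords, labs),
                                control_label = "nope"), "control")
})

test_that("distances and angle magnitudes survive component sign flips", {
  withr::with_seed(17, {
    coords <- matrix(rnorm(40, sd = 3), 20, 2)
    labs <- rep(c("control", "A", "B", "C"), 5)
    a <- centroid_summary(fake_embedding(coords, labs))
    flipped <- coords
    flipped[, 2] <- -flipped[, 2]
    b <- centroid_summary(fake_embedding(flipped, labs))
    expect_equal(a$distances, b$distances)
    expect_equal(abs(cos(a$angles * pi / 180)),
                 abs(cos(b$angles * pi / 180)), tolerance = 1e-12)
  })
})

test_that("the SVM boundary separates separable clusters and reports w, b", {
  withr::with_seed(13, {
    n <- 20
    coords <- rbind(cbind(rnorm(n, 5, 0.1), rnorm(n, 0, 0.1)),
                    cbind(rnorm(n, -5, 0.1), rnorm(n, 0, 0.1)))
    labs <- rep(c("D-AP5", "muscimol"), each = n)
    emb <- fake_embedding(coords, labs)
    sv <- svm_boundary(emb)
    expect_equal(sv$training_accuracy, 1.0)
    # the reported (w, b) reproduce the decision rule
    dec <- drop(coords %*% sv$weights) + sv$bias
    pred <- stats::predict(sv$model, coords)
    expect_true(all((dec > 0) == (pred == "glutamatergic")))
    # single superclass is rejected
    expect_error(svm_boundary(fake_embedding(coords, rep("D-AP5", 2 * n))),
                 "both")
    # random labels give near-chance training accuracy
    accs <- replicate(30, {
      sh <- sample(labs)
      svm_boundary(fake_embedding(coords, sh))$training_accuracy
    })
    expect_lt(abs(mean(accs) - 0.5), 0.15)
  })
})

test_that("parameter PCA embeds the 4-D coefficient vectors, excluding tau", {
  withr::with_seed(19, {
    fits <- do.call(rbind, lapply(1:10, function(i)
      fit_row(runif(1, 0.1, 0.6), sample(c(1, 601, 3600), 1),
              runif(1, 0.1, 6), runif(1, 0.7, 1.9), runif(1, 0.1, 1))))
    emb <- param_pca(fits)
    expect_equal(dim(emb$coordinates), c(10L, 2L))
    # tau plays no role: changing it leaves the embedding unchanged
    fits2 <- fits
    fits2$tau <- 1
    expect_equal(param_pca(fits2)$coordinates, emb$coordinates)
  })
})

test_that("dispersion summarises site scatter and its correlation", {
  base <- do.call(rbind, lapply(1:8, function(i)
    fit_row(0.3, 601, 0.5, 1.2, 0.5, condition = "A")))
  d <- dispersion_summary(base)
  expect_equal(d$table$delta_gamma_d, 0)
  expect_equal(d$table$delta_rho_U, 0)
  # hand value: sd of (0.1 x4, 0.5 x4) = 0.2138
  base$gamma_d <- rep(c(0.1, 0.5), each = 4)
  expect_equal(dispersion_summary(base)$table$delta_gamma_d, 0.2138090,
               tolerance = 1e-6)
  # proportional dispersion vectors give r = 1
  tabs <- do.call(rbind, lapply(1:4, function(k) {
    f <- do.call(rbind, lapply(1:8, function(i)
      fit_row(0.3, 601, 0.5, 1.2, 0.5, condition = paste0("c", k))))
    f$gamma_d <- 0.5 + k * 0.1 * scale(1:8)[, 1]
    f$rho_U <- 1.2 + k * 0.05 * scale(1:8)[, 1]
    f
  }))
  expect_equal(dispersion_summary(tabs)$correlation_r, 1.0)
  # a single-site condition has undefined dispersion
  solo <- dispersion_summary(rbind(base, fit_row(0.3, 1, 1, 1.2, 0.5,
                                                 condition = "solo")))
  expect_true(is.na(solo$table$delta_gamma_d[solo$table$condition == "solo"]))
})

test_that("injected site scatter is recovered by the dispersion summary", {
  sigmas <- seq(0.05, 0.35, by = 0.05)
  mk_preset <- function(i) {
    structure(list(label = paste0("p", i), superclass = "control",
                   params = efficacy_params(0.3, 1801, 2.0, 1.2, 0.5),
                   ri_5 = 0.2, ri_anchors = c("5" = 0.2),
                   site_scatter = c(gamma_d = sigmas[i], rho_U = sigmas[i]),
                   recovery_min = 15),
              class = "condition_preset")
  }
  presets <- lapply(seq_along(sigmas), mk_preset)
  names(presets) <- paste0("p", seq_along(sigmas))
  ratios <- matrix(0, length(sigmas), 20)
  rs <- numeric(20)
  for (s in 1:20) {
    ds <- simulate_ri_dataset(presets,
                              generator_config(seed = 100 + s,
                                               snap_to_grid = FALSE))
    d <- dispersion_summary(ds$truth)
    ratios[, s] <- d$table$delta_gamma_d / sigmas
    rs[s] <- d$correlation_r
  }
  med <- apply(ratios, 1, median)
  expect_true(all(med >= 0.7 & med <= 1.3))
  # proportional injected scatters imply a strong positive correlation
  expect_gt(median(rs), 0.7)
})
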