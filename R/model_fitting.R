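#' Six-point ratio-index time course for one electrode site
#'
#' A ratio-index (RI) series holds the post-tetanus LFP depression readout
#' at the six anchors t = 10, 20, ..., 60 min, together with the electrode
#' site coordinates and the pharmacological condition label. The 10-min
#' value doubles as the initial efficacy `rho_0` when the series is fitted.
#'
#' @param ri Numeric vector of six non-negative RI values (fractions, not
#'   percent) at t = 10, 20, ..., 60 min after tetanic stimulation.
#' @param condition Condition label (character), e.g. `"control"`.
#' @param slice_id Slice identifier.
#' @param site_row,site_col Electrode grid coordinates relative to the
#'   tetanised site at (0, 0) (150 um pitch).
#' @return An object of class `ri_series`.
#' @export
ri_series <- function(ri, condition = NA_character_, slice_id = NA_character_,
                      site_row = NA_integer_, site_col = NA_integer_) {
  if (!is.numeric(ri) || length(ri) != 6L)
    stop("ri_series: need the six anchors t = 10, 20, ..., 60 min; got ",
         length(ri), " values")
  if (any(!is.finite(ri)))
    stop("ri_series: RI values must be finite; missing anchors at t = ",
         paste(seq(10, 60, 10)[!is.finite(ri)], collapse = ", "), " min")
  if (any(ri < 0))
    stop("ri_series: RI is a ratio of peak magnitudes and cannot be negative")
  structure(list(times_min = seq(10, 60, by = 10), ri = as.numeric(ri),
                 condition = as.character(condition),
                 slice_id = as.character(slice_id),
                 site_row = as.integer(site_row),
                 site_col = as.integer(site_col)),
            class = "ri_series")
}

#' @export
print.ri_series <- function(x, ...) {
  cat(sprintf("RI series [%s, slice %s, site (%s, %s)]\n", x$condition,
              x$slice_id, x$site_row, x$site_col))
  print(stats::setNames(round(x$ri, 4), paste0(x$times_min, "min")))
  invisible(x)
}

.ri_anchor_seconds <- seq(600, 3600, by = 600)

#' Fitting grid for the synaptic-efficacy model
#'
#' Builds the exhaustive candidate grid over which the model coefficients
#' are searched: `alpha` from 0.1 to 0.6 in steps of 0.05, `tau` from 1 to
#' 3600 s in steps of 300 s (the last value clamped to 3600 s), `gamma_d`
#' from 0.1 to 6.0 in steps of 0.1, and `rho_U` from the smallest multiple
#' of `rho_U_step` strictly above each `alpha` up to 1.9 (the strict
#' `rho_U < 2` bound). All candidates respect `0 < alpha < rho_U < 2`.
#'
#' @param alpha_values,tau_values,gamma_d_values Numeric grids; defaults as
#'   above.
#' @param rho_U_step Step of the per-`alpha` `rho_U` grid (default 0.1).
#' @param rho_U_max Largest `rho_U` candidate (default 1.9).
#' @param rho_U_values Optional explicit `rho_U` grid overriding the
#'   per-`alpha` rule; values not satisfying `alpha < rho_U < 2` are
#'   dropped per `alpha`.
#' @return An object of class `parameter_grid`: the four grid definitions
#'   plus a `candidates` data frame (columns `alpha`, `tau`, `gamma_d`,
#'   `rho_U`) in fixed lexicographic enumeration order.
#' @export
parameter_grid <- function(alpha_values = seq(0.1, 0.6, by = 0.05),
                           tau_values = c(seq(1, 3600, by = 300), 3600),
                           gamma_d_values = seq(0.1, 6.0, by = 0.1),
                           rho_U_step = 0.1,
                           rho_U_max = 1.9,
                           rho_U_values = NULL) {
  tau_values <- sort(unique(pmin(tau_values, 3600)))
  alpha_values <- round(alpha_values, 10)     # strip seq() dust so grid
  gamma_d_values <- round(gamma_d_values, 10) # values are exact decimals
  stopifnot(length(alpha_values) > 0, length(tau_values) > 0,
            length(gamma_d_values) > 0, rho_U_step > 0)
  if (any(alpha_values <= 0) || any(tau_values <= 0) ||
      any(gamma_d_values <= 0))
    stop("parameter_grid: all grid values must be positive")
  rho_U_for <- function(a) {
    v <- if (!is.null(rho_U_values)) {
      sort(rho_U_values)
    } else {
      k <- a / rho_U_step
      k0 <- if (abs(k - round(k)) < 1e-8) round(k) + 1 else ceiling(k)
      round(seq(k0, round(rho_U_max / rho_U_step + 1e-8)) * rho_U_step, 10)
    }
    v[v > a & v < 2]
  }
  blocks <- lapply(sort(alpha_values), function(a) {
    rU <- rho_U_for(a)
    if (length(rU) == 0L) return(NULL)
    expand.grid(rho_U = rU, gamma_d = sort(gamma_d_values),
                tau = tau_values, alpha = a,
                KEEP.OUT.ATTRS = FALSE)[, c("alpha", "tau", "gamma_d", "rho_U")]
  })
  cands <- do.call(rbind, blocks)
  if (is.null(cands) || nrow(cands) == 0L)
    stop("parameter_grid: grid is empty after enforcing alpha < rho_U < 2")
  cands <- cands[order(cands$alpha, cands$tau, cands$gamma_d, cands$rho_U), ]
  rownames(cands) <- NULL
  structure(list(alpha_values = sort(alpha_values), tau_values = tau_values,
                 gamma_d_values = sort(gamma_d_values),
                 rho_U_step = rho_U_step, rho_U_max = rho_U_max,
                 candidates = cands),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("Efficacy fitting grid: %d candidates (%d alpha x %d tau x %d gamma_d, rho_U per alpha)\n",
              nrow(x$candidates), length(x$alpha_values),
              length(x$tau_values), length(x$gamma_d_values)))
  invisible(x)
}

#' Error function of a candidate parameter set on an RI series
#'
#' The fitting objective: the model trajectory is integrated from
#' `rho_0` at t = 600 s and sampled at the six anchors t = 600, 1200, ...,
#' 3600 s; the error is the sum of absolute residuals
#' \eqn{EF = \sum_{i=1}^{6} |\rho(600 i) - RI(10 i\,\mathrm{min})|}.
#' The i = 1 term is included even though it vanishes whenever
#' `rho_0 = RI(10)`.
#'
#' @param params An [efficacy_params] object.
#' @param series An [ri_series] object.
#' @return The dimensionless error `EF` (non-negative scalar).
#' @export
ef_error <- function(params, series) {
  stopifnot(inherits(params, "efficacy_params"), inherits(series, "ri_series"))
  traj <- simulate_efficacy(params, .ri_anchor_seconds)
  sum(abs(traj$rho - series$ri))
}

# Fixed-step exponential-Euler sweep of EF over all candidates at once.
# The drift factors as -(rho - alpha) * g(rho) / tau with
# g(rho) = (2 - rho)(rho_U - rho) + gamma_d, so the frozen-coefficient
# update rho <- alpha + (rho - alpha) exp(-g(rho) dt / tau) is
# unconditionally stable (small tau candidates collapse to alpha instead of
# overflowing) and exact wherever g is locally constant.
.search_ef <- function(cands, rho_0, ri, dt = 10) {
  n_sub <- as.integer(round(600 / dt))
  r <- rep_len(rho_0, nrow(cands))
  a <- cands$alpha; tau <- cands$tau; gd <- cands$gamma_d; rU <- cands$rho_U
  ef <- abs(r - ri[1L])
  for (i in 2:6) {
    for (s in seq_len(n_sub)) {
      g <- (2 - r) * (rU - r) + gd
      r <- a + (r - a) * exp(-g * dt / tau)
    }
    ef <- ef + abs(r - ri[i])
  }
  ef
}

#' Fit the synaptic-efficacy model to one RI series by grid search
#'
#' `rho_0` is fixed to the series' 10-min value; the remaining four
#' coefficients are searched exhaustively over the grid. A fast fixed-step
#' exponential-Euler sweep (dt = 10 s) ranks all candidates, the candidates
#' within `rescore_margin` of the provisional minimum (at most `rescore_k`)
#' are re-scored against [ef_error] at the adaptive solver's tight
#' tolerance, and the exact minimiser is returned. Candidates whose exact
#' `EF` lies within `tie_tol` of the minimum count as ties; among ties the
#' lexicographically smallest `(alpha, tau, gamma_d, rho_U)` wins, so the
#' result is deterministic and independent of enumeration order.
#'
#' @param series An [ri_series] object.
#' @param grid A [parameter_grid] object.
#' @param rescore_k Maximum number of candidates re-scored exactly.
#' @param rescore_margin Search-EF margin above the provisional minimum
#'   within which candidates are re-scored.
#' @param tie_tol Absolute EF tolerance defining ties.
#' @return An object of class `ef_fit`: list with `params`
#'   ([efficacy_params]), `ef` (exact minimal error), `n_candidates`
#'   (grid size evaluated) and `ties` (count of EF-equivalent candidates
#'   among those re-scored).
#' @export
fit_grid <- function(series, grid, rescore_k = 50, rescore_margin = 0.02,
                     tie_tol = 1e-12) {
  stopifnot(inherits(series, "ri_series"), inherits(grid, "parameter_grid"))
  cands <- grid$candidates
  if (nrow(cands) == 0L) stop("fit_grid: empty parameter grid")
  rho_0 <- max(series$ri[1L], 1e-6)
  ef_s <- .search_ef(cands, rho_0, series$ri)
  # bucket the provisional EF well below its own accuracy so that exact
  # ties are enumerated in lexicographic order, not floating-point order
  ef_b <- round(ef_s, 9)
  ord <- order(ef_b, cands$alpha, cands$tau, cands$gamma_d, cands$rho_U)
  keep <- ord[ef_s[ord] <= ef_s[ord[1L]] + rescore_margin]
  keep <- keep[seq_len(min(length(keep), rescore_k))]
  ef_x <- vapply(keep, function(i) {
    p <- efficacy_params(cands$alpha[i], cands$tau[i], cands$gamma_d[i],
                         cands$rho_U[i], rho_0)
    ef_error(p, series)
  }, numeric(1))
  tie <- which(ef_x <= min(ef_x) + tie_tol)
  sub <- cands[keep[tie], , drop = FALSE]
  pick <- tie[order(sub$alpha, sub$tau, sub$gamma_d, sub$rho_U)[1L]]
  best <- keep[pick]
  structure(list(params = efficacy_params(cands$alpha[best], cands$tau[best],
                                          cands$gamma_d[best],
                                          cands$rho_U[best], rho_0),
                 ef = ef_x[pick], n_candidates = nrow(cands),
                 ties = length(tie)),
            class = "ef_fit")
}

#' @export
print.ef_fit <- function(x, ...) {
  cat(sprintf("Grid fit: EF = %.6g over %d candidates (%d tie%s)\n", x$ef,
              x$n_candidates, x$ties, if (x$ties == 1L) "" else "s"))
  print(x$params)
  invisible(x)
}

#' Fit every RI series of a dataset
#'
#' Applies [fit_grid] to each series of a dataset keyed by condition, slice
#' and site, and assembles the per-site parameter table used by all
#' downstream analyses. Individual failures are recorded and reported as a
#' warning, never fatal.
#'
#' @param dataset Either a list of [ri_series] objects or a long-format
#'   data frame with columns `condition`, `slice_id`, `site_row`,
#'   `site_col`, `t_min`, `ri` (six anchor rows per site).
#' @param grid A [parameter_grid] object.
#' @param ... Passed on to [fit_grid].
#' @return A data frame with one row per fitted series and columns
#'   `condition`, `slice_id`, `site_row`, `site_col`, `alpha`, `tau`,
#'   `gamma_d`, `rho_U`, `rho_0`, `ef`, `stability_class`, `discriminant`.
#'   Failed series are listed in the `failures` attribute (a data frame of
#'   keys and error messages).
#' @export
fit_all_sites <- function(dataset, grid = parameter_grid(), ...) {
  series_list <- if (is.data.frame(dataset)) ri_table_to_series(dataset)
                 else dataset
  stopifnot(all(vapply(series_list, inherits, logical(1), "ri_series")))
  rows <- vector("list", length(series_list))
  fails <- list()
  for (k in seq_along(series_list)) {
    s <- series_list[[k]]
    res <- tryCatch(fit_grid(s, grid, ...), error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(condition = s$condition, slice_id = s$slice_id,
                   site_row = s$site_row, site_col = s$site_col,
                   message = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    p <- res$params
    fp <- fixed_points(p)
    rows[[k]] <- data.frame(condition = s$condition, slice_id = s$slice_id,
                            site_row = s$site_row, site_col = s$site_col,
                            alpha = p$alpha, tau = p$tau,
                            gamma_d = p$gamma_d, rho_U = p$rho_U,
                            rho_0 = p$rho_0, ef = res$ef,
                            stability_class = fp$stability_class,
                            discriminant = fp$discriminant,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(condition = character(), slice_id = character(),
                      site_row = integer(), site_col = integer(),
                      alpha = numeric(), tau = numeric(), gamma_d = numeric(),
                      rho_U = numeric(), rho_0 = numeric(), ef = numeric(),
                      stability_class = character(),
                      discriminant = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(condition = character(), slice_id = character(),
               site_row = integer(), site_col = integer(),
               message = character(), stringsAsFactors = FALSE)
  if (nrow(failures))
    warning("fit_all_sites: ", nrow(failures), " series failed to fit; ",
            "see attr(, 'failures')")
  attr(out, "failures") <- failures
  out
}

#' Convert a long RI table to a list of RI series
#'
#' @param df Long-format data frame with columns `condition`, `slice_id`,
#'   `site_row`, `site_col`, `t_min`, `ri`.
#' @return Named list of [ri_series] objects, keyed
#'   `condition/slice_id/site_row/site_col`, in first-appearance order.
#' @export
ri_table_to_series <- function(df) {
  need <- c("condition", "slice_id", "site_row", "site_col", "t_min", "ri")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ri_table_to_series: missing columns ", paste(miss, collapse = ", "))
  key <- interaction(df$condition, df$slice_id, df$site_row, df$site_col,
                     drop = TRUE, lex.order = TRUE, sep = "/")
  idx <- split(seq_len(nrow(df)), key)
  idx <- idx[order(vapply(idx, min, integer(1)))]  # first-appearance order
  lapply(idx, function(i) {
    sub <- df[i, ][order(df$t_min[i]), ]
    anchors <- seq(10, 60, by = 10)
    pos <- match(anchors, sub$t_min)
    if (anyNA(pos))
      stop("ri_table_to_series: series ", as.character(key[i[1]]),
           " is missing anchors at t = ",
           paste(anchors[is.na(pos)], collapse = ", "), " min")
    ri_series(sub$ri[pos], condition = sub$condition[1],
              slice_id = sub$slice_id[1], site_row = sub$site_row[1],
              site_col = sub$site_col[1])
  })
}
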