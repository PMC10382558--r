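#' Fit the protonation-gating model to an occupancy-versus-pH table
#'
#' Least-squares fit of the non-cooperative subunit-protonation model to
#' experimental sub-state occupancies. The free parameters (per-class proton
#' dissociation constants `K_H` and/or the brief-closed equilibrium constant
#' `K_OC`) are optimized on the log10 scale; the objective is the (weighted)
#' sum of squared occupancy residuals over all rows and levels of the table.
#'
#' @param data A titration table ([read_titration()] / [predict_titration()]
#'   format): columns `pH`, `C`, `O1`..`Om`, optional `weight`.
#' @param params0 Starting [model_params()]. Its aggregation must produce the
#'   same number of conducting levels as `data` has.
#' @param free Character vector naming the free parameters: `"K_OC"`,
#'   `"K_H"` (frees every site class), or `"K_H:<label>"` for a single
#'   class. Default frees all `K_H` and `K_OC`.
#' @param weights Optional per-row weights (default: the `weight` column if
#'   present, else 1).
#' @param control Passed to [stats::optim()]; sensible tight defaults are
#'   merged in.
#' @return An object of class `"titration_fit"` with methods [print()],
#'   [summary()], [coef()], [predict()], [fitted()], [residuals()],
#'   [deviance()], [plot()] and [simulate()]. Fields include `params` (the
#'   fitted [model_params()]), `convergence` (`TRUE` if the optimizer
#'   reported success), and the per-row, per-level residual matrix.
#' @examples
#' truth <- model_params()   # K_H = 2e-7, K_OC = 0.05
#' tab <- predict_titration(truth, pH = c(6, 6.5, 7, 7.4, 8))
#' start <- model_params(site_class("HBC", 4, 1e-6), K_OC = 0.1)
#' fit <- fit_titration(tab, start)
#' coef(fit)
#' @export
fit_titration <- function(data, params0 = model_params(),
                          free = c("K_H", "K_OC"),
                          weights = NULL, control = list()) {
  data <- validate_titration(data)
  stopifnot(inherits(params0, "model_params"))
  lev <- level_columns(data)
  m_data <- length(lev) - 1L
  if (max(params0$aggregation) != m_data)
    stop("aggregation in 'params0' yields ", max(params0$aggregation),
         " conducting levels but the data have ", m_data)
  free_names <- expand_free(free, params0)
  if (!length(free_names)) stop("no free parameters requested")

  occ <- as.matrix(data[lev])
  distinct <- nrow(unique(round(occ, 12)))
  if (distinct < 2L)
    stop("degenerate data: all occupancy rows are identical")
  if (nrow(data) < length(free_names))
    stop("need at least as many rows (", nrow(data),
         ") as free parameters (", length(free_names), ")")
  if (is.null(weights))
    weights <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  if (length(weights) != nrow(data) || any(!is.finite(weights)) || any(weights < 0))
    stop("'weights' must be non-negative, one per row")

  objective <- function(theta) {
    p <- set_free_params(params0, theta, free_names)
    pred <- predict_occ(p, data$pH)
    sum(weights * rowSums((occ - pred)^2))
  }
  theta0 <- log10(get_free_params(params0, free_names))
  ctl <- utils::modifyList(list(reltol = 1e-14, maxit = 5000), control)
  if (length(theta0) == 1L) {
    opt <- stats::optim(theta0, objective, method = "Brent",
                        lower = -14, upper = 3,
                        control = ctl[setdiff(names(ctl), "reltol")])
  } else {
    opt <- stats::optim(theta0, objective, method = "Nelder-Mead", control = ctl)
    # quasi-Newton polish from the simplex optimum
    opt2 <- tryCatch(stats::optim(opt$par, objective, method = "BFGS",
                                  control = list(reltol = 1e-14)),
                     error = function(e) NULL)
    if (!is.null(opt2) && opt2$value <= opt$value) opt <- opt2
  }
  params <- set_free_params(params0, opt$par, free_names)
  pred <- predict_occ(params, data$pH)
  resid <- occ - pred
  structure(list(params = params, params0 = params0,
                 free = free_names,
                 convergence = identical(opt$convergence, 0L),
                 optim_message = opt$message,
                 sse = opt$value,
                 data = data, weights = weights,
                 fitted_occ = pred, residuals = resid,
                 counts = opt$counts),
            class = "titration_fit")
}

# expand user 'free' spec into canonical names K_H:<label> / K_OC
expand_free <- function(free, params) {
  labels <- vapply(params$site_classes, `[[`, character(1), "label")
  out <- character(0)
  for (f in free) {
    if (f == "K_OC") {
      out <- c(out, "K_OC")
    } else if (f == "K_H") {
      out <- c(out, paste0("K_H:", labels))
    } else if (grepl("^K_H:", f)) {
      lbl <- sub("^K_H:", "", f)
      if (!lbl %in% labels) stop("unknown site class in 'free': ", lbl)
      out <- c(out, f)
    } else {
      stop("unknown free parameter: ", f)
    }
  }
  unique(out)
}

get_free_params <- function(params, free_names) {
  labels <- vapply(params$site_classes, `[[`, character(1), "label")
  vapply(free_names, function(f) {
    if (f == "K_OC") params$K_OC
    else params$site_classes[[match(sub("^K_H:", "", f), labels)]]$K_H
  }, numeric(1))
}

set_free_params <- function(params, theta, free_names) {
  labels <- vapply(params$site_classes, `[[`, character(1), "label")
  vals <- 10^theta
  for (i in seq_along(free_names)) {
    f <- free_names[i]
    if (f == "K_OC") params$K_OC <- vals[i]
    else params$site_classes[[match(sub("^K_H:", "", f), labels)]]$K_H <- vals[i]
  }
  params
}

# occupancy matrix (rows = pH) without data-frame overhead
predict_occ <- function(params, pH) {
  t(vapply(pH,
           function(p) aggregate_levels(state_distribution(params, p),
                                        params$aggregation),
           numeric(max(params$aggregation) + 1L)))
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Protonation-gating titration fit\n")
  cat(sprintf("  %d pH points, %d levels, %d free parameter(s)\n",
              nrow(x$data), ncol(x$residuals), length(x$free)))
  cf <- coef(x)
  for (nm in names(cf)) cat(sprintf("  %-12s %.6g\n", nm, cf[[nm]]))
  cat(sprintf("  weighted SSE %.4g | converged: %s\n", x$sse, x$convergence))
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) {
  labels <- vapply(object$params$site_classes, `[[`, character(1), "label")
  c(stats::setNames(
    vapply(object$params$site_classes, `[[`, numeric(1), "K_H"),
    paste0("K_H.", labels)),
    stats::setNames(object$params$K_OC, "K_OC"))
}

#' @export
deviance.titration_fit <- function(object, ...) object$sse

#' @export
fitted.titration_fit <- function(object, ...) object$fitted_occ

#' @export
residuals.titration_fit <- function(object, ...) object$residuals

#' @export
predict.titration_fit <- function(object, pH = NULL, ...) {
  if (is.null(pH)) pH <- object$data$pH
  predict_titration(object$params, pH)
}

#' @export
summary.titration_fit <- function(object, ...) {
  rr <- sqrt(rowSums(object$residuals^2))
  structure(list(fit = object,
                 coef = coef(object),
                 pKa = -log10(coef(object)[grep("^K_H", names(coef(object)))]),
                 row_rmse = stats::setNames(rr, object$data$pH),
                 sse = object$sse,
                 convergence = object$convergence),
            class = "summary.titration_fit")
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  print(x$fit)
  cat("  apparent pKa:", paste(format(x$pKa, digits = 4), collapse = " "), "\n")
  cat("  per-row residual norm:\n")
  print(round(x$row_rmse, 5))
  invisible(x)
}

#' Plot a titration fit
#'
#' Occupancy of each level versus pH: data as points, model prediction on a
#' fine pH grid as lines.
#'
#' @param x A `"titration_fit"`.
#' @param n_grid Number of pH grid points for the curves.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.titration_fit <- function(x, n_grid = 121L, ...) {
  lev <- level_columns(x$data)
  grid <- seq(min(x$data$pH), max(x$data$pH), length.out = n_grid)
  pred <- predict_occ(x$params, grid)
  cols <- seq_along(lev)
  graphics::matplot(grid, pred, type = "l", lty = 1, col = cols,
                    xlab = "pH", ylab = "occupancy",
                    ylim = c(0, 1), ...)
  graphics::matpoints(x$data$pH, as.matrix(x$data[lev]), pch = 16, col = cols)
  graphics::legend("left", legend = lev, col = cols, lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Simulate noisy titration tables from a fitted model
#'
#' Draws occupancy tables at the fitted parameters with additive Gaussian
#' occupancy noise, truncated at zero and renormalized row-wise (a simple
#' error model for finite-recording occupancy estimates).
#'
#' @param object A `"titration_fit"`.
#' @param nsim Number of tables.
#' @param seed Optional RNG seed.
#' @param sd Occupancy noise standard deviation.
#' @param ... Unused.
#' @return A list of `nsim` titration tables.
#' @export
simulate.titration_fit <- function(object, nsim = 1, seed = NULL, sd = 0.02,
                                   ...) {
  if (!is.null(seed)) set.seed(seed)
  lev <- level_columns(object$data)
  base <- predict_occ(object$params, object$data$pH)
  lapply(seq_len(nsim), function(i) {
    noisy <- pmax(base + matrix(stats::rnorm(length(base), 0, sd),
                                nrow(base)), 0)
    noisy <- noisy / rowSums(noisy)
    out <- data.frame(pH = object$data$pH, noisy, check.names = FALSE)
    names(out) <- c("pH", lev)
    class(out) <- c("titration_table", "data.frame")
    out
  })
}
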