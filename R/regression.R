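ssi_predictors <- c("sffi", "apl", "diameter", "acc", "transitivity",
                    "modularity")

#' Pairwise correlations among topology metrics and SSI
#'
#' Pearson correlation for every pair of columns among the response `ssi`
#' and the topology predictors present in `observations`, plus a
#' long-format table suitable for scatterplot matrices. Constant columns
#' yield `NA` correlations and are flagged with a warning.
#'
#' @param observations A `data.frame` with a numeric `ssi` column and any
#'   of `sffi`, `apl`, `diameter`, `acc`, `transitivity`, `modularity`
#'   (e.g. the output of [topology_ssi_study()]).
#' @return A list with `r` (correlation matrix) and `pairs` (long-format
#'   `data.frame` with columns `var_x`, `var_y`, `x`, `y`).
#' @export
correlation_matrix <- function(observations) {
  vars <- intersect(c("ssi", ssi_predictors), names(observations))
  if (nrow(observations) < 3) stop("need at least 3 observations")
  X <- observations[vars]
  const <- vapply(X, function(v) stats::var(v, na.rm = TRUE) == 0, FALSE)
  if (any(const)) {
    warning("constant column(s), correlations undefined: ",
            paste(vars[const], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  pairs <- do.call(rbind, lapply(seq_along(vars), function(i) {
    do.call(rbind, lapply(seq_along(vars), function(j) {
      if (i >= j) return(NULL)
      data.frame(var_x = vars[i], var_y = vars[j],
                 x = X[[i]], y = X[[j]], stringsAsFactors = FALSE)
    }))
  }))
  list(r = r, pairs = pairs)
}

#' Regression of equilibrium SSI on network topology
#'
#' Ordinary least squares of `ssi` on the topology metrics, followed by
#' backward elimination: at each pass the predictor with the largest
#' partial-F p-value above `alpha` is removed and the model refitted, until
#' every remaining predictor is significant at `alpha`. Aliased
#' (rank-deficient) columns are dropped with a warning before fitting.
#' Redundant predictors -- e.g. transitivity, clustering coefficient and
#' modularity, which are strongly collinear across tunable-transitivity
#' network families -- are thereby pruned to the subset that carries the
#' signal.
#'
#' @param observations As in [correlation_matrix()]; one row per network.
#' @param alpha Significance level for the partial F-tests (default 0.05).
#' @return An object of class `"ssi_regression"`: a list with the final
#'   `fit` (an `lm`), `retained` predictor names, `dropped` (in elimination
#'   order), `anova` (partial F table of the final model), `adj_r_squared`,
#'   `coefficients` and the predictor `correlations`.
#' @examples
#' obs <- data.frame(transitivity = runif(30))
#' obs$ssi <- 2 * obs$transitivity + rnorm(30, sd = 0.01)
#' fit_ssi_model(obs)
#' @export
fit_ssi_model <- function(observations, alpha = 0.05) {
  preds <- intersect(ssi_predictors, names(observations))
  if (length(preds) == 0) stop("no topology predictor columns found")
  if (!"ssi" %in% names(observations)) stop("no 'ssi' response column")
  dat <- observations[c("ssi", preds)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= length(preds) + 1) {
    stop("need more observations than predictors + 1")
  }
  # drop constant and aliased columns up front
  const <- vapply(dat[preds], function(v) stats::var(v) == 0, FALSE)
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(preds[const], collapse = ", "))
    preds <- preds[!const]
  }
  fit <- stats::lm(stats::reformulate(preds, "ssi"), data = dat)
  if (any(is.na(stats::coef(fit)))) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("dropping aliased predictor(s): ", paste(alias, collapse = ", "))
    preds <- setdiff(preds, alias)
    fit <- stats::lm(stats::reformulate(preds, "ssi"), data = dat)
  }
  dropped <- character(0)
  repeat {
    if (length(preds) == 0) break
    tab <- stats::drop1(fit, test = "F")
    pv <- tab[["Pr(>F)"]][-1]      # first row is <none>
    names(pv) <- rownames(tab)[-1]
    if (length(pv) == 0 || all(is.na(pv))) break
    worst <- which.max(pv)
    if (is.na(pv[worst]) || pv[worst] <= alpha) break
    dropped <- c(dropped, names(pv)[worst])
    preds <- setdiff(preds, names(pv)[worst])
    fit <- if (length(preds) == 0) {
      stats::lm(ssi ~ 1, data = dat)
    } else {
      stats::lm(stats::reformulate(preds, "ssi"), data = dat)
    }
  }
  an <- if (length(preds) > 0) stats::drop1(fit, test = "F") else NULL
  structure(list(
    fit = fit,
    retained = preds,
    dropped = dropped,
    anova = an,
    adj_r_squared = summary(fit)$adj.r.squared,
    coefficients = summary(fit)$coefficients,
    alpha = alpha,
    correlations = suppressWarnings(correlation_matrix(dat)$r)
  ), class = "ssi_regression")
}

#' @export
print.ssi_regression <- function(x, ...) {
  cat("SSI ~ topology regression (backward elimination, alpha =",
      x$alpha, ")\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  if (length(x$dropped)) {
    cat("  dropped: ", paste(x$dropped, collapse = ", "), "\n")
  }
  cat(sprintf("  adjusted R-squared: %.3f\n", x$adj_r_squared))
  stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  invisible(x)
}

#' @export
summary.ssi_regression <- function(object, ...) summary(object$fit, ...)

#' @export
coef.ssi_regression <- function(object, ...) stats::coef(object$fit)

#' @export
predict.ssi_regression <- function(object, ...) stats::predict(object$fit, ...)

#' @export
plot.ssi_regression <- function(x, ...) {
  vars <- c("ssi", x$retained)
  dat <- stats::model.frame(x$fit)
  graphics::pairs(dat[intersect(vars, names(dat))], ...)
  invisible(x)
}
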