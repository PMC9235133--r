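#' MCMC control settings
#'
#' @param n_iter total chain length (default 10000, of which `burnin` are
#'   discarded).
#' @param burnin burn-in iterations (default 1000).
#' @param steps initial Metropolis steps for (h2, l2, c2).
#' @param step_lambda,step_pstar ZIP proposal steps.
#' @param grid_size Simpson points for the density-at-zero grid.
#' @param density_grid store per-iteration conditional densities at zero
#'   (required for Bayes factors).
#' @param adapt adapt proposal steps during burn-in.
#' @param zip_focus DIC focus for the ZIP model (`"marginal"` or
#'   `"conditional"`; see [chain_dic()]).
#' @param threshold exceedance threshold for posterior summaries.
#' @param gh_points Gauss-Hermite nodes for the marginal ZIP deviance.
#' @return list of settings for [vr_fit()].
#' @export
vr_control <- function(n_iter = 10000, burnin = 1000,
                       steps = c(0.05, 0.05, 0.05), step_lambda = 0.3,
                       step_pstar = 0.5, grid_size = 129,
                       density_grid = TRUE, adapt = TRUE,
                       zip_focus = c("marginal", "conditional"),
                       threshold = 0.10, gh_points = 31) {
  list(n_iter = n_iter, burnin = burnin, steps = steps,
       step_lambda = step_lambda, step_pstar = step_pstar,
       grid_size = grid_size, density_grid = density_grid, adapt = adapt,
       zip_focus = match.arg(zip_focus), threshold = threshold,
       gh_points = gh_points)
}

summarize_chain <- function(chain, threshold = 0.10) {
  rat <- chain$ratios
  out <- data.frame(
    parameter = colnames(rat),
    mean = colMeans(rat),
    sd = apply(rat, 2, sd),
    prob_exceeds = apply(rat, 2, function(v) mean(v > threshold)),
    geweke_z = apply(rat, 2, function(v)
      tryCatch(geweke_z(v), error = function(e) NA_real_)),
    row.names = NULL)
  attr(out, "threshold") <- threshold
  out
}

#' Fit the variance-ratio animal model to one trait
#'
#' The main fitting interface.  Fits the linear mixed model, the
#' zero-inflated Poisson mixed model, or both (`model = "auto"`, the
#' study's protocol: fit both where the trait admits a ZIP likelihood,
#' choose by DIC, and report Savage-Dickey Bayes factors for
#' `h2 = 0`, `l2 = 0`, `c2 = 0` from the chosen model's chain).
#'
#' @param formula model formula: trait on the left, systematic factors on
#'   the right (e.g. `trait1 ~ group + batch + weight_class`).
#' @param data data.frame with the trait, the systematic factors and the
#'   `id`, `litter` and `cage` columns, one row per observed animal.
#' @param pedigree a `pedigree` object covering all observed animals.
#' @param model `"auto"`, `"lmm"` or `"zip"`.
#' @param id,litter,cage names of the animal, litter and cage columns.
#' @param control settings from [vr_control()].
#' @param seed integer seed; the full fit is deterministic given it.
#' @return a `vrfit` object with components `chains` (per fitted model),
#'   `dic`, `model` (selected), `bf` (Bayes-factor table),
#'   `summary` (per-ratio posterior summaries), `zip_skipped` reason if
#'   applicable, plus the data bindings needed by the methods.
#' @export
vr_fit <- function(formula, data, pedigree, model = c("auto", "lmm", "zip"),
                   id = "animal", litter = "litter", cage = "cage",
                   control = vr_control(), seed = NULL) {
  model <- match.arg(model)
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  for (v in c(id, litter, cage))
    if (!v %in% names(data)) stop("data lacks column '", v, "'")
  ids <- as.character(data[[id]])
  sped <- if (is_sorted_pedigree(pedigree)) pedigree else sort_pedigree(pedigree)
  A <- relationship_matrix(sped)
  design <- list(X = X,
                 Z_L = onehot(data[[litter]], "litter"),
                 Z_C = onehot(data[[cage]], "cage"),
                 animal_ids = ids)
  kernels <- make_kernels(A, design)
  vr_fit_core(y, X, kernels, model, control, seed,
              call = match.call(), trait = deparse(formula[[2]]))
}

# Shared core over prepared (y, X, kernels); also used by vr_study().
vr_fit_core <- function(y, X, kernels, model, control, seed,
                        call = NULL, trait = "trait") {
  chains <- list()
  dic <- list()
  zip_skipped <- NULL
  zip_ok <- all(y >= 0) && all(y == floor(y))
  if (model == "zip" && !zip_ok)
    stop("trait contains negative or non-integer values; ZIP model not applicable")
  fit_lmm <- model %in% c("auto", "lmm")
  fit_zip <- model == "zip" || (model == "auto" && zip_ok)
  if (model == "auto" && !zip_ok)
    zip_skipped <- "trait has negative or non-integer values"
  if (fit_lmm) {
    chains$lmm <- run_lmm_mcmc(
      y, X, kernels, n_iter = control$n_iter, burnin = control$burnin,
      steps = control$steps, grid_size = control$grid_size,
      density_grid = control$density_grid, adapt = control$adapt,
      seed = seed)
    dic$lmm <- chain_dic(chains$lmm, y, X, kernels)
  }
  if (fit_zip) {
    chains$zip <- run_zip_mcmc(
      y, X, kernels, n_iter = control$n_iter, burnin = control$burnin,
      steps = control$steps, step_lambda = control$step_lambda,
      step_pstar = control$step_pstar, grid_size = control$grid_size,
      density_grid = control$density_grid, adapt = control$adapt,
      seed = if (is.null(seed)) NULL else seed + 1L,
      gh_points = control$gh_points)
    dic$zip <- chain_dic(chains$zip, y, X, kernels,
                         zip_focus = control$zip_focus)
  }
  selected <- if (length(chains) == 2L)
    select_model(dic$lmm, dic$zip)$choice
  else names(chains)[1]
  chain <- chains[[selected]]
  bf <- if (control$density_grid) bf_table(chain) else NULL
  structure(list(
    chains = chains, dic = dic, model = selected, bf = bf,
    summary = summarize_chain(chain, control$threshold),
    zip_skipped = zip_skipped, y = y, X = X, kernels = kernels,
    control = control, seed = seed, call = call, trait = trait),
    class = "vrfit")
}

#' @export
print.vrfit <- function(x, ...) {
  cat("Variance-ratio animal model fit:", x$trait, "\n")
  cat("  n =", length(x$y), "observations\n")
  if (length(x$dic) == 2L)
    cat(sprintf("  DIC: LMM %.1f | ZIP %.1f -> %s selected\n",
                x$dic$lmm$dic, x$dic$zip$dic, toupper(x$model)))
  else
    cat(sprintf("  model: %s (DIC %.1f)\n", toupper(x$model),
                x$dic[[x$model]]$dic))
  if (!is.null(x$zip_skipped))
    cat("  ZIP skipped:", x$zip_skipped, "\n")
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-3s mean %.3f (sd %.3f)  P(> %.2f) = %.2f%s\n",
                s$parameter[k], s$mean[k], s$sd[k],
                attr(s, "threshold"), s$prob_exceeds[k],
                if (!is.null(x$bf))
                  sprintf("  BF = %.3g [%s]", x$bf$bf[k], x$bf$evidence[k])
                else ""))
  invisible(x)
}

#' @export
summary.vrfit <- function(object, ...) {
  chain <- object$chains[[object$model]]
  out <- list(trait = object$trait, model = object$model,
              n = length(object$y), dic = object$dic,
              ratios = object$summary, bf = object$bf,
              sigma2_P = posterior_summary(chain$sigma2, threshold = 0),
              accept = chain$accept,
              p = if (object$model == "zip")
                posterior_summary(plogis(chain$pstar), threshold = 0)
              else NULL,
              zip_skipped = object$zip_skipped)
  class(out) <- "summary.vrfit"
  out
}

#' @export
print.summary.vrfit <- function(x, ...) {
  cat("Trait:", x$trait, " (n =", x$n, ")\n")
  for (m in names(x$dic))
    cat(sprintf("  DIC[%s] = %.2f (Dbar %.2f, pD %.2f)\n", m,
                x$dic[[m]]$dic, x$dic[[m]]$dbar, x$dic[[m]]$pd))
  cat("Selected model:", toupper(x$model), "\n")
  cat("Posterior summaries of the variance ratios:\n")
  print(x$ratios, row.names = FALSE, digits = 3)
  if (!is.null(x$bf)) {
    cat("Savage-Dickey Bayes factors (null: ratio = 0):\n")
    print(x$bf, row.names = FALSE, digits = 3)
  }
  cat(sprintf("sigma2_P: mean %.4g (sd %.3g)\n", x$sigma2_P$mean, x$sigma2_P$sd))
  if (!is.null(x$p))
    cat(sprintf("zero-inflation p: mean %.3f (sd %.3f)\n", x$p$mean, x$p$sd))
  invisible(x)
}

#' @export
coef.vrfit <- function(object, ...) {
  chain <- object$chains[[object$model]]
  beta <- if (ncol(chain$beta)) colMeans(chain$beta) else numeric(0)
  names(beta) <- colnames(object$X)
  c(beta, colMeans(chain$ratios), sigma2_P = mean(chain$sigma2))
}

#' @export
predict.vrfit <- function(object, ...) {
  chain <- object$chains[[object$model]]
  beta <- if (ncol(chain$beta)) colMeans(chain$beta) else numeric(0)
  mu <- if (length(beta)) drop(object$X %*% beta) else rep(0, length(object$y))
  if (object$model == "zip") {
    p <- mean(plogis(chain$pstar))
    (1 - p) * exp(chain$lamstar_mean)
  } else mu
}

#' @export
residuals.vrfit <- function(object, ...) {
  if (object$model == "zip")
    object$y - predict(object)
  else
    object$y - predict(object)
}

#' @export
plot.vrfit <- function(x, which = c("trace", "density"), ...) {
  which <- match.arg(which)
  chain <- x$chains[[x$model]]
  old <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (nm in c("h2", "l2", "c2")) {
    v <- chain$ratios[, nm]
    if (which == "trace") {
      plot(v, type = "l", xlab = "kept iteration", ylab = nm,
           main = paste("trace of", nm))
    } else {
      plot(density(v, from = 0, to = 1), xlab = nm, main = paste("posterior of", nm))
      abline(v = mean(v), lty = 2)
    }
  }
  invisible(x)
}

#' @export
simulate.vrfit <- function(object, nsim = 1, seed = NULL, ...) {
  chain <- object$chains[[object$model]]
  n <- length(object$y)
  rbar <- pmax(colMeans(chain$ratios), 0)
  if (sum(rbar) > 1) rbar <- rbar / (sum(rbar) + 1e-12)
  V <- build_V(rbar, mean(chain$sigma2), object$kernels)
  L <- t(chol(V + diag(1e-10 * mean(diag(V)), n)))
  beta <- if (ncol(chain$beta)) colMeans(chain$beta) else numeric(0)
  mu <- if (length(beta)) drop(object$X %*% beta) else rep(0, n)
  with_seed(seed, {
    out <- replicate(nsim, {
      eta <- mu + drop(L %*% rnorm(n))
      if (object$model == "zip") {
        y <- rpois(n, exp(pmin(eta, 19)))
        y[runif(n) < mean(plogis(chain$pstar))] <- 0L
        y
      } else eta
    })
    as.data.frame(out)
  })
}
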