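#' MCMC sampler settings
#'
#' Container for the chain settings shared by all model-fitting functions.
#' Defaults follow the settings used for the tactic-transition model
#' (3 chains, 20,000 iterations, thinning interval 100, burn-in 2,500); the
#' outcome-model fitters override them with their own defaults. `iterations`
#' counts post-burn-in iterations, so each chain contributes
#' `iterations / thin` retained draws.
#'
#' @param chains Number of chains (>= 2 so that split-R-hat is defined).
#' @param iterations Post-burn-in iterations per chain.
#' @param burnin Burn-in iterations discarded after adaptation.
#' @param thin Thinning interval (>= 1).
#' @param adapt Adaptation iterations for the JAGS samplers.
#' @param seed Integer seed; every chain derives its own RNG seed from it, so
#'   a fit is reproducible given the config.
#' @return An object of class `mcmc_config`.
#' @export
#' @examples
#' mcmc_config(chains = 3, iterations = 2000, burnin = 500, thin = 1, seed = 7)
mcmc_config <- function(chains = 3, iterations = 20000, burnin = 2500,
                        thin = 100, adapt = 500, seed = 1L) {
  stopifnot(chains >= 2, iterations >= 1, burnin >= 0, thin >= 1, adapt >= 0)
  if (iterations < thin) stop("`iterations` must be at least `thin`")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 thin = as.integer(thin),
                 adapt = as.integer(adapt),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

chain_seeds <- function(config) {
  # keep derived seeds positive and well below .Machine$integer.max
  base <- (abs(config$seed) %% 20000000L)
  base * 100L + seq_len(config$chains)
}

#' Run an MCMC model through JAGS
#'
#' Shared sampling engine for every model in the package. Takes a model in
#' the BUGS language, compiles it with `rjags`, runs adaptation and burn-in,
#' and returns post-burn-in thinned draws. Chains are seeded deterministically
#' from `config$seed`, so two runs with identical inputs give identical draws.
#'
#' @param model Single character string containing the BUGS model.
#' @param data Named list of data passed to [rjags::jags.model()].
#' @param monitor Character vector of node names to record.
#' @param config An [mcmc_config()].
#' @param inits Optional list (one element per chain) of initial values;
#'   RNG seeds are added automatically.
#' @param glm_module Load JAGS's `glm` samplers (helps the Bernoulli and
#'   Gaussian hierarchical models).
#' @return A [coda::mcmc.list] with one [coda::mcmc] object per chain.
#' @export
#' @examples
#' \donttest{
#' model <- "model {
#'   for (i in 1:N) { y[i] ~ dnorm(mu, 1) }
#'   mu ~ dnorm(0, 0.0001)
#' }"
#' draws <- run_mcmc(model, data = list(y = rnorm(20), N = 20), monitor = "mu",
#'                   config = mcmc_config(iterations = 1000, burnin = 200,
#'                                        thin = 1, adapt = 100))
#' summarize_draws(draws)
#' }
run_mcmc <- function(model, data, monitor, config = mcmc_config(),
                     inits = NULL, glm_module = FALSE) {
  stopifnot(is.character(model), length(model) == 1L, is.list(data),
            inherits(config, "mcmc_config"))
  if (glm_module) rjags::load.module("glm", quiet = TRUE)
  seeds <- chain_seeds(config)
  full_inits <- lapply(seq_len(config$chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = seeds[ch])
    if (!is.null(inits)) {
      extra <- if (is.function(inits)) inits(ch) else inits[[ch]]
      ini <- c(extra, ini)
    }
    ini
  })
  jm <- rjags::jags.model(textConnection(model), data = data,
                          inits = full_inits, n.chains = config$chains,
                          n.adapt = config$adapt, quiet = TRUE)
  if (config$burnin > 0) stats::update(jm, config$burnin, progress.bar = "none")
  out <- rjags::coda.samples(jm, variable.names = monitor,
                             n.iter = config$iterations, thin = config$thin,
                             progress.bar = "none")
  # the compiled graph lives on the C++ heap, invisible to R's allocator;
  # collect it promptly so long simulation studies keep a flat footprint
  rm(jm)
  gc(verbose = FALSE)
  out
}

as_chain_matrices <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    lapply(draws, function(ch) {
      m <- as.matrix(ch)
      if (is.null(colnames(m))) colnames(m) <- paste0("par", seq_len(ncol(m)))
      m
    })
  } else if (is.list(draws) && all(vapply(draws, is.matrix, logical(1)))) {
    draws
  } else if (is.matrix(draws)) {
    list(draws)
  } else {
    stop("`draws` must be an mcmc.list, a matrix or a list of matrices")
  }
}

#' Potential scale reduction factor (split R-hat)
#'
#' Computes the split-chain potential scale reduction statistic for each
#' monitored parameter: every chain is split in half, and R-hat is
#' `sqrt(((n - 1)/n * W + B/n) / W)` where `W` is the mean within-(half-)chain
#' variance and `B/n` the between-(half-)chain variance of the means.
#' Values near 1 indicate convergence; the package follows the convention
#' that all parameters must satisfy R-hat < 1.1.
#'
#' @param draws A [coda::mcmc.list] or list of per-chain draw matrices
#'   (iterations x parameters) with identical dimensions.
#' @return Named numeric vector of R-hat values (NA for constant parameters).
#' @export
#' @examples
#' chains <- replicate(3, matrix(rnorm(600), ncol = 2,
#'                               dimnames = list(NULL, c("a", "b"))),
#'                     simplify = FALSE)
#' gelman_rubin(chains)
gelman_rubin <- function(draws) {
  chains <- as_chain_matrices(draws)
  if (length(chains) < 2L) stop("R-hat requires at least two chains")
  n_iter <- unique(vapply(chains, nrow, integer(1)))
  if (length(n_iter) != 1L) stop("chains must have equal lengths")
  if (n_iter < 4L) stop("chains too short to split")
  half <- floor(n_iter / 2)
  halves <- unlist(lapply(chains, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n_iter - half + 1):n_iter, , drop = FALSE])
  }), recursive = FALSE)
  pars <- colnames(chains[[1]])
  rhat <- vapply(seq_along(pars), function(j) {
    xs <- lapply(halves, function(m) m[, j])
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, stats::var, numeric(1))
    W <- mean(vars)
    B_over_n <- stats::var(means)  # = B/n in the usual notation
    if (!is.finite(W) || W == 0) return(NA_real_)
    sqrt(((half - 1) / half * W + B_over_n) / W)
  }, numeric(1))
  names(rhat) <- pars
  rhat
}

#' Credible interval and the 97.5% credibility rule
#'
#' Summarizes a vector of posterior draws into a 95% equal-tailed credible
#' interval (2.5 and 97.5 percentiles, linear-interpolation quantiles,
#' `type = 7`) and a credibility flag. An effect is credible when 97.5% or
#' more of its posterior mass lies on one side of zero; the boundary is
#' inclusive, so a posterior with exactly 97.5% of draws positive is credible.
#'
#' @param draws Numeric vector of posterior draws (>= 40 so that the tail
#'   percentiles are estimable).
#' @return List with elements `lci`, `hci`, `credible` and `p_positive`
#'   (the share of draws strictly greater than zero).
#' @export
#' @examples
#' credibility(rnorm(1000, mean = 3))$credible   # TRUE
#' credibility(rnorm(1000, mean = 0))$credible   # FALSE
credibility <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 40L) stop("need at least 40 draws")
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  p_pos <- mean(draws > 0)
  list(lci = qs[1], hci = qs[2],
       credible = p_pos >= 0.975 || p_pos <= 0.025,
       p_positive = p_pos)
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, 95% credible interval, split R-hat and the
#' 97.5% credibility flag, recomputable from the draws alone.
#'
#' @param draws A [coda::mcmc.list] or list of per-chain draw matrices.
#' @param params Optional character vector restricting the summary.
#' @return A data frame with columns `parameter`, `mean`, `lci`, `hci`,
#'   `rhat`, `credible`.
#' @export
summarize_draws <- function(draws, params = NULL) {
  chains <- as_chain_matrices(draws)
  all_mat <- do.call(rbind, chains)
  pars <- colnames(all_mat)
  if (!is.null(params)) pars <- intersect(pars, params)
  rhat <- if (length(chains) >= 2L) gelman_rubin(chains) else
    stats::setNames(rep(NA_real_, ncol(all_mat)), colnames(all_mat))
  out <- do.call(rbind, lapply(pars, function(p) {
    cr <- credibility(all_mat[, p])
    data.frame(parameter = p, mean = mean(all_mat[, p]),
               lci = cr$lci, hci = cr$hci, rhat = unname(rhat[p]),
               credible = cr$credible, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Standardize numeric covariates
#'
#' Applies the covariate-scaling convention shared by every model: numeric
#' columns whose observed range extends below 0 or above 1 are z-scored
#' (centred on their mean, divided by their standard deviation); columns
#' already contained in \[0, 1\] (proportions, indicators) are left
#' untouched. The scaling metadata is attached as attribute `"scaling"` so
#' fitted effects and prediction grids can be mapped back to the raw scale.
#'
#' @param df A data frame.
#' @param cols Columns to consider; default all numeric columns.
#' @return `df` with scaled columns and a `"scaling"` attribute: a data frame
#'   with columns `variable`, `mean`, `sd`, `scaled`.
#' @seealso [destandardize()] for the inverse transformation.
#' @export
#' @examples
#' d <- standardize_covariates(data.frame(prop = c(0.2, 0.8), wt = c(-100, 100)))
#' attr(d, "scaling")
standardize_covariates <- function(df, cols = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(cols)) cols <- names(df)[vapply(df, is.numeric, logical(1))]
  meta <- data.frame(variable = character(0), mean = numeric(0),
                     sd = numeric(0), scaled = logical(0),
                     stringsAsFactors = FALSE)
  for (col in cols) {
    x <- df[[col]]
    rng <- range(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    needs <- rng[1] < 0 || rng[2] > 1
    if (needs && (!is.finite(s) || s == 0)) {
      warning("column '", col, "' has zero variance; left unscaled")
      needs <- FALSE
    }
    if (needs) df[[col]] <- (x - mean(x, na.rm = TRUE)) / s
    meta <- rbind(meta, data.frame(variable = col,
                                   mean = if (needs) mean(x, na.rm = TRUE) else 0,
                                   sd = if (needs) s else 1,
                                   scaled = needs, stringsAsFactors = FALSE))
  }
  attr(df, "scaling") <- meta
  df
}

#' Invert covariate standardization
#'
#' Maps standardized values back to the raw scale using the metadata produced
#' by [standardize_covariates()].
#'
#' @param x Numeric vector of standardized values.
#' @param scaling The `"scaling"` attribute of a standardized data frame.
#' @param variable Name of the variable `x` belongs to.
#' @return Numeric vector on the original scale.
#' @export
destandardize <- function(x, scaling, variable) {
  row <- scaling[scaling$variable == variable, , drop = FALSE]
  if (nrow(row) != 1L) stop("no scaling entry for '", variable, "'")
  x * row$sd + row$mean
}

standardize_value <- function(x, scaling, variable) {
  row <- scaling[scaling$variable == variable, , drop = FALSE]
  if (nrow(row) != 1L) stop("no scaling entry for '", variable, "'")
  (x - row$mean) / row$sd
}
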