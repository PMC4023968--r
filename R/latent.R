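#' Latent-gradient weights
#'
#' A sparse weight vector over environmental variables defining a latent site
#' gradient `x_i = sum_l c_l env_il`. Weights are normalized to unit Euclidean
#' norm (the response curve is invariant to joint rescaling of gradient,
#' optimum and tolerance, so the raw scale is unidentified) and the inclusion
#' indicator of a variable is 0 exactly when its weight is 0.
#'
#' @param weights numeric vector, one weight per environmental variable;
#'   normalized internally.
#' @param indicators optional 0/1 inclusion indicators; derived from the
#'   zero pattern when omitted.
#' @param anchor index of the variable whose weight fixes the sign convention
#'   (kept non-negative).
#' @return a `latent_weights` list with unit-norm `weights`, `indicators`
#'   and `anchor`.
#' @export
latent_weights <- function(weights, indicators = NULL, anchor = 1L) {
  weights <- as.numeric(weights)
  if (all(weights == 0)) stop("at least one weight must be non-zero")
  weights <- .normalized_weights(weights)
  anc <- if (weights[anchor] != 0) anchor else which(weights != 0)[1L]
  if (weights[anc] < 0) weights <- -weights
  if (is.null(indicators)) indicators <- as.integer(weights != 0)
  if (any((indicators == 0) != (weights == 0)))
    stop("indicators must be 0 exactly where weights are 0")
  structure(list(weights = weights, indicators = as.integer(indicators),
                 anchor = as.integer(anchor)),
            class = "latent_weights")
}

#' Site scores on a latent environmental gradient
#'
#' @param env standardized [env_table()] (or plain matrix), `n x L`.
#' @param w a [latent_weights()] object or numeric weight vector
#'   (normalized to unit norm if it is not already).
#' @return numeric vector of site scores `x_i = sum_l c_l env_il`.
#' @export
latent_scores <- function(env, w) {
  if (inherits(w, "latent_weights")) w <- w$weights
  w <- .normalized_weights(as.numeric(w))
  values <- unclass(env)
  if (ncol(values) != length(w))
    stop("weight length must match the number of environmental variables")
  drop(values %*% w)
}

#' Fit the niche model on an estimated sparse latent gradient
#'
#' Replaces the measured gradient by `x_i = sum_l c_l env_il` and estimates
#' the weights jointly with all niche-model parameters. Weights carry the
#' same spike-and-slab prior as the trait slopes (applied to the raw weights,
#' before normalization); since they enter the Bernoulli likelihood
#' nonlinearly they move by Metropolis add/delete toggles plus a joint
#' random walk on the included weights. Excluded variables have weight
#' exactly 0 in every draw. The sign gauge (flipping all weights and all
#' optima leaves the posterior unchanged) is fixed deterministically on every
#' draw by keeping the anchor variable's weight non-negative; reported
#' weights (`c_env[l]`) are unit-norm.
#'
#' Convergence for this mode is much slower than for a measured gradient;
#' the default run length is therefore ten times longer.
#'
#' @param occ an [occurrence_matrix()].
#' @param env standardized [env_table()], `n x L`.
#' @param traits standardized [trait_table()] or `NULL`.
#' @param opts an [mcmc_options()]; defaults to `mcmc_options(n_iter = 1e5)`.
#' @param inits optional `init_bundle` (computed on the initial scores when
#'   omitted).
#' @param anchor index of the sign-anchor variable (default: first).
#' @param weights_init starting raw weights (default: equal weights, all
#'   variables included).
#' @param update_weights set `FALSE` to keep the weights fixed at
#'   `weights_init`; the sampler then reduces exactly to [fit_niche()] on the
#'   precomputed scores.
#' @return a `niche_fit` with additional `c_env[l]`, `gamma_env[l]` and
#'   `lambda_env` draws.
#' @export
fit_latent <- function(occ, env, traits = NULL, opts = NULL, inits = NULL,
                       anchor = 1L, weights_init = NULL,
                       update_weights = TRUE) {
  if (is.null(opts)) opts <- mcmc_options(n_iter = 100000L)
  if (!inherits(occ, "occurrence_matrix")) occ <- occurrence_matrix(occ)
  y <- unclass(occ)
  Env <- unclass(env)
  n <- nrow(y); m <- ncol(y); L <- ncol(Env)
  if (nrow(Env) != n) stop("environmental table rows must match sites")
  Z <- if (is.null(traits) || ncol(traits) == 0L) NULL else unclass(traits)
  K <- if (is.null(Z)) 0L else ncol(Z)
  if (is.null(weights_init)) weights_init <- rep(1 / sqrt(L), L)
  w0 <- as.numeric(weights_init)
  if (length(w0) != L) stop("weights_init must have one entry per variable")
  anc <- if (w0[anchor] != 0) anchor else which(w0 != 0)[1L]
  if (!is.na(anc) && w0[anc] < 0) w0 <- -w0
  x0 <- drop(Env %*% .normalized_weights(w0))
  if (is.null(inits)) inits <- initial_values(occ, x0, traits)
  state <- if (inherits(inits, "init_bundle"))
    .state_from_bundle(inits, K, n, opts) else inits
  state$w <- w0
  state$gamma_env <- as.integer(w0 != 0)
  state$lambda_env <- 1
  if (!update_weights) {
    blocks <- c("opt", "ltol", "a", "eps", "mu", "beta", "sigma",
                "sigma_site", "lambda")
    opts$update <- if (identical(opts$update, "all")) blocks
                   else setdiff(opts$update, "weights")
  }
  chains <- lapply(seq_len(opts$n_chains), function(ch) {
    .run_chain(y, Z, opts, state,
               chain_seed = (opts$seed + ch - 1L) %% .Machine$integer.max,
               chain_index = ch, Env = Env, anchor = as.integer(anchor))
  })
  .build_fit(chains, y, Z, opts, inits, Env = Env, anchor = as.integer(anchor))
}

#' Posterior summary of the latent-gradient weights
#'
#' @param fit a latent `niche_fit` from [fit_latent()].
#' @return data frame per environmental variable: posterior mean and median
#'   of the unit-norm weight and the posterior inclusion probability.
#' @export
latent_weight_summary <- function(fit) {
  if (!isTRUE(fit$latent)) stop("not a latent-gradient fit")
  cw <- extract_draws(fit, "^c_env\\[")
  gw <- extract_draws(fit, "^gamma_env\\[")
  vars <- colnames(fit$data$env)
  if (is.null(vars)) vars <- paste0("env", seq_len(fit$L))
  data.frame(variable = vars,
             weight_mean = colMeans(cw),
             weight_median = apply(cw, 2L, stats::median),
             inclusion_prob = colMeans(gw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior-mean latent site scores
#'
#' @param fit a latent `niche_fit`.
#' @return numeric vector of site scores at the (re-normalized) posterior
#'   mean weights.
#' @export
latent_scores_posterior <- function(fit) {
  if (!isTRUE(fit$latent)) stop("not a latent-gradient fit")
  st <- .posterior_mean_state(fit)
  st$x
}
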