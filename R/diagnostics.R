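#' Deviance information criterion with both effective-parameter estimators
#'
#' Computes `D_bar` (posterior mean deviance), `D_hat` (deviance at the
#' posterior mean of the parameters), the classic effective parameter count
#' `p_D = D_bar - D_hat`, the variance-based estimator
#' `p_D = Var(D) / 2` (within-chain sample variance, `n - 1` denominator,
#' averaged over chains), and the corresponding
#' `DIC = D_bar + p_D`. The classic `p_D` can be negative; it is then
#' flagged, never truncated.
#'
#' For a `niche_fit`, `D_hat` re-evaluates the Bernoulli deviance at the
#' posterior means of all species parameters and site effects (posterior mean
#' log tolerance back-transformed; for latent fits the mean weights are
#' re-normalized).
#'
#' @param x a `niche_fit`, or (default method) a list of per-chain deviance
#'   vectors (a single numeric vector is treated as one chain).
#' @param D_hat deviance at the posterior mean (default method only).
#' @param ... unused.
#' @return a `dic_report` list: `D_bar`, `D_hat`, `p_D_classic`, `p_D_var`,
#'   `DIC_classic`, `DIC_var`, `flag_negative_pD`.
#' @export
compute_dic <- function(x, ...) UseMethod("compute_dic")

#' @rdname compute_dic
#' @export
compute_dic.default <- function(x, D_hat, ...) {
  dev <- if (is.list(x)) x else list(x)
  all_dev <- unlist(dev)
  if (length(all_dev) < 2L) stop("DIC needs at least 2 kept draws")
  if (any(!is.finite(all_dev))) stop("non-finite deviance in draws")
  if (!is.finite(D_hat)) stop("non-finite deviance at the posterior mean")
  D_bar <- mean(all_dev)
  var_within <- mean(vapply(dev, stats::var, numeric(1)))
  p_D_classic <- D_bar - D_hat
  p_D_var <- var_within / 2
  structure(list(D_bar = D_bar, D_hat = D_hat,
                 p_D_classic = p_D_classic, p_D_var = p_D_var,
                 DIC_classic = D_bar + p_D_classic,
                 DIC_var = D_bar + p_D_var,
                 flag_negative_pD = p_D_classic < 0),
            class = "dic_report")
}

#' @rdname compute_dic
#' @export
compute_dic.niche_fit <- function(x, ...) {
  dev <- lapply(x$chains, function(ch) ch$deviance)
  st <- .posterior_mean_state(x)
  D_hat <- .deviance_from_state(unclass(x$data$y), st$x, st$opt, st$tol,
                                st$a, st$eps)
  compute_dic.default(dev, D_hat)
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("DIC report\n  D_bar  = %.2f   D_hat = %.2f\n", x$D_bar, x$D_hat))
  cat(sprintf("  p_D (classic)  = %.2f%s\n", x$p_D_classic,
              if (x$flag_negative_pD) "   [! negative]" else ""))
  cat(sprintf("  p_D (var/2)    = %.2f\n", x$p_D_var))
  cat(sprintf("  DIC (classic)  = %.2f\n  DIC (var)      = %.2f\n",
              x$DIC_classic, x$DIC_var))
  invisible(x)
}

#' Percentage of niche-parameter variance explained by traits
#'
#' Compares the residual variances of the three niche-parameter submodels in
#' a fit with traits against the same fit without traits:
#' `100 * (sigma2_without - sigma2_with) / sigma2_without`, each variance
#' estimated by its posterior median. The fraction can be negative (traits
#' costing rather than explaining variance) and is at most 100.
#'
#' @param with_traits,without_traits `niche_fit` objects on identical data
#'   and gradient (checked by fingerprint).
#' @return data frame per niche parameter (`opt`, `ltol`, `a`):
#'   `sigma2_without`, `sigma2_with`, `fraction_pct`. The tolerance row is on
#'   the log-tolerance scale.
#' @export
variance_explained <- function(with_traits, without_traits) {
  if (!identical(with_traits$fingerprint, without_traits$fingerprint))
    stop("fits are not on identical data/gradient (fingerprint mismatch)")
  med <- function(fit, par) stats::median(extract_draws(fit, paste0("^", par, "$")))
  out <- do.call(rbind, lapply(c("opt", "ltol", "a"), function(th) {
    s_wo <- med(without_traits, paste0("sigma2_", th))
    s_wi <- med(with_traits, paste0("sigma2_", th))
    data.frame(parameter = th, sigma2_without = s_wo, sigma2_with = s_wi,
               fraction_pct = variance_explained_pct(s_wo, s_wi),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname variance_explained
#' @param sigma2_without,sigma2_with variance components (posterior medians)
#'   for the scalar helper.
#' @export
variance_explained_pct <- function(sigma2_without, sigma2_with) {
  100 * (sigma2_without - sigma2_with) / sigma2_without
}

## split-Rhat (two halves per chain) for a list of equal-length chains
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    N <- length(ch)
    h <- N %/% 2L
    list(ch[seq_len(h)], ch[(N - h + 1L):N])
  }), recursive = FALSE)
  nseq <- length(halves)
  len <- length(halves[[1L]])
  if (len < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  Bn <- stats::var(means)                 # B / n
  if (W <= 0) return(if (Bn <= 0) 1 else Inf)
  sqrt((len - 1) / len + Bn / W)
}

## effective sample size by Geyer's initial positive sequence, summed over
## chains
.ess_geyer <- function(chains) {
  sum(vapply(chains, function(ch) {
    N <- length(ch)
    if (stats::var(ch) <= 0) return(as.numeric(N))
    lag_max <- min(N - 1L, 2000L)
    rho <- drop(stats::acf(ch, lag.max = lag_max, plot = FALSE,
                           demean = TRUE)$acf)
    npair <- (length(rho)) %/% 2L
    tau <- 0
    for (jp in seq_len(npair)) {
      g <- rho[2L * jp - 1L] + rho[2L * jp]   # rho[1] is lag 0
      if (g <= 0) break
      tau <- tau + g
    }
    tau <- max(2 * tau - 1, 1)
    N / tau
  }, numeric(1)))
}

#' Convergence diagnostics per scalar parameter
#'
#' Split-R-hat (each chain split in half; requires at least two chains) and
#' effective sample size (initial-positive-sequence autocorrelation
#' estimator, summed over chains) for every parameter. Parameters that are
#' constant across all draws (e.g. never-included indicators) get `NA`
#' R-hat and `ESS = N`.
#'
#' @param fit a `niche_fit`.
#' @param pattern optional regular expression selecting parameters.
#' @param rhat_warn threshold above which a parameter is listed in the
#'   `"flagged"` attribute (default 1.1).
#' @return data frame with `parameter`, `rhat`, `ess`; flagged parameter
#'   names in `attr(, "flagged")`.
#' @export
convergence_report <- function(fit, pattern = NULL, rhat_warn = 1.1) {
  sel <- fit$param_names
  if (!is.null(pattern)) sel <- sel[grepl(pattern, sel)]
  single <- length(fit$chains) < 2L
  if (single)
    message("single chain: R-hat omitted, reporting ESS only")
  res <- lapply(sel, function(p) {
    chains <- lapply(fit$chains, function(ch) ch$draws[, p])
    const <- all(vapply(chains, function(v) stats::var(v) <= 0, logical(1)))
    if (const) {
      data.frame(parameter = p, rhat = NA_real_,
                 ess = sum(lengths(chains)), stringsAsFactors = FALSE)
    } else {
      data.frame(parameter = p,
                 rhat = if (single) NA_real_ else .split_rhat(chains),
                 ess = .ess_geyer(chains), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  flagged <- out$parameter[!is.na(out$rhat) & out$rhat > rhat_warn]
  attr(out, "flagged") <- flagged
  out
}

#' Posterior inclusion probabilities
#'
#' Posterior means of the spike-and-slab inclusion indicators: per trait and
#' niche parameter for the trait slopes, and per environmental variable for a
#' latent-gradient fit.
#'
#' @param fit a `niche_fit` run with `prior = "spike_slab"` (or any latent
#'   fit).
#' @return data frame with `block` (`opt`, `ltol`, `a` or `env`),
#'   `variable` and `prob`.
#' @export
inclusion_probabilities <- function(fit) {
  has_gamma <- any(grepl("^gamma_", fit$param_names))
  if (!has_gamma)
    stop("no indicators in this model (normal-prior fit without latent weights)")
  rows <- list()
  trait_names <- colnames(fit$data$Z)
  if (is.null(trait_names) && fit$K > 0L) trait_names <- paste0("trait", seq_len(fit$K))
  for (th in c("opt", "ltol", "a")) {
    cols <- grep(paste0("^gamma_", th, "\\["), fit$param_names)
    if (length(cols) == 0L) next
    g <- extract_draws(fit)[, cols, drop = FALSE]
    rows[[th]] <- data.frame(block = th, variable = trait_names,
                             prob = colMeans(g), stringsAsFactors = FALSE)
  }
  cols <- grep("^gamma_env\\[", fit$param_names)
  if (length(cols) > 0L) {
    g <- extract_draws(fit)[, cols, drop = FALSE]
    env_names <- colnames(fit$data$env)
    if (is.null(env_names)) env_names <- paste0("env", seq_len(fit$L))
    rows$env <- data.frame(block = "env", variable = env_names,
                           prob = colMeans(g), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
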