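#' Configuration for the community simulator
#'
#' Describes one draw from the generative side of the hierarchical niche
#' model: traits are drawn (continuous: standard normal; binary: Bernoulli
#' with prevalence `binary_prev`, then standardized like the real pipeline),
#' species niche parameters come from the trait submodels with Gaussian
#' residuals (tolerance generated on the log scale, matching the inference
#' parameterization), site effects are Gaussian, and occurrences are
#' Bernoulli under the Gaussian logistic response curve.
#'
#' @param n,m,L sites, species, environmental variables.
#' @param K_cont,K_bin numbers of continuous and binary traits.
#' @param mu named list/vector of submodel intercepts for `opt`, `ltol`, `a`.
#' @param beta list of true slope vectors (`opt`, `ltol`, `a`), each of length
#'   `K_cont + K_bin` (or empty for no trait effects).
#' @param sigma_opt,sigma_tol,sigma_a residual sds of the submodels
#'   (`sigma_tol` acts on log tolerance); all non-negative.
#' @param sigma_site site-effect sd.
#' @param latent_weights optional true weights over the `L` environmental
#'   variables (normalized internally); when `NULL` the gradient is the first
#'   environmental variable.
#' @param gradient `"normal"` or `"uniform"` distribution of the raw gradient
#'   variable; uniform gradients exercise truncated response curves (optima
#'   near or beyond the sampled range).
#' @param binary_prev prevalence of binary traits before standardization,
#'   in (0, 1).
#' @param seed mandatory integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n, m, L = 1L, K_cont = 0L, K_bin = 0L,
                             mu = c(opt = 0, ltol = 0, a = 0),
                             beta = NULL,
                             sigma_opt = 0.5, sigma_tol = 0.2, sigma_a = 0.5,
                             sigma_site = 0.5,
                             latent_weights = NULL,
                             gradient = c("normal", "uniform"),
                             binary_prev = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  gradient <- match.arg(gradient)
  K <- K_cont + K_bin
  if (is.null(beta)) beta <- list(opt = rep(0, K), ltol = rep(0, K), a = rep(0, K))
  for (th in c("opt", "ltol", "a")) {
    beta[[th]] <- rep_len(as.numeric(beta[[th]]), K)
  }
  if (any(c(sigma_opt, sigma_tol, sigma_a, sigma_site) < 0))
    stop("all residual sds must be non-negative")
  if (binary_prev <= 0 || binary_prev >= 1)
    stop("binary_prev must lie strictly in (0, 1)")
  if (!is.null(latent_weights)) {
    latent_weights <- as.numeric(latent_weights)
    if (length(latent_weights) != L)
      stop("latent_weights must have length L")
    if (all(latent_weights == 0)) stop("latent_weights must not be all zero")
  }
  structure(list(n = as.integer(n), m = as.integer(m), L = as.integer(L),
                 K_cont = as.integer(K_cont), K_bin = as.integer(K_bin),
                 mu = mu, beta = beta,
                 sigma_opt = sigma_opt, sigma_tol = sigma_tol,
                 sigma_a = sigma_a, sigma_site = sigma_site,
                 latent_weights = latent_weights, gradient = gradient,
                 binary_prev = binary_prev, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a presence-absence community with known truth
#'
#' Runs the generative model of [synthetic_config()]. The occurrence
#' probabilities are evaluated by [response_probability()], the same function
#' the likelihood uses, so the generative and inferential response curves are
#' one piece of code. Identical seeds give bit-identical output.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `occ` ([occurrence_matrix()]), `env` (standardized
#'   [env_table()]), `traits` (standardized [trait_table()], `NULL` when
#'   `K = 0`) and `truth` (realized `opt`, `tol`, `a`, `eps`, gradient `x`,
#'   probability matrix `p`, normalized latent weights, and the config).
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n; m <- cfg$m; L <- cfg$L
  K <- cfg$K_cont + cfg$K_bin

  # traits: continuous standard normal, binary Bernoulli(prev); standardized
  # like the real pipeline (binary columns included)
  Z <- NULL; traits <- NULL
  if (K > 0L) {
    raw <- matrix(0, m, K)
    kinds <- c(rep("continuous", cfg$K_cont), rep("binary", cfg$K_bin))
    for (k in seq_len(K)) {
      if (kinds[k] == "continuous") {
        raw[, k] <- stats::rnorm(m)
      } else {
        repeat {                         # avoid degenerate constant columns
          v <- stats::rbinom(m, 1L, cfg$binary_prev)
          if (stats::var(v) > 0) break
        }
        raw[, k] <- v
      }
    }
    colnames(raw) <- paste0(ifelse(kinds == "binary", "bintrait", "trait"),
                            seq_len(K))
    std <- .standardize_matrix(raw, rep(FALSE, K), "trait")
    traits <- trait_table(std$values, kinds = kinds, standardized = TRUE)
    attr(traits, "center") <- std$center
    attr(traits, "scale") <- std$scale
    Z <- unclass(traits)
  }

  # environment: raw gradient variable first, iid normal companions;
  # all columns standardized
  raw_env <- matrix(stats::rnorm(n * L), n, L)
  if (cfg$gradient == "uniform") raw_env[, 1L] <- stats::runif(n, -2, 2)
  colnames(raw_env) <- paste0("env", seq_len(L))
  std_env <- .standardize_matrix(raw_env, rep(FALSE, L), "environmental")
  env <- env_table(std_env$values, standardized = TRUE)

  w_true <- NULL
  if (is.null(cfg$latent_weights)) {
    x <- unclass(env)[, 1L]
  } else {
    w_true <- .normalized_weights(cfg$latent_weights)
    x <- drop(unclass(env) %*% w_true)
  }

  lin <- function(th, sigma) {
    mean <- cfg$mu[[th]] + if (K > 0L) drop(Z %*% cfg$beta[[th]]) else 0
    mean + stats::rnorm(m, 0, sigma)
  }
  opt <- lin("opt", cfg$sigma_opt)
  ltol <- lin("ltol", cfg$sigma_tol)
  a <- lin("a", cfg$sigma_a)
  eps <- stats::rnorm(n, 0, cfg$sigma_site)

  p <- response_probability(x, opt, exp(ltol), a, eps)
  p <- matrix(p, n, m)
  y <- matrix(as.numeric(stats::runif(n * m) < p), n, m)
  colnames(y) <- paste0("sp", seq_len(m))
  rownames(y) <- paste0("site", seq_len(n))

  list(occ = occurrence_matrix(y),
       env = env,
       traits = traits,
       truth = structure(list(opt = opt, tol = exp(ltol), a = a, eps = eps,
                              x = x, p = p, latent_weights = w_true,
                              config = cfg),
                         class = "synthetic_truth"))
}

#' Simulator preset shaped like the lake phytoplankton case study
#'
#' A configuration with 203 sites, 60 species, 11 environmental variables and
#' 6 traits (3 continuous, 3 binary), the gradient a sparse latent
#' combination of the environmental variables dominated by two variables with
#' opposite signs, and a two-group niche structure: the first binary trait
#' carries a strong positive slope on the optimum, so species possessing it
#' sit on the positive side of the gradient and species lacking it on the
#' negative side. Effect sizes are moderate so that every species remains
#' above the 5% occupancy screen in typical draws.
#'
#' @param seed integer seed (default 1).
#' @return a [synthetic_config()]; the index of the group-defining trait is
#'   in `attr(, "group_trait")`.
#' @export
case_study_preset <- function(seed = 1L) {
  K <- 6L
  beta <- list(
    opt = c(0.4, 0, 0, 1.5, 0, 0),    # trait 4 = first binary: group structure
    ltol = rep(0, K),
    a = c(0, 0.3, 0, 0, 0, 0))
  w <- c(0.7, -0.7, 0.3, 0.2, 0.2, rep(0, 6))
  cfg <- synthetic_config(
    n = 203L, m = 60L, L = 11L, K_cont = 3L, K_bin = 3L,
    mu = c(opt = 0, ltol = log(1.3), a = 0.8),
    beta = beta,
    sigma_opt = 0.4, sigma_tol = 0.15, sigma_a = 0.4, sigma_site = 0.4,
    latent_weights = w, gradient = "normal", binary_prev = 0.3,
    seed = seed)
  attr(cfg, "group_trait") <- 4L
  cfg
}
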