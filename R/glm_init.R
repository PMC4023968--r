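#' Gaussian niche parameters for one species
#'
#' @param opt niche optimum, in gradient units.
#' @param tol niche tolerance (curve width), strictly positive.
#' @param a logit of the occurrence probability at the optimum.
#' @return a `gaussian_niche` list with `opt`, `tol`, `a` and the derived
#'   `p_max = plogis(a)`.
#' @export
gaussian_niche <- function(opt, tol, a) {
  if (!is.finite(opt) || !is.finite(tol) || !is.finite(a))
    stop("niche parameters must be finite")
  if (tol <= 0) stop("tol must be strictly positive")
  structure(list(opt = opt, tol = tol, a = a, p_max = stats::plogis(a)),
            class = "gaussian_niche")
}

#' Augment a species record with absences outside the observed range
#'
#' A species whose optimum lies at or beyond the edge of the sampled gradient
#' appears monotone within it (a truncated response curve) and its quadratic
#' logit fit then has non-negative curvature. Appending artificial absences
#' outside the observed range pulls the fitted optimum inside the (widened)
#' range so a proper unimodal curve can be estimated. Augmentation is used for
#' starting values only; model fitting uses the original data.
#'
#' @param y binary presence vector.
#' @param x gradient vector, same length, non-constant.
#' @param n_aug number of zeros appended on each side (default 25).
#' @param extend how far beyond the observed range to place them, in units of
#'   the observed range width (default 1).
#' @return list with `y` and `x`; original observations first and unchanged.
#' @export
augment_absences <- function(y, x, n_aug = 25L, extend = 1.0) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  rng <- range(x)
  if (diff(rng) <= 0) stop("x must be non-constant")
  if (n_aug == 0L) return(list(y = y, x = x))
  w <- diff(rng) * extend
  # uniform grids on the open intervals (min - w, min) and (max, max + w)
  step <- w / (n_aug + 1L)
  left  <- rng[1L] - step * (n_aug:1L)
  right <- rng[2L] + step * (1L:n_aug)
  list(y = c(y, rep(0, 2L * n_aug)), x = c(x, left, right))
}

#' Fit the quadratic-logit GLM for one species
#'
#' Maximum-likelihood logistic regression of presence/absence on
#' `(1, x, x^2)`; the quadratic logit is the GLM form of the Gaussian
#' logistic curve. Perfect separation is detected and a ridge-stabilized
#' refit (a tiny L2 penalty on the coefficients) is used when the ML fit
#' diverges; both conditions are flagged in the result, never silent.
#'
#' @param y binary presence vector with at least one 0 and one 1.
#' @param x gradient vector.
#' @param ridge penalty used by the stabilized refit.
#' @return a `poly_coefficients` list: `b0`, `b1`, `b2`, `converged`,
#'   `separation`, `ridged`.
#' @export
fit_species_glm <- function(y, x, ridge = 1e-3) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (all(y == 0) || all(y == 1))
    stop("degenerate response: y must contain at least one 0 and one 1")
  x2 <- x * x
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x, x2), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- fit$coefficients
  converged <- isTRUE(fit$converged) && all(is.finite(b))
  ridged <- FALSE
  if (!converged || separation) {
    # penalized Bernoulli log-likelihood, quadratic penalty
    nll <- function(b) {
      eta <- b[1L] + b[2L] * x + b[3L] * x2
      -sum(.bern_loglik_cells(y, eta)) + ridge * sum(b * b)
    }
    start <- if (all(is.finite(b))) pmin(pmax(b, -10), 10) else c(stats::qlogis(mean(y)), 0, -0.1)
    opt <- stats::optim(start, nll, method = "BFGS", control = list(maxit = 500))
    b <- opt$par
    converged <- opt$convergence == 0L
    ridged <- TRUE
  }
  structure(list(b0 = unname(b[1L]), b1 = unname(b[2L]), b2 = unname(b[3L]),
                 converged = converged, separation = separation, ridged = ridged),
            class = "poly_coefficients")
}

#' Convert quadratic logit coefficients to Gaussian niche parameters
#'
#' For `logit(p) = b0 + b1 x + b2 x^2` with `b2 < 0`, the equivalent Gaussian
#' logistic curve has `opt = -b1 / (2 b2)`, `tol = 1 / sqrt(-2 b2)` and
#' `a = b0 - b1^2 / (4 b2)`; the GLM estimates mapped this way equal the
#' direct nonlinear ML estimates of the Gaussian logistic model.
#'
#' @param b a `poly_coefficients` object or list with `b0`, `b1`, `b2`.
#' @return a [gaussian_niche()].
#' @export
poly_to_niche <- function(b) {
  if (!is.finite(b$b2) || b$b2 >= 0)
    stop("no interior optimum: b2 must be negative")
  opt <- -b$b1 / (2 * b$b2)
  tol <- 1 / sqrt(-2 * b$b2)
  a <- b$b0 - b$b1^2 / (4 * b$b2)
  gaussian_niche(opt, tol, a)
}

#' Expand Gaussian niche parameters to quadratic logit coefficients
#'
#' Inverse of [poly_to_niche()].
#' @param niche a [gaussian_niche()].
#' @return a `poly_coefficients` list.
#' @export
niche_to_poly <- function(niche) {
  b2 <- -1 / (2 * niche$tol^2)
  b1 <- niche$opt / niche$tol^2
  b0 <- niche$a - niche$opt^2 / (2 * niche$tol^2)
  structure(list(b0 = b0, b1 = b1, b2 = b2,
                 converged = TRUE, separation = FALSE, ridged = FALSE),
            class = "poly_coefficients")
}

#' Starting values for the hierarchical model
#'
#' Per-species niche parameters come from augmented quadratic-logit GLM fits
#' ([augment_absences()] + [fit_species_glm()] + [poly_to_niche()]); the trait
#' submodel intercepts, slopes and residual variances come from ordinary
#' least squares of each niche parameter (optimum, log tolerance, maximum
#' coefficient) on the trait matrix. A species whose curve cannot be
#' estimated even after augmentation receives neutral fallback values
#' (`opt = 0`, `tol = 1`, `a = logit(prevalence)`) and is recorded in
#' `$fallback`.
#'
#' @param occ an [occurrence_matrix()].
#' @param x standardized gradient vector (length `n`).
#' @param traits standardized [trait_table()], or `NULL` for the no-traits
#'   model.
#' @param n_aug,extend augmentation controls, see [augment_absences()].
#' @param sigma2_site_init starting value for the site-effect variance.
#' @return an `init_bundle`: per-species `niches` data frame, per-parameter
#'   `submodels` (intercept, slopes, residual variance), `sigma2_site`,
#'   fallback flags, and the augmentation settings used.
#' @export
initial_values <- function(occ, x, traits = NULL, n_aug = 25L, extend = 1.0,
                           sigma2_site_init = 0.1) {
  if (!inherits(occ, "occurrence_matrix")) occ <- occurrence_matrix(occ)
  y <- unclass(occ)
  n <- nrow(y); m <- ncol(y)
  if (length(x) != n) stop("gradient length must match the number of sites")
  opt <- tol <- a <- numeric(m)
  fallback <- logical(m)
  for (j in seq_len(m)) {
    yj <- y[, j]
    prev <- min(max(mean(yj), 1 / (2 * n)), 1 - 1 / (2 * n))
    niche <- tryCatch({
      aug <- augment_absences(yj, x, n_aug = n_aug, extend = extend)
      poly_to_niche(fit_species_glm(aug$y, aug$x))
    }, error = function(e) NULL)
    if (is.null(niche) || !all(is.finite(c(niche$opt, niche$tol, niche$a)))) {
      niche <- gaussian_niche(0, 1, stats::qlogis(prev))
      fallback[j] <- TRUE
    }
    opt[j] <- niche$opt; tol[j] <- niche$tol; a[j] <- niche$a
  }
  # keep inits inside a sane band; extreme augmented fits otherwise start the
  # chain in a region of negligible posterior mass
  opt <- pmin(pmax(opt, min(x) - 2 * diff(range(x))), max(x) + 2 * diff(range(x)))
  tol <- pmin(pmax(tol, 0.05), 20)
  a <- pmin(pmax(a, -15), 15)

  Z <- if (is.null(traits)) NULL else unclass(traits)
  ols_submodel <- function(t) {
    if (is.null(Z) || ncol(Z) == 0L) {
      res <- t - mean(t)
      df <- max(m - 1L, 1L)
      return(list(intercept = mean(t), slopes = numeric(0),
                  sigma2 = max(sum(res^2) / df, 1e-6)))
    }
    fit <- stats::lm.fit(cbind(1, Z), t)
    cf <- fit$coefficients
    cf[!is.finite(cf)] <- 0
    df <- max(m - length(cf), 1L)
    list(intercept = unname(cf[1L]), slopes = unname(cf[-1L]),
         sigma2 = max(sum(fit$residuals^2) / df, 1e-6))
  }
  structure(list(
    niches = data.frame(species = colnames(y), opt = opt, tol = tol, a = a,
                        p_max = stats::plogis(a), fallback = fallback,
                        stringsAsFactors = FALSE),
    submodels = list(opt = ols_submodel(opt),
                     ltol = ols_submodel(log(tol)),
                     a = ols_submodel(a)),
    sigma2_site = sigma2_site_init,
    augmentation = list(n_aug = n_aug, extend = extend)),
    class = "init_bundle")
}

#' Write / read an init bundle as JSON
#'
#' @param bundle an `init_bundle` from [initial_values()].
#' @param path file path.
#' @return `path` (write) or the `init_bundle` (read).
#' @rdname init_bundle_json
#' @export
write_init_bundle <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname init_bundle_json
#' @export
read_init_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  b$submodels <- lapply(b$submodels, function(s) {
    s$slopes <- as.numeric(s$slopes)
    s
  })
  structure(b, class = "init_bundle")
}
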