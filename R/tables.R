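#' Construct a sites-by-species occurrence matrix
#'
#' Validates and labels a binary presence (1) / absence (0) table with sites
#' in rows and species in columns. All downstream fitting functions take this
#' object (or any coercible 0/1 matrix) as the community input.
#'
#' @param values numeric matrix of 0/1 values, `n` sites by `m` species.
#' @param site_ids,species_ids optional label vectors; default to existing
#'   dimnames or generated labels.
#' @return an `occurrence_matrix`: a base matrix with unique dimnames and the
#'   class attribute set.
#' @export
occurrence_matrix <- function(values, site_ids = NULL, species_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("occurrence matrix needs at least 2 sites")
  if (ncol(values) < 1L) stop("occurrence matrix needs at least 1 species")
  if (anyNA(values)) stop("occurrence matrix must not contain missing cells")
  if (!all(values %in% c(0, 1))) stop("occurrence matrix cells must be exactly 0 or 1")
  storage.mode(values) <- "double"
  if (is.null(site_ids)) site_ids <- rownames(values)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(values)))
  if (is.null(species_ids)) species_ids <- colnames(values)
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(ncol(values)))
  if (anyDuplicated(site_ids)) stop("site ids must be unique")
  if (anyDuplicated(species_ids)) stop("species ids must be unique")
  dimnames(values) <- list(site_ids, species_ids)
  class(values) <- c("occurrence_matrix", class(values))
  values
}

#' Construct a sites-by-variables environmental table
#'
#' @param values numeric matrix, `n` sites by `L` environmental variables.
#'   Missing cells are permitted before imputation.
#' @param log_flags logical vector, length `L`: which columns are
#'   log-transformed by [transform_and_standardize()]. Flagged columns must be
#'   strictly positive on the raw scale.
#' @param standardized logical; `TRUE` only for tables already centred and
#'   scaled (columns with mean 0, sd 1).
#' @return an `env_table` matrix carrying `log_flags` and `standardized`
#'   attributes (plus `center`/`scale` once standardized).
#' @export
env_table <- function(values, log_flags = rep(FALSE, ncol(values)),
                      standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) colnames(values) <- paste0("env", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("site", seq_len(nrow(values)))
  if (anyDuplicated(colnames(values))) stop("environmental variable names must be unique")
  log_flags <- rep_len(as.logical(log_flags), ncol(values))
  for (l in which(log_flags)) {
    bad <- which(!is.na(values[, l]) & values[, l] <= 0)
    if (!standardized && length(bad) > 0L)
      stop(sprintf("log-flagged column '%s' has non-positive value at row %d",
                   colnames(values)[l], bad[1L]))
  }
  structure(values,
            log_flags = log_flags,
            standardized = isTRUE(standardized),
            class = c("env_table", "matrix", "array"))
}

#' Construct a species-by-traits table
#'
#' @param values numeric matrix, `m` species by `K` traits.
#' @param kinds character vector, length `K`, each `"continuous"` or
#'   `"binary"`. Defaults to auto-detection (columns whose observed values are
#'   all 0/1 are binary).
#' @param standardized logical, as for [env_table()].
#' @return a `trait_table` matrix with `kinds` and `standardized` attributes.
#' @export
trait_table <- function(values, kinds = NULL, standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) > 0L) {
    if (is.null(colnames(values))) colnames(values) <- paste0("trait", seq_len(ncol(values)))
    if (is.null(rownames(values))) rownames(values) <- paste0("sp", seq_len(nrow(values)))
  }
  if (anyDuplicated(colnames(values))) stop("trait names must be unique")
  if (is.null(kinds)) {
    kinds <- vapply(seq_len(ncol(values)), function(k) {
      v <- values[, k]
      if (all(v[!is.na(v)] %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  kinds <- if (ncol(values) == 0L) character(0) else
    match.arg(rep_len(kinds, ncol(values)), c("continuous", "binary"),
              several.ok = TRUE)
  if (!standardized) {
    for (k in which(kinds == "binary")) {
      v <- values[, k]
      if (!all(v[!is.na(v)] %in% c(0, 1)))
        stop(sprintf("binary trait '%s' contains values other than 0/1",
                     colnames(values)[k]))
    }
  }
  structure(values,
            kinds = kinds,
            standardized = isTRUE(standardized),
            class = c("trait_table", "matrix", "array"))
}

## rebuild attributes after an operation that returns a bare matrix
.rewrap <- function(values, template, standardized = attr(template, "standardized"),
                    center = attr(template, "center"), scale = attr(template, "scale")) {
  out <- structure(values,
                   standardized = standardized,
                   center = center, scale = scale,
                   class = class(template))
  if (inherits(template, "env_table")) attr(out, "log_flags") <- attr(template, "log_flags")
  if (inherits(template, "trait_table")) attr(out, "kinds") <- attr(template, "kinds")
  out
}

#' Impute missing cells by column mean or mode
#'
#' Deterministic single imputation: continuous columns receive the mean of
#' their observed values, binary (trait) columns the observed mode, with ties
#' resolved to 0. Environmental tables are treated as all-continuous. For
#' log-flagged environmental columns the mean is taken on the natural-log
#' scale and back-transformed, so that imputation and the later log transform
#' commute with the distributional assumption.
#'
#' @param table an [env_table()] or [trait_table()] (missing cells as `NA`).
#' @return the table with no missing cells; attribute `"imputed"` holds a
#'   logical mask of the filled cells.
#' @export
simple_impute <- function(table) {
  values <- unclass(table)
  mask <- is.na(values)
  if (!any(mask)) {
    attr(table, "imputed") <- mask
    return(table)
  }
  kinds <- attr(table, "kinds")
  if (is.null(kinds)) kinds <- rep("continuous", ncol(values))
  log_flags <- attr(table, "log_flags")
  if (is.null(log_flags)) log_flags <- rep(FALSE, ncol(values))
  for (k in seq_len(ncol(values))) {
    miss <- mask[, k]
    if (!any(miss)) next
    obs <- values[!miss, k]
    if (length(obs) == 0L)
      stop(sprintf("column '%s' is fully missing; cannot impute", colnames(values)[k]))
    fill <- if (kinds[k] == "binary") {
      n1 <- sum(obs == 1)
      n0 <- sum(obs == 0)
      if (n1 > n0) 1 else 0            # tie -> 0
    } else if (log_flags[k]) {
      exp(mean(log(obs)))
    } else {
      mean(obs)
    }
    values[miss, k] <- fill
  }
  out <- .rewrap(values, table)
  attr(out, "imputed") <- mask
  out
}

.standardize_matrix <- function(values, log_flags, label) {
  if (anyNA(values)) stop("missing cells present; impute before standardizing")
  for (l in which(log_flags)) {
    bad <- which(values[, l] <= 0)
    if (length(bad) > 0L)
      stop(sprintf("%s column '%s' has non-positive value at row %d; cannot log-transform",
                   label, colnames(values)[l], bad[1L]))
    values[, l] <- log(values[, l])
  }
  ctr <- colMeans(values)
  scl <- apply(values, 2L, stats::sd)     # n-1 sample sd
  zero <- which(scl < .Machine$double.eps * 100)
  if (length(zero) > 0L)
    stop(sprintf("%s column '%s' has zero variance", label, colnames(values)[zero[1L]]))
  values <- sweep(sweep(values, 2L, ctr, "-"), 2L, scl, "/")
  list(values = values, center = ctr, scale = scl)
}

#' Log-transform flagged columns and standardize every column
#'
#' Applies the natural log to the environmental columns flagged in the table,
#' then centres and scales every environmental and trait column to sample
#' mean 0 and sample standard deviation 1 (denominator `n - 1`). Binary
#' traits are standardized like continuous ones; their `kinds` metadata is
#' retained. Transformation parameters are stored for [inverse_transform()].
#'
#' @param env an [env_table()] with no missing cells, or `NULL`.
#' @param traits a [trait_table()] with no missing cells, or `NULL`.
#' @return list with elements `env` and `traits`, both standardized.
#' @export
transform_and_standardize <- function(env, traits = NULL) {
  env_out <- NULL
  if (!is.null(env)) {
    if (!inherits(env, "env_table")) env <- env_table(env)
    if (isTRUE(attr(env, "standardized")))
      stop("environmental table is already standardized")
    s <- .standardize_matrix(unclass(env), attr(env, "log_flags"), "environmental")
    env_out <- .rewrap(s$values, env, standardized = TRUE,
                       center = s$center, scale = s$scale)
  }
  traits_out <- NULL
  if (!is.null(traits)) {
    if (!inherits(traits, "trait_table")) traits <- trait_table(traits)
    if (isTRUE(attr(traits, "standardized")))
      stop("trait table is already standardized")
    st <- .standardize_matrix(unclass(traits), rep(FALSE, ncol(traits)), "trait")
    traits_out <- .rewrap(st$values, traits, standardized = TRUE,
                          center = st$center, scale = st$scale)
  }
  list(env = env_out, traits = traits_out)
}

#' Map a standardized table back to its raw scale
#'
#' Inverts [transform_and_standardize()] using the stored column means and
#' standard deviations, exponentiating log-flagged environmental columns.
#'
#' @param table a standardized [env_table()] or [trait_table()].
#' @return the table on the raw measurement scale.
#' @export
inverse_transform <- function(table) {
  if (!isTRUE(attr(table, "standardized")))
    stop("table is not standardized; nothing to invert")
  ctr <- attr(table, "center"); scl <- attr(table, "scale")
  if (is.null(ctr) || is.null(scl))
    stop("table lacks stored transformation parameters")
  values <- sweep(sweep(unclass(table), 2L, scl, "*"), 2L, ctr, "+")
  log_flags <- attr(table, "log_flags")
  if (!is.null(log_flags)) {
    for (l in which(log_flags)) values[, l] <- exp(values[, l])
  }
  out <- .rewrap(values, table, standardized = FALSE, center = NULL, scale = NULL)
  out
}

#' Drop species that occur in too few sites
#'
#' Retains a species if its number of presences divided by the number of
#' sites is at least `min_frac` (default 5% of sites, the usual screen for
#' rare species before niche modelling). Column order is preserved.
#'
#' @param occ an [occurrence_matrix()].
#' @param min_frac minimum occurrence fraction, strictly between 0 and 1.
#' @return the filtered `occurrence_matrix`.
#' @export
filter_rare_species <- function(occ, min_frac = 0.05) {
  if (!inherits(occ, "occurrence_matrix")) occ <- occurrence_matrix(occ)
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac <= 0 || min_frac >= 1)
    stop("min_frac must lie strictly between 0 and 1")
  frac <- colMeans(unclass(occ))
  keep <- frac >= min_frac
  if (!any(keep)) stop("all species fall below the occurrence threshold")
  out <- unclass(occ)[, keep, drop = FALSE]
  occurrence_matrix(out)
}

## ---- CSV readers / writers ------------------------------------------------

.read_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  values
}

#' Read the three community input tables from CSV
#'
#' All files are plain CSV with a header row; the first column holds site or
#' species ids. Missing cells may be empty fields or `NA`.
#'
#' @param path path to the CSV file.
#' @param log_flags,kinds metadata passed to the table constructors; for
#'   `read_env_csv`, `log_flags` may be a character vector of column names to
#'   flag.
#' @return the corresponding table object.
#' @rdname read_tables
#' @export
read_occurrence_csv <- function(path) {
  occurrence_matrix(.read_table_csv(path))
}

#' @rdname read_tables
#' @export
read_env_csv <- function(path, log_flags = NULL) {
  values <- .read_table_csv(path)
  if (is.null(log_flags)) log_flags <- rep(FALSE, ncol(values))
  if (is.character(log_flags)) {
    unknown <- setdiff(log_flags, colnames(values))
    if (length(unknown) > 0L)
      stop("log-flagged column not in table: ", paste(unknown, collapse = ", "))
    log_flags <- colnames(values) %in% log_flags
  }
  env_table(values, log_flags = log_flags)
}

#' @rdname read_tables
#' @export
read_traits_csv <- function(path, kinds = NULL) {
  trait_table(.read_table_csv(path), kinds = kinds)
}

#' Write a community table to CSV at full double precision
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces finite doubles bit for bit.
#'
#' @param table a matrix-like table with row ids.
#' @param path output path.
#' @param id_name header for the id column.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path, id_name = "id") {
  values <- unclass(table)
  chr <- matrix("", nrow(values), ncol(values))
  finite <- !is.na(values)
  chr[finite] <- sprintf("%.17g", values[finite])
  chr[!finite] <- "NA"
  df <- data.frame(rownames(values), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_name, colnames(values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
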