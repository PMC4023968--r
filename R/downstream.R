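#' Split species into two groups by the sign of their niche optimum
#'
#' Group 1 holds species with posterior mean optimum below the threshold,
#' group 2 the rest (ties go to group 2). On a standardized gradient the
#' default threshold 0 separates species preferring the low end from species
#' preferring the high end.
#'
#' @param opt_means posterior mean (or median) optima, one per species.
#' @param threshold split point on the gradient (default 0).
#' @param species optional species ids (taken from names otherwise).
#' @param gradient_name label of the gradient used for grouping.
#' @return a `species_groups` data frame with `species`, `opt` and `group`;
#'   the threshold and gradient name are attributes.
#' @export
classify_groups <- function(opt_means, threshold = 0, species = NULL,
                            gradient_name = "gradient") {
  if (is.null(species)) species <- names(opt_means)
  if (is.null(species)) species <- paste0("sp", seq_along(opt_means))
  out <- data.frame(species = species, opt = as.numeric(opt_means),
                    group = ifelse(opt_means < threshold, 1L, 2L),
                    stringsAsFactors = FALSE)
  structure(out, threshold = threshold, gradient_name = gradient_name,
            class = c("species_groups", "data.frame"))
}

#' Test trait differences between two species groups
#'
#' For each continuous trait a two-sided Wilcoxon rank-sum test between the
#' two groups (exact when both groups have at most `exact_max` members and
#' there are no ties, normal approximation with tie correction otherwise);
#' for each binary trait a chi-square test on the 2x2 cross-tabulation of
#' trait value by group (no continuity correction by default). Group means,
#' standard deviations and counts are reported alongside.
#'
#' @param groups a [classify_groups()] result.
#' @param traits a [trait_table()] for the same species (transformed /
#'   standardized values are tested; binary traits are tabulated by their two
#'   distinct values).
#' @param correct apply the continuity correction in the chi-square test.
#' @param exact_max largest group size for which the Wilcoxon test is exact.
#' @return data frame per trait: `trait`, `kind`, `test`, `statistic`,
#'   `p_value`, group means/sds/counts, and a `note` (e.g. a skipped
#'   zero-variance trait).
#' @export
trait_difference_tests <- function(groups, traits, correct = FALSE,
                                   exact_max = 6L) {
  Z <- unclass(traits)
  if (nrow(Z) != nrow(groups))
    stop("trait table rows must match the number of grouped species")
  kinds <- attr(traits, "kinds")
  if (is.null(kinds)) kinds <- rep("continuous", ncol(Z))
  g <- groups$group
  n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 species")
  rows <- lapply(seq_len(ncol(Z)), function(k) {
    v <- Z[, k]
    v1 <- v[g == 1L]; v2 <- v[g == 2L]
    base <- data.frame(trait = colnames(Z)[k], kind = kinds[k],
                       test = NA_character_, statistic = NA_real_,
                       p_value = NA_real_,
                       mean1 = mean(v1), sd1 = stats::sd(v1),
                       mean2 = mean(v2), sd2 = stats::sd(v2),
                       n1 = n1, n2 = n2, note = "",
                       stringsAsFactors = FALSE)
    if (kinds[k] == "binary") {
      tab <- table(factor(v, levels = sort(unique(v))), factor(g, levels = c(1L, 2L)))
      if (nrow(tab) < 2L) {
        base$note <- "constant trait; test skipped"
        return(base)
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      base$test <- "chi-square"
      base$statistic <- unname(ct$statistic)
      base$p_value <- ct$p.value
    } else {
      if (stats::sd(v) == 0) {
        base$note <- "zero-variance trait; test skipped"
        return(base)
      }
      exact <- n1 <= exact_max && n2 <= exact_max && !any(duplicated(v))
      wt <- suppressWarnings(stats::wilcox.test(v1, v2, exact = exact,
                                                correct = !exact))
      base$test <- "wilcoxon"
      base$statistic <- unname(wt$statistic)
      base$p_value <- wt$p.value
    }
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "chisq_correct") <- correct
  out
}
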