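#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an engagement regression fit
#'
#' @param x An [engagement_regression()] result.
#' @param ... Unused.
#' @return The full model-ranking tibble (`model`, `k`, `r_squared`,
#'   `bic`, `post_prob`, `rank`).
#' @method tidy engagement_fit
#' @export
tidy.engagement_fit <- function(x, ...) x$models

#' @rdname tidy.engagement_fit
#' @return For `glance()`: a one-row tibble with the selected model, its
#'   R-squared and posterior probability, and the window count.
#' @method glance engagement_fit
#' @export
glance.engagement_fit <- function(x, ...) {
  tibble::tibble(best_model = x$best_model,
                 r_squared = x$best_r_squared,
                 post_prob = x$models$post_prob[1],
                 n_windows = x$n_windows,
                 n_models = nrow(x$models))
}

#' Tidy a permutation-test result
#' @param x A [permutation_test_proximity()] result.
#' @param ... Unused.
#' @return One-row tibble with `r_obs`, `p`, `n_perm`, `n_pairs`,
#'   `alternative`, `p_rule`, `seed`.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(r_obs = x$r_obs, p = x$p, n_perm = x$n_perm,
                 n_pairs = x$n_pairs, alternative = x$alternative,
                 p_rule = x$p_rule, seed = x$seed)
}

#' Tidy a Bayes-factor result
#' @param x A [bf_paired_ttest()] or [bf_correlation()] result.
#' @param ... Unused.
#' @return One-row tibble with `bf10`, `method`, `posterior_median`,
#'   `ci_low`, `ci_high`.
#' @method tidy bayes_result
#' @export
tidy.bayes_result <- function(x, ...) {
  tibble::tibble(bf10 = x$bf10, method = x$method,
                 posterior_median = x$posterior_median,
                 ci_low = x$ci[1], ci_high = x$ci[2])
}

#' Tidy a group contrast
#' @param x A [group_contrast()] result.
#' @param ... Unused.
#' @return The cell-means tibble.
#' @method tidy group_contrast
#' @export
tidy.group_contrast <- function(x, ...) x$cell_means

#' @rdname tidy.group_contrast
#' @method glance group_contrast
#' @export
glance.group_contrast <- function(x, ...) {
  tibble::tibble(best_model = x$models$model[1],
                 post_prob = x$models$post_prob[1], n_pairs = x$n_pairs)
}

#' Tidy a cross-expression matrix into long format
#' @param x A [between_expression_matrix()] or
#'   [individual_vs_rest_matrix()] result.
#' @param ... Unused.
#' @return Tibble with `expression_row`, `expression_col`, `r`.
#' @method tidy cross_expression_matrix
#' @export
tidy.cross_expression_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    expression_row = .channel_factor(rep(rownames(m), times = ncol(m))),
    expression_col = .channel_factor(rep(colnames(m), each = nrow(m))),
    r = as.vector(m))
}
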