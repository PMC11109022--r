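#' Euclidean seat distance
#'
#' Adjacent seats on a row and similarly numbered seats on adjacent rows
#' are both 1 seat unit apart, so the distance between seats
#' `(row_a, seat_a)` and `(row_b, seat_b)` is
#' `sqrt((row_a - row_b)^2 + (seat_a - seat_b)^2)`.
#'
#' @param a,b Length-2 vectors `c(row, seat)` or 2-column matrices (row,
#'   seat) of equal height for vectorized use.
#' @return Numeric distance(s) in seat units.
#' @export
#' @examples
#' seat_distance(c(0, 0), c(0, 1))  # 1
#' seat_distance(c(0, 0), c(1, 1))  # sqrt(2)
seat_distance <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 2)
  if (!is.matrix(b)) b <- matrix(b, ncol = 2)
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

# Vectorized pair feature computation shared by pairwise_isc().
pair_features_table <- function(age_a, age_b, empathy_a, empathy_b,
                                gender_a, gender_b) {
  gender_group <- dplyr::case_when(
    gender_a == "female" & gender_b == "female" ~ "female",
    gender_a == "male" & gender_b == "male" ~ "male",
    gender_a %in% c("female", "male") &
      gender_b %in% c("female", "male") ~ "different",
    TRUE ~ "excluded")
  age_group <- dplyr::case_when(
    is.na(age_a) | is.na(age_b) ~ NA_character_,
    age_a < 25 & age_b < 25 ~ "young",
    age_a > 25 & age_b > 25 ~ "old",
    TRUE ~ "different")  # mixed pairs, and any member aged exactly 25
  tibble::tibble(
    total_age = age_a + age_b,
    total_empathy = empathy_a + empathy_b,
    gender_group = gender_group,
    age_group = age_group)
}

#' Combined characteristics of a participant pair
#'
#' Total (summed) age and empathy, plus the gender and age groupings used
#' by the group contrasts: a pair is `"female"`/`"male"` only when both
#' members share that gender, `"different"` for mixed female/male pairs,
#' and `"excluded"` when either member's gender is other/unknown. A pair
#' is `"young"` when both are under 25 and `"old"` when both are over 25;
#' anything else — including a member aged exactly 25 — is `"different"`.
#' Missing age or empathy makes the corresponding output missing.
#'
#' @param info_a,info_b Single-row data frames (or lists) with `age`,
#'   `gender`, `empathy_total`.
#' @return One-row tibble with `total_age`, `total_empathy`,
#'   `gender_group`, `age_group`.
#' @export
pair_features <- function(info_a, info_b) {
  pair_features_table(info_a$age, info_b$age,
                      info_a$empathy_total, info_b$empathy_total,
                      info_a$gender, info_b$gender)
}

# Rows of a pair table for one expression with finite z.
.pair_rows <- function(table, expression) {
  expression <- .match_channel(expression)
  stopifnot(inherits(table, "pair_isc_table"))
  sub <- table[table$expression == expression & !is.na(table$z), ,
               drop = FALSE]
  tibble::as_tibble(sub)
}

#' Correlation between pair synchrony and seat proximity
#'
#' Pearson correlation across pairs between the square root of seat
#' distance (the square root keeps the distance distribution close to
#' normal) and the Fisher-z pair ISC for one expression. A negative value
#' means closer pairs are more synchronized.
#'
#' @param table A [pairwise_isc()] table.
#' @param expression One of [expression_channels()].
#' @return Single correlation; `NA` with a warning when either variable
#'   has zero variance.
#' @export
proximity_correlation <- function(table, expression) {
  sub <- .pair_rows(table, expression)
  sub <- sub[!is.na(sub$seat_distance), , drop = FALSE]
  if (nrow(sub) < 4L) {
    stop("need at least 4 pairs with defined ISC and distance",
         call. = FALSE)
  }
  x <- sqrt(sub$seat_distance)
  if (stats::sd(x) == 0 || stats::sd(sub$z) == 0) {
    warning("zero variance: proximity correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, sub$z)
}

#' Permutation test for the proximity-synchrony correlation
#'
#' Shuffles the Fisher-z pair ISC values across pairs `n_perm` times,
#' recomputing the correlation with sqrt(seat distance) each time, and
#' reports the proportion of permuted correlations at least as extreme as
#' the observed one in the tested direction. Because the "greater than or
#' equal to the observed" counting rule is ambiguous for negative
#' observed correlations, three p-value rules are exposed: `"plain"`
#' (k/n in the tested direction, the default), `"add_one"`
#' ((k+1)/(n+1)), and `"ge_observed"` (proportion of permuted r >=
#' observed r regardless of direction).
#'
#' @param table A [pairwise_isc()] table.
#' @param expression One of [expression_channels()].
#' @param n_perm Number of permutations (default 10000; < 100 warns).
#' @param seed Integer seed making the draw reproducible.
#' @param alternative Direction of the tested hypothesis: `"negative"`
#'   (closer pairs more synchronized; default) or `"positive"`.
#' @param p_rule `"plain"`, `"add_one"` or `"ge_observed"`.
#' @return Object of class `permutation_result`: list with `r_obs`, `p`,
#'   `n_perm`, `n_pairs`, `seed`, `alternative`, `p_rule`.
#' @export
permutation_test_proximity <- function(table, expression, n_perm = 10000L,
                                       seed = 1L,
                                       alternative = c("negative",
                                                       "positive"),
                                       p_rule = c("plain", "add_one",
                                                  "ge_observed")) {
  alternative <- match.arg(alternative)
  p_rule <- match.arg(p_rule)
  if (n_perm < 100L) warning("n_perm < 100: p resolution is coarse",
                             call. = FALSE)
  sub <- .pair_rows(table, expression)
  sub <- sub[!is.na(sub$seat_distance), , drop = FALSE]
  if (nrow(sub) < 4L) {
    stop("need at least 4 pairs with defined ISC and distance",
         call. = FALSE)
  }
  x <- sqrt(sub$seat_distance)
  z <- sub$z
  r_obs <- stats::cor(x, z)
  set.seed(seed)
  m <- length(z)
  r_perm <- numeric(n_perm)
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    take <- min(chunk, n_perm - done)
    zp <- vapply(seq_len(take), function(i) z[sample.int(m)], numeric(m))
    r_perm[(done + 1L):(done + take)] <- as.numeric(stats::cor(x, zp))
    done <- done + take
  }
  k <- switch(alternative,
              negative = sum(r_perm <= r_obs),
              positive = sum(r_perm >= r_obs))
  p <- switch(p_rule,
              plain = k / n_perm,
              add_one = (k + 1) / (n_perm + 1),
              ge_observed = sum(r_perm >= r_obs) / n_perm)
  structure(list(r_obs = r_obs, p = p, n_perm = as.integer(n_perm),
                 n_pairs = m, seed = as.integer(seed),
                 alternative = alternative, p_rule = p_rule),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> r_obs = %.4f, p = %.4g (%s, %s rule, %d permutations, %d pairs, seed %d)\n",
    x$r_obs, x$p, x$alternative, x$p_rule, x$n_perm, x$n_pairs, x$seed))
  invisible(x)
}

#' Association between pair characteristics and synchrony
#'
#' Correlates one combined pair characteristic (total age or total
#' empathy) with the Fisher-z pair ISC of one expression, with a Bayes
#' factor under the directional prior (positive for empathy, negative for
#' age — the hypothesized directions), and compares the four regressions
#' over both characteristics (null, age, empathy, age + empathy) with the
#' BIC-based proxy.
#'
#' @param table A [pairwise_isc()] table.
#' @param feature `"total_age"` or `"total_empathy"`.
#' @param expression One of [expression_channels()].
#' @param bayes A [bayes_spec()].
#' @return Object of class `feature_association`: list with `correlation`
#'   (tibble: `feature`, `expression`, `n_pairs`, `r`, `z`, `bf10`,
#'   `direction`) and `models` (tibble over the four candidate models with
#'   `r_squared`, `bic`, `post_prob`, `rank`).
#' @export
feature_association <- function(table,
                                feature = c("total_age", "total_empathy"),
                                expression, bayes = bayes_spec()) {
  feature <- match.arg(feature)
  sub <- .pair_rows(table, expression)
  v <- sub[[feature]]
  if (all(is.na(v))) stop("feature '", feature, "' entirely missing",
                          call. = FALSE)
  ok <- !is.na(v)
  if (sum(ok) < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  direction <- if (feature == "total_age") "negative" else "positive"
  if (stats::sd(v[ok]) == 0 || stats::sd(sub$z[ok]) == 0) {
    warning("zero variance: association undefined", call. = FALSE)
    corr <- tibble::tibble(feature = feature, expression = expression,
                           n_pairs = sum(ok), r = NA_real_, z = NA_real_,
                           bf10 = NA_real_, direction = direction)
  } else {
    r <- stats::cor(v[ok], sub$z[ok])
    # one-sided BF in the hypothesized direction: flip the sign for
    # negative-direction hypotheses so the positive-truncated prior applies
    r_dir <- if (direction == "negative") -r else r
    bf <- bf_correlation(pmin(pmax(r_dir, -1 + 1e-7), 1 - 1e-7),
                         sum(ok), bayes)
    corr <- tibble::tibble(feature = feature, expression = expression,
                           n_pairs = sum(ok), r = r, z = fisher_z(r),
                           bf10 = bf$bf10, direction = direction)
  }
  both <- !is.na(sub$total_age) & !is.na(sub$total_empathy)
  models <- NULL
  if (sum(both) >= 5L &&
      stats::sd(sub$total_age[both]) > 0 &&
      stats::sd(sub$total_empathy[both]) > 0) {
    y <- sub$z[both]
    n <- length(y)
    tss <- sum((y - mean(y))^2)
    design <- list(
      "(null)" = NULL,
      "total_age" = cbind(sub$total_age[both]),
      "total_empathy" = cbind(sub$total_empathy[both]),
      "total_age + total_empathy" = cbind(sub$total_age[both],
                                          sub$total_empathy[both]))
    fits <- purrr::imap(design, function(X, nm) {
      if (is.null(X)) {
        rss <- tss; k <- 1L
      } else {
        fit <- stats::lm.fit(cbind(1, X), y)
        rss <- sum(fit$residuals^2)
        k <- ncol(X) + 1L
      }
      tibble::tibble(model = nm, k = k, rss = max(rss, 1e-12 * tss),
                     r_squared = 1 - rss / tss)
    })
    mods <- dplyr::bind_rows(fits)
    scores <- bic_model_scores(mods, n)
    models <- dplyr::arrange(
      dplyr::bind_cols(mods[, c("model", "k", "r_squared")],
                       scores[, c("bic", "post_prob", "rank")]),
      .data$rank)
  }
  structure(list(correlation = corr, models = models),
            class = "feature_association")
}

#' @export
print.feature_association <- function(x, ...) {
  with(x$correlation, cat(sprintf(
    "<feature_association> %s vs %s ISC: r = %.3f (n = %d pairs), BF10 = %.3g (%s direction)\n",
    feature, expression, r, n_pairs, bf10, direction)))
  if (!is.null(x$models)) {
    cat("  best model:", x$models$model[1], "\n")
  }
  invisible(x)
}

#' Gender and age group contrast of pair synchrony
#'
#' Cell means of Fisher-z pair ISC per (gender group, age group) cell,
#' plus a model comparison of `z ~ age_group` (the null, since the age
#' effect is assessed separately), `z ~ age_group + gender_group`, and
#' `z ~ age_group * gender_group`, scored with the BIC proxy. Pairs with
#' excluded gender or missing age group are dropped; empty cells are
#' reported, never fabricated.
#'
#' @param table A [pairwise_isc()] table.
#' @param expression One of [expression_channels()].
#' @return Object of class `group_contrast`: list with `cell_means`
#'   (tibble: `gender_group`, `age_group`, `n_pairs`, `mean_z`),
#'   `models` tibble and `n_pairs`.
#' @export
group_contrast <- function(table, expression) {
  sub <- .pair_rows(table, expression)
  sub <- sub[sub$gender_group != "excluded" & !is.na(sub$age_group), ,
             drop = FALSE]
  if (length(unique(sub$gender_group)) < 2L) {
    stop("group contrast needs >= 2 gender groups", call. = FALSE)
  }
  if (nrow(sub) < 4L) stop("too few pairs for a group contrast",
                           call. = FALSE)
  cells <- dplyr::summarise(
    dplyr::group_by(sub, .data$gender_group, .data$age_group),
    n_pairs = dplyr::n(), mean_z = mean(.data$z), .groups = "drop")
  y <- sub$z
  n <- length(y)
  gg <- factor(sub$gender_group); ag <- factor(sub$age_group)
  # a single observed age group degenerates the age terms to the intercept
  one_age <- nlevels(droplevels(ag)) < 2L
  fit_rss <- function(formula_x) {
    X <- stats::model.matrix(formula_x, data.frame(gg = gg, ag = ag))
    fit <- stats::lm.fit(X, y)
    list(rss = sum(fit$residuals^2), k = qr(X)$rank)
  }
  f_null <- fit_rss(if (one_age) ~1 else ~ag)
  f_gender <- fit_rss(if (one_age) ~gg else ~ag + gg)
  f_inter <- fit_rss(if (one_age) ~gg else ~ag * gg)
  tss <- sum((y - mean(y))^2)
  mods <- tibble::tibble(
    model = c("age", "age + gender", "age * gender"),
    k = c(f_null$k, f_gender$k, f_inter$k),
    rss = pmax(c(f_null$rss, f_gender$rss, f_inter$rss), 1e-12 * tss))
  scores <- bic_model_scores(mods, n)
  models <- dplyr::arrange(
    dplyr::bind_cols(
      dplyr::mutate(mods[, c("model", "k")],
                    r_squared = 1 - mods$rss / tss),
      scores[, c("bic", "post_prob", "rank")]),
    .data$rank)
  structure(list(cell_means = cells, models = models, n_pairs = n),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %d pairs; best model: %s (post prob %.3f)\n",
              x$n_pairs, x$models$model[1], x$models$post_prob[1]))
  print(x$cell_means)
  invisible(x)
}
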