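# Accuracy statistics against reference measurements.

#' Root-mean-square error of paired measurements
#'
#' `RMSE = sqrt(sum((v - v_ref)^2) / n)`.
#'
#' @param v Measured values (proposed method), one per tree.
#' @param v_ref Reference values (manual delineation or field survey),
#'   aligned with `v`.
#' @return RMSE in the units of the feature.
#' @export
rmse <- function(v, v_ref) {
  if (length(v) != length(v_ref)) stop("v and v_ref differ in length")
  if (length(v) < 1L) stop("need at least one pair")
  sqrt(sum((v - v_ref)^2) / length(v))
}

#' Relative RMSE (percent of the reference mean)
#'
#' `R-RMSE = RMSE / mean(v_ref)`, reported as a percentage.
#'
#' @inheritParams rmse
#' @return Relative RMSE in percent.
#' @export
r_rmse <- function(v, v_ref) {
  m <- mean(v_ref)
  if (m == 0) stop("reference mean is zero; relative RMSE undefined")
  100 * rmse(v, v_ref) / m
}

#' Squared Pearson correlation of paired measurements
#'
#' @inheritParams rmse
#' @return R-squared between 0 and 1.
#' @export
r_squared <- function(v, v_ref) {
  if (length(v) != length(v_ref)) stop("v and v_ref differ in length")
  if (length(v) < 2L) stop("need at least two pairs")
  if (sd(v) == 0 || sd(v_ref) == 0)
    stop("correlation undefined for a constant vector")
  cor(v, v_ref)^2
}

#' Evaluate crown measurements against a reference table
#'
#' Joins predicted and reference records by `tree_id` (unmatched ids on
#' either side are reported and excluded) and computes R-squared, RMSE and
#' relative RMSE per feature.
#'
#' @param pred Data frame of predicted crown records (e.g. from
#'   [crown_metrics()]); must contain `tree_id` and the feature columns.
#' @param ref Data frame of reference values with `tree_id` and the same
#'   feature columns.
#' @param features Character vector of feature columns to evaluate.
#' @return An object of class `crown_eval`; see [tidy.crown_eval()],
#'   [glance.crown_eval()] and [autoplot.crown_eval()].
#' @export
evaluate_crowns <- function(pred, ref,
                            features = c("W1_m", "W2_m", "CPA_m2")) {
  pred <- as_tibble(as.data.frame(pred))
  ref <- as_tibble(as.data.frame(ref))
  for (f in c("tree_id", features)) {
    if (!f %in% names(pred)) stop("predicted table missing column: ", f)
    if (!f %in% names(ref)) stop("reference table missing column: ", f)
  }
  unmatched_pred <- setdiff(pred$tree_id, ref$tree_id)
  unmatched_ref <- setdiff(ref$tree_id, pred$tree_id)
  joined <- dplyr::inner_join(
    dplyr::select(pred, dplyr::all_of(c("tree_id", features))),
    dplyr::select(ref, dplyr::all_of(c("tree_id", features))),
    by = "tree_id", suffix = c("_pred", "_ref")
  )
  if (nrow(joined) < 2L) stop("fewer than two matched tree_ids")
  stats <- dplyr::bind_rows(lapply(features, function(f) {
    v <- joined[[paste0(f, "_pred")]]
    vr <- joined[[paste0(f, "_ref")]]
    tibble(
      feature = f, n = nrow(joined),
      r_squared = r_squared(v, vr),
      rmse = rmse(v, vr),
      r_rmse_pct = r_rmse(v, vr)
    )
  }))
  structure(list(
    stats = stats, pairs = joined,
    unmatched_pred = unmatched_pred, unmatched_ref = unmatched_ref
  ), class = "crown_eval")
}

#' @export
print.crown_eval <- function(x, ...) {
  cat("<crown_eval>", nrow(x$pairs), "matched trees")
  if (length(x$unmatched_pred) || length(x$unmatched_ref))
    cat(sprintf(" (%d pred / %d ref unmatched, excluded)",
                length(x$unmatched_pred), length(x$unmatched_ref)))
  cat("\n")
  print(x$stats)
  invisible(x)
}

#' Tidy a crown evaluation
#'
#' @param x A `crown_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `n`, `r_squared`,
#'   `rmse`, `r_rmse_pct`.
#' @method tidy crown_eval
#' @export
tidy.crown_eval <- function(x, ...) x$stats

#' One-row summary of a crown evaluation
#'
#' @param x A `crown_eval` object.
#' @param ... Unused.
#' @return One-row tibble: matched pair count, unmatched counts, and the
#'   number of features evaluated.
#' @method glance crown_eval
#' @export
glance.crown_eval <- function(x, ...) {
  tibble(
    n_trees = nrow(x$pairs),
    n_features = nrow(x$stats),
    n_unmatched_pred = length(x$unmatched_pred),
    n_unmatched_ref = length(x$unmatched_ref)
  )
}

#' Scatter plot of predicted vs reference values per feature
#'
#' @param object A `crown_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crown_eval
#' @export
autoplot.crown_eval <- function(object, ...) {
  long <- dplyr::bind_rows(lapply(object$stats$feature, function(f) {
    tibble(
      feature = f,
      reference = object$pairs[[paste0(f, "_ref")]],
      predicted = object$pairs[[paste0(f, "_pred")]]
    )
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = "reference", y = "proposed method") +
    ggplot2::theme_minimal()
}
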