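#' Tidy a step-model fit
#'
#' @param x A `step_model_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`: the baseline steps/s intercept and the
#'   steps/AP slope.
#' @export
tidy.step_model_fit <- function(x, ...) {
  tibble(term = c("steps_base", "steps_ap"),
         estimate = c(x$steps_base, x$steps_ap))
}

#' @rdname tidy.step_model_fit
#' @return For `glance()`: one-row tibble `r_squared`, `n_points`.
#' @export
glance.step_model_fit <- function(x, ...) {
  tibble(r_squared = x$fit_r2, n_points = x$n_points)
}

#' Tidy a PCA model
#'
#' @param x A `pca_model` from [pca_reduce()].
#' @param ... Unused.
#' @return Long tibble `feature`, `component`, `loading` for the retained
#'   components.
#' @export
tidy.pca_model <- function(x, ...) {
  l <- as.data.frame(x$loadings)
  l$feature <- rownames(x$loadings)
  tidyr::pivot_longer(as_tibble(l), -"feature",
                      names_to = "component", values_to = "loading")
}

#' @rdname tidy.pca_model
#' @return For `glance()`: `n_retained`, `variance_threshold`,
#'   `explained_variance`.
#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_retained = x$n_retained,
         variance_threshold = x$variance_threshold,
         explained_variance =
           sum(x$explained_variance_fractions[seq_len(x$n_retained)]))
}

#' Tidy a nested cluster tree
#'
#' @param x A `cluster_tree` from [run_nested_clustering()].
#' @param ... Unused.
#' @return The assignments tibble (`model_id`, `level1`, `level2`, `level3`,
#'   `final_label`, `level1_noise`).
#' @export
tidy.cluster_tree <- function(x, ...) x$assignments

#' @rdname tidy.cluster_tree
#' @return For `glance()`: one-row tibble with per-level cluster counts and
#'   the noise fraction before reassignment.
#' @export
glance.cluster_tree <- function(x, ...) {
  a <- x$assignments
  tibble(n_models = nrow(a),
         k_level1 = length(unique(a$level1)),
         k_level2 = length(unique(a$level2[!is.na(a$level2)])),
         k_level3 = length(unique(a$level3[!is.na(a$level3)])),
         noise_fraction = mean(a$level1_noise))
}

#' Tidy a channel cluster set
#'
#' @param x A `channel_cluster_set` from [cluster_channels()].
#' @param ... Unused.
#' @return The labels tibble (`model_id`, `cluster`).
#' @export
tidy.channel_cluster_set <- function(x, ...) x$labels

#' @rdname tidy.channel_cluster_set
#' @export
glance.channel_cluster_set <- function(x, ...) {
  tab <- table(x$labels$cluster)
  tibble(n_models = nrow(x$labels),
         n_clusters = length(tab),
         n_singletons = sum(tab == 1))
}
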