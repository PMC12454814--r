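#' Tidy a group comparison
#'
#' One row per group pair: mean difference, Welch t statistic and p-value.
#'
#' @param x A `tailshift_groupcomp`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tailshift_groupcomp <- function(x, ...) {
  x$pairwise
}

#' Glance at a group comparison
#'
#' One row: the omnibus method (one-way ANOVA, or the Welch t test itself
#' for two groups), its statistic, degrees of freedom, p-value and the
#' number of groups.
#'
#' @param x A `tailshift_groupcomp`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.tailshift_groupcomp <- function(x, ...) {
  x$omnibus %>% mutate(n_groups = nrow(x$summary),
                       n_items = sum(x$summary$n))
}
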