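#' Poly(A)-tail-length distributions by stage
#'
#' Boxplots of per-read tail lengths per stage, optionally split by the
#' full-length flag.
#'
#' @param reads Read table.
#' @param by_full_length Facet by the full-length flag.
#' @return A ggplot.
#' @export
plot_pal_distribution <- function(reads, by_full_length = FALSE) {
  df <- reads %>% filter(!is.na(polya_len))
  p <- ggplot(df, aes(x = stage, y = polya_len)) +
    geom_boxplot(outlier.size = 0.3, fill = "grey85") +
    labs(x = NULL, y = "poly(A) tail length (nt)") +
    theme_bw()
  if (by_full_length) {
    p <- p + facet_wrap(~ full_length,
                        labeller = labeller(full_length = c(
                          `TRUE` = "full-length", `FALSE` = "non-full-length")))
  }
  p
}

#' Metagene density profile
#'
#' Line plot of the normalized site density along the scaled
#' 5'UTR | CDS | 3'UTR axis, with region boundaries marked.
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  B <- nrow(profile) / 3
  ggplot(profile, aes(x = bin, y = density)) +
    geom_line() +
    geom_vline(xintercept = c(B, 2 * B) + 0.5, linetype = "dashed",
               colour = "grey50") +
    annotate("text", x = c(B / 2, 1.5 * B, 2.5 * B), y = Inf,
             label = c("5'UTR", "CDS", "3'UTR"), vjust = 1.5, size = 3) +
    labs(x = "scaled transcript position (bins)", y = "site density") +
    theme_bw()
}

#' Proximal/distal usage-change scatter for an APA result
#'
#' Plots each gene's log2 proximal-count change against its log2
#' distal-count change between the two conditions, coloured by shift
#' class.
#'
#' @param object A `tailshift_apa` result from [apa_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tailshift_apa <- function(object, ...) {
  c0 <- attr(object, "params")$pseudocount %||% 1
  df <- object %>%
    mutate(ppas_change = log2((ppas_2 + c0) / (ppas_1 + c0)),
           dpas_change = log2((dpas_2 + c0) / (dpas_1 + c0)))
  ggplot(df, aes(x = .data$ppas_change, y = .data$dpas_change,
                 colour = shift_class)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    labs(x = "pPAS log2 change", y = "dPAS log2 change",
         colour = "shift class") +
    theme_bw()
}

#' Boxplot of a group comparison
#'
#' @param object A `tailshift_groupcomp`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tailshift_groupcomp <- function(object, ...) {
  ggplot(object$data, aes(x = group, y = value)) +
    geom_boxplot(outlier.size = 0.3, fill = "grey85") +
    labs(x = NULL, y = "value",
         subtitle = sprintf("%s p = %.3g", object$omnibus$method,
                            object$omnibus$p_value)) +
    theme_bw()
}
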