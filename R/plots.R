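#' Plot PCA scores
#'
#' @param object a `geno_pca`
#' @param colour optional vector (one per individual) to colour points by,
#'   e.g. cluster labels or fire category
#' @param pcs which two components to draw (default `c(1, 2)`)
#' @param ... unused
#' @return A ggplot.
#' @export
autoplot.geno_pca <- function(object, colour = NULL, pcs = c(1, 2), ...) {
  df <- tidy(object)
  xn <- paste0("PC", pcs[1]); yn <- paste0("PC", pcs[2])
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot(df, aes(x = .data[[xn]], y = .data[[yn]])) +
    labs(
      x = sprintf("%s (%.1f%%)", xn, 100 * object$explained[pcs[1]]),
      y = sprintf("%s (%.1f%%)", yn, 100 * object$explained[pcs[2]])) +
    theme_minimal()
  if (is.null(colour)) p + geom_point() else
    p + geom_point(aes(colour = .data$colour)) + labs(colour = NULL)
}

#' Plot the filter attrition ledger
#'
#' @param object a `filter_report`
#' @param ... unused
#' @return A ggplot of loci remaining after each stage.
#' @export
autoplot.filter_report <- function(object, ...) {
  df <- object$stages %>%
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot(df, aes(x = .data$stage, y = .data$n_after)) +
    geom_col(fill = "grey35") +
    geom_text(aes(label = .data$n_after), vjust = -0.4, size = 3) +
    labs(x = NULL, y = "loci remaining") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Plot the pairwise kinship distribution
#'
#' @param object a `kinship_result`
#' @param threshold clonality cutoff drawn as a dashed line (default 0.45)
#' @param ... unused
#' @return A ggplot histogram of phi.
#' @export
autoplot.kinship_result <- function(object, threshold = 0.45, ...) {
  df <- filter(object$pairs, !is.na(.data$phi))
  ggplot(df, aes(x = .data$phi)) +
    geom_histogram(bins = 50, fill = "grey35") +
    geom_vline(xintercept = threshold, linetype = 2, colour = "firebrick") +
    labs(x = "pairwise kinship (phi)", y = "pairs") +
    theme_minimal()
}

#' Plot an outlier scan
#'
#' @param object an `outlier_scan` tibble
#' @param ... unused
#' @return A ggplot of -log10 p by locus order, outliers highlighted,
#'   one facet per covariate.
#' @export
autoplot.outlier_scan <- function(object, ...) {
  df <- object %>% group_by(.data$covariate) %>%
    mutate(index = row_number()) %>% ungroup()
  ggplot(df, aes(x = .data$index, y = -log10(.data$p_value),
                 colour = .data$is_outlier)) +
    geom_point(size = 0.6) +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "dodgerblue3"),
                        guide = "none") +
    facet_wrap(~covariate) +
    labs(x = "locus", y = expression(-log[10](p))) +
    theme_minimal()
}

#' Plot fire-model coefficients
#'
#' @param object a `fire_model`
#' @param ... unused
#' @return A ggplot dot-and-whisker of estimates with ~95% intervals.
#' @export
autoplot.fire_model <- function(object, ...) {
  df <- object$coefs %>%
    mutate(lo = .data$estimate - 1.96 * .data$std_error,
           hi = .data$estimate + 1.96 * .data$std_error)
  ggplot(df, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = 3) +
    geom_pointrange(aes(xmin = .data$lo, xmax = .data$hi)) +
    labs(x = sprintf("coefficient (%s, %s)", object$response, object$family),
         y = NULL) +
    theme_minimal()
}

#' Heatmap of a pairwise matrix
#'
#' @param object a `pairwise_matrix`
#' @param ... unused
#' @return A ggplot tile heatmap.
#' @export
autoplot.pairwise_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$id_a, y = .data$id_b, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = object$kind) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6),
          axis.text.y = element_text(size = 6))
}
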