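#' Plot a Kaplan-Meier curve set
#'
#' Step curves of survival probability per group, with censoring ticks.
#'
#' @param object A `km_curve` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(group = unique(object$group), time = 0, surv = 1),
    object[, c("group", "time", "surv")]
  )
  cens <- object[object$n_censor > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability",
                  colour = "Group") +
    ggplot2::theme_minimal()
  if (nrow(cens) > 0) {
    p <- p + ggplot2::geom_point(data = cens, shape = 3, size = 1.5)
  }
  p
}

#' @rdname autoplot.km_curve
#' @export
autoplot.stratification <- function(object, ...) {
  autoplot(object$km) +
    ggplot2::labs(
      title = paste0("Stratification by ", object$criterion),
      subtitle = sprintf("log-rank p = %.3g%s", object$p,
                         if (!is.null(object$cutpoint) &&
                             !is.na(object$cutpoint %||% NA)) {
                           paste0(", cutpoint = ",
                                  format(object$cutpoint))
                         } else "")
    )
}

#' Plot 96-context signature profiles
#'
#' Bar profiles over the 96 trinucleotide context bins, faceted by
#' signature, in the conventional substitution-type layout.
#'
#' @param object A `signature_fit` from [extract_signatures()], or a
#'   k x 96 matrix of profiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_fit <- function(object, ...) {
  plot_signature_profiles(object$signatures)
}

#' @rdname autoplot.signature_fit
#' @param profiles k x 96 matrix with rows as profiles.
#' @export
plot_signature_profiles <- function(profiles) {
  bins <- sbs_contexts()
  df <- as_tibble(t(profiles))
  df$context <- factor(bins, levels = bins)
  df$substitution <- sub(".*\\[(.*)\\].*", "\\1", bins)
  long <- tidyr::pivot_longer(df, -c("context", "substitution"),
                              names_to = "signature",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$context,
                                     y = .data$fraction,
                                     fill = .data$substitution)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(signature ~ substitution, scales = "free_x",
                        space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank(),
                   legend.position = "none") +
    ggplot2::labs(x = "Trinucleotide context", y = "Fraction of mutations")
}
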