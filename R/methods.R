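#' @export
print.trend_fit <- function(x, ...) {
  cat("Log-slant trend fit of the disparity weight\n")
  cat(sprintf("  %d subjects, %d cell means, %d bootstrap replicates\n",
              x$n_subjects, x$n_cells, x$n_boot))
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trend_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.trend_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared,
         sigma = s$sigma,
         n_subjects = x$n_subjects,
         n_cells = x$n_cells,
         n_boot = x$n_boot,
         conf = x$conf)
}

#' @exportS3Method ggplot2::autoplot
autoplot.trend_fit <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "Disparity-weight trend coefficients",
                  subtitle = sprintf("subject-level bootstrap, %d replicates",
                                     object$n_boot)) +
    ggplot2::theme_minimal()
}

#' @export
print.pre_post_test <- function(x, ...) {
  cat("Paired pre/post sign-flip permutation test (max-T adjusted)\n")
  cat(sprintf("  %d subjects, %d permutations, alpha = %g\n",
              x$n_subjects, x$n_perm, x$alpha))
  print(x$cells)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pre_post_test <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.pre_post_test <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         n_significant = sum(x$cells$significant, na.rm = TRUE),
         n_subjects = x$n_subjects,
         n_perm = x$n_perm,
         alpha = x$alpha)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pre_post_test <- function(object, ...) {
  df <- object$cells %>%
    mutate(condition = sprintf("[%g°, %g°]",
                               .data$delta_sigma, .data$delta_tau))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$sigma_c),
                                   y = factor(.data$tau_c),
                                   fill = .data$p_maxt)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       size = 6) +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "white",
                                 limits = c(0, 1), name = "adj. p") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = expression(sigma[c] ~ "(deg)"),
                  y = expression(tau[c] ~ "(deg)"),
                  title = "Pre/post reweighting significance (max-T)") +
    ggplot2::theme_minimal()
}

#' Plot a weight map
#'
#' Cell-mean disparity weight against central slant, one line per central
#' tilt, faceted by discrepancy condition (and phase when present).
#'
#' @param object A [aggregate_weights()] weight map.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.weight_map <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(condition = sprintf("[%g°, %g°]",
                               .data$delta_sigma, .data$delta_tau))
  if ("subject" %in% names(df)) {
    df <- df %>%
      group_by(across(dplyr::all_of(
        intersect(c("phase", "condition", "sigma_c", "tau_c"), names(df))))) %>%
      summarise(mean_w_d = mean(.data$mean_w_d), .groups = "drop")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma_c, y = .data$mean_w_d,
                                        colour = factor(.data$tau_c))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log",
                                breaks = sort(unique(df$sigma_c))) +
    ggplot2::labs(x = expression(sigma[c] ~ "(deg, log scale)"),
                  y = expression(bar(w)[d]),
                  colour = expression(tau[c])) +
    ggplot2::theme_minimal()
  if ("phase" %in% names(df)) {
    p + ggplot2::facet_grid(phase ~ condition)
  } else {
    p + ggplot2::facet_wrap(~condition)
  }
}
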