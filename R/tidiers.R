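#' Tidy a random-intercept REML fit
#'
#' Broom-style view of a [fit_oneway_random()] / [fit_mixed_covariates()]
#' object: one row per fixed effect plus one per variance component.
#'
#' @param x A `biovar_fit`.
#' @param ... Unused.
#' @return Tibble with columns `effect` (`"fixed"` / `"ran_pars"`), `term`
#'   and `estimate`.
#' @method tidy biovar_fit
#' @export
tidy.biovar_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(effect = "fixed", term = names(x$fixed_effects),
                   estimate = unname(x$fixed_effects)),
    tibble::tibble(effect = "ran_pars",
                   term = c("sigma2_between", "sigma2_within"),
                   estimate = c(x$components$sigma2_between,
                                x$components$sigma2_within)))
}

#' Glance at a random-intercept REML fit
#'
#' @param x A `biovar_fit`.
#' @param ... Unused.
#' @return One-row tibble: variance components, ICC, scale, singular flag,
#'   REML criterion, subjects and observations used.
#' @method glance biovar_fit
#' @export
glance.biovar_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_between = x$components$sigma2_between,
    sigma2_within = x$components$sigma2_within,
    icc = x$icc,
    scale = x$scale,
    singular = x$singular,
    reml_criterion = x$reml_criterion,
    n_subjects = x$n_subjects_used,
    n_obs = x$n_obs)
}

#' Plot a reliability table as an ICC forest
#'
#' Crude (and, when present, adjusted) ICC point estimates with their
#' bootstrap intervals, one row per biomarker, shaded by the qualitative
#' reliability band.
#'
#' @param object A `biovar_reliability` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot biovar_reliability
#' @export
autoplot.biovar_reliability <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$icc), ]
  d$biomarker <- factor(d$biomarker, levels = rev(d$biomarker))
  has_adj <- "icc_adj" %in% names(d) && any(!is.na(d$icc_adj))
  long <- tibble::tibble(
    biomarker = rep(d$biomarker, if (has_adj) 2 else 1),
    model = rep(if (has_adj) c("crude", "adjusted") else "crude", each = nrow(d)),
    icc = c(d$icc, if (has_adj) d$icc_adj),
    low = c(d$icc_low, if (has_adj) d$icc_adj_low),
    high = c(d$icc_high, if (has_adj) d$icc_adj_high))
  long <- long[!is.na(long$icc), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$icc, y = .data$biomarker,
                                     colour = .data$model)) +
    ggplot2::annotate("rect", xmin = 0.75, xmax = 1, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "darkgreen") +
    ggplot2::annotate("rect", xmin = 0.40, xmax = 0.75, ymin = -Inf,
                      ymax = Inf, alpha = 0.05, fill = "orange") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$low, xmax = .data$high),
      position = ggplot2::position_dodge(width = 0.5), linewidth = 0.4) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "intraclass correlation (bootstrap 95% CI)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a baseline correlation matrix
#'
#' @param object A `biovar_cormat` from [baseline_correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot tile map of Spearman correlations.
#' @method autoplot biovar_cormat
#' @export
autoplot.biovar_cormat <- function(object, ...) {
  r <- object$r
  d <- tibble::as_tibble(as.table(r), .name_repair = "minimal")
  names(d) <- c("a", "b", "rho")
  d$a <- factor(d$a, levels = rownames(r))
  d$b <- factor(d$b, levels = rev(colnames(r)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "Spearman\nrho",
                  title = paste0("Biomarker correlations, visit ", object$visit)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
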