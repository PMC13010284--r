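# tidiers and plots for the tabular result types

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn density_regression tidy coefficient table (term, estimate,
#'   std.error, p.value)
#' @param x a `density_regression`
#' @param ... unused
#' @export
tidy.density_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "cell_density"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$se_intercept, x$se_slope),
                 p.value = c(summary(x$fit)$coefficients["(Intercept)",
                                                         "Pr(>|t|)"],
                             x$p_value))
}

#' @describeIn density_regression one-row model summary
#' @export
glance.density_regression <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r^2, p.value = x$p_value, nobs = x$n)
}

#' @describeIn gan_train per-epoch training trace in long form
#' @param x a `gan_model`
#' @param ... unused
#' @export
tidy.gan_model <- function(x, ...) {
  tr <- x$trace
  long <- lapply(setdiff(names(tr), "epoch"), function(m)
    tibble::tibble(epoch = tr$epoch, metric = m, value = tr[[m]]))
  do.call(rbind, long)
}

#' @describeIn gan_train one-row final-state summary
#' @export
glance.gan_model <- function(x, ...) {
  tr <- x$trace[nrow(x$trace), ]
  tibble::tibble(epochs = x$config$epochs, image_size = x$config$image_size,
                 final_loss_d = tr$loss_d, final_loss_g_adv = tr$loss_g_adv,
                 final_loss_l1 = tr$loss_l1,
                 final_val_residual_tn = tr$val_residual_tn)
}

#' @describeIn evaluate_subject threshold curves in long form
#' @param x an `evaluation_report`
#' @param ... unused
#' @export
tidy.evaluation_report <- function(x, ...) {
  rbind(tibble::tibble(threshold = x$dice_curve$threshold, metric = "dice",
                       value = x$dice_curve$dice),
        tibble::tibble(threshold = x$expansion_curve$threshold,
                       metric = "expansion_gliomap",
                       value = x$expansion_curve$expansion_gliomap),
        tibble::tibble(threshold = x$expansion_curve$threshold,
                       metric = "expansion_truth",
                       value = x$expansion_curve$expansion_truth))
}

#' @describeIn evaluate_subject one-row scalar summary
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(residual_mean = x$residual$mean, residual_sd = x$residual$sd,
                 signed_mean = x$residual$signed_mean,
                 psnr_db = x$quality$psnr_db, snr_db = x$quality$snr_db,
                 ssim = x$quality$ssim)
}

#' Plot the adversarial training trace
#'
#' Per-epoch discriminator loss, generator adversarial loss, L1 term and
#' (when tracked) held-out residual error in T/N units.
#'
#' @param object a `gan_model`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.gan_model <- function(object, ...) {
  d <- tidy.gan_model(object)
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training trace")
}

#' Plot Dice and volume-expansion threshold curves
#'
#' @param object an `evaluation_report`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- tidy.evaluation_report(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "T/N threshold", y = NULL, colour = NULL)
}

#' Scatter plot of VOI signal against cell density with the fitted line
#'
#' @param object a `density_regression`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.density_regression <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_density,
                                  y = .data$voi_mean_tn)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(x = "cell density (cells/mm2)", y = "VOI mean T/N")
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
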