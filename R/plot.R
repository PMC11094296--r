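# Diagnostic plot: the inner relation of one latent component.

#' Plot the inner relation of a MIR-PLS component
#'
#' Scatter of the training input scores `t` against the output scores `u`
#' for component `h`, overlaid with the fitted monotone spline. Purely a
#' diagnostic aid.
#'
#' @param model a fitted `mirpls_model` (with training scores, i.e. not one
#'   reloaded from disk).
#' @param h component index (default 1).
#' @param ... passed to [plot()].
#' @return The model, invisibly.
#' @export
plot_inner_relation <- function(model, h = 1L, ...) {
  stopifnot(inherits(model, "mirpls_model"), h >= 1L, h <= model$n_components)
  cmp <- model$components[[h]]
  if (is.null(cmp$t_train)) {
    mirpls_error("training scores unavailable (model loaded from file)",
                 "mirpls_validation_error")
  }
  graphics::plot(cmp$t_train, cmp$u_train,
                 xlab = sprintf("t (component %d input scores)", h),
                 ylab = sprintf("u (component %d output scores)", h),
                 main = sprintf("Inner relation, component %d", h), ...)
  tg <- seq(min(cmp$t_train), max(cmp$t_train), length.out = 200)
  graphics::lines(tg, eval_spline(cmp$spline, tg), col = "red", lty = 2)
  invisible(model)
}
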