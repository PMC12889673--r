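#' Input-output nonlinearities
#'
#' The supralinear rate model uses a rectified quadratic transfer function
#' `f(u) = max(u, 0)^2`, which captures the expansive gain of cortical
#' neurons; a rectified linear variant `f(u) = max(u, 0)` is provided for
#' the ablation experiments. Derivatives are `2*max(u,0)` and the 0/1 step;
#' both are defined as 0 at `u <= 0` so silent units have zero gain.
#'
#' @param u input current (any numeric array).
#' @param kind `"rectified_quadratic"` or `"rectified_linear"`.
#' @return `apply_nonlinearity` returns the rate, `nonlinearity_deriv` the
#'   pointwise derivative `f'(u)`; both keep the shape of `u`.
#' @examples
#' apply_nonlinearity(c(-1, 0, 2), "rectified_quadratic")  # 0 0 4
#' @export
apply_nonlinearity <- function(u, kind = c("rectified_quadratic",
                                           "rectified_linear")) {
  kind <- match.arg(kind)
  up <- pmax(u, 0)
  if (kind == "rectified_quadratic") up * up else up
}

#' @rdname apply_nonlinearity
#' @export
nonlinearity_deriv <- function(u, kind = c("rectified_quadratic",
                                           "rectified_linear")) {
  kind <- match.arg(kind)
  if (kind == "rectified_quadratic") 2 * pmax(u, 0) else as.numeric(u > 0)
}
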