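#' Denoiser contract
#'
#' A denoiser is any callable taking a noisy state `x_t` and an integer
#' timestep `t` and returning a noise prediction of the same shape. This
#' constructor wraps such a function together with descriptive metadata,
#' so the sampler, the training loss and the evaluation sweep can accept
#' interchangeably a fitted [ddpm()] model, an analytic oracle, or any
#' drop-in replacement.
#'
#' @param fn function of `(x_t, t)` returning an array shaped like `x_t`.
#' @param ... metadata fields (e.g. `dimensionality`, `description`)
#'   stored alongside.
#' @return An object of class `"denoiser"`.
#' @seealso [oracle_denoiser()], [zero_denoiser()]
#' @export
denoiser <- function(fn, ...) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, meta = list(...)), class = "denoiser")
}

#' @export
print.denoiser <- function(x, ...) {
  desc <- x$meta$description %||% "user-supplied"
  cat(sprintf("<denoiser: %s>\n", desc))
  invisible(x)
}

# normalize anything callable-ish to the contract
as_denoiser <- function(x) {
  if (inherits(x, "denoiser")) return(x)
  if (inherits(x, "ddpm")) return(ddpm_denoiser(x))
  if (is.function(x)) return(denoiser(x, description = "bare function"))
  stop("cannot interpret object as a denoiser", call. = FALSE)
}

denoiser_predict <- function(d, x_t, t) {
  out <- d$fn(x_t, t)
  if (!all(is.finite(out))) stop("denoiser produced non-finite values", call. = FALSE)
  out
}

#' Oracle denoiser that knows the true injected noise
#'
#' Returns a [denoiser()] that reconstructs the exact noise component
#' from the known clean image:
#' \eqn{\epsilon = (x_t - \sqrt{\bar\alpha_t}\,x_0)/\sqrt{1-\bar\alpha_t}}.
#' With this oracle a full backward pass inverts the forward process
#' exactly (up to float error), which makes it the reference against
#' which the sampler algebra is tested.
#'
#' @param x0 the clean image the chain was started from.
#' @param schedule a [build_cosine_schedule()] object.
#' @return A `"denoiser"`.
#' @export
oracle_denoiser <- function(x0, schedule) {
  force(x0); force(schedule)
  denoiser(function(x_t, t) {
    ab <- schedule$alpha_bar[t]
    (x_t - sqrt(ab) * x0) / sqrt(1 - ab)
  }, description = "oracle (true noise from known x0)")
}

#' Trivial denoiser predicting zero noise
#'
#' Baseline for loss comparisons: predicting zero makes the training
#' loss equal the mean squared norm of the drawn noise (about 1 per
#' element).
#'
#' @return A `"denoiser"`.
#' @export
zero_denoiser <- function() {
  denoiser(function(x_t, t) array(0, arr_dim(x_t)),
           description = "zero prediction baseline")
}
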