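#' Fit a normal null distribution to genome-wide signal
#'
#' Fits a normal distribution to the normalized ChIP signal of all
#' transcripts genome-wide. The fitted normal serves as the null for the
#' automatic positive/negative threshold: under it, a chosen fraction of
#' transcripts is expected to exceed the threshold by chance.
#'
#' `method = "mle"` uses the sample mean and SD (the literal reading of
#' fitting all signals, enriched loci included); `method = "robust"` uses
#' the median and 1.4826 x MAD, which resists contamination by the enriched
#' tail. Non-finite values are dropped with a message.
#'
#' @param signals Numeric vector of normalized signals (>= 2 finite values).
#' @param method `"mle"` or `"robust"`.
#' @return An object of class `null_fit`: list with `mu`, `sigma`,
#'   `method`, `n` (values used), `degenerate` (TRUE when `sigma == 0`).
#' @export
fit_null_normal <- function(signals, method = c("mle", "robust")) {
  method <- match.arg(method)
  keep <- is.finite(signals)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("fit_null_normal: dropped ", n_drop, " non-finite value(s)")
  x <- signals[keep]
  if (length(x) < 2L)
    stop("need at least 2 finite signal values to fit the null", call. = FALSE)
  if (method == "mle") {
    mu <- mean(x)
    sigma <- sd(x)
  } else {
    mu <- median(x)
    sigma <- mad(x)  # scaled by 1.4826 for normal consistency
  }
  degenerate <- sigma == 0
  if (degenerate)
    warning("degenerate null fit: sigma = 0 (constant signal)", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, method = method,
                 n = length(x), degenerate = degenerate),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("null_fit (%s): mu = %.4g, sigma = %.4g, n = %d%s\n",
              x$method, x$mu, x$sigma, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Automatic threshold at an expected-by-chance rate
#'
#' Computes the signal level that a fraction `alpha` of transcripts would
#' be expected to exceed by chance under the fitted normal null:
#' `threshold = mu + sigma * qnorm(1 - alpha)` (one-sided, upper tail).
#' The default `alpha = 0.05` expects 5% of transcripts to score positive
#' by chance.
#'
#' @param fit A `null_fit` from [fit_null_normal()].
#' @param alpha Expected-by-chance rate in (0, 1).
#' @return The threshold (a single numeric value).
#' @examples
#' fit <- structure(list(mu = 0, sigma = 1, method = "mle", n = 100,
#'                       degenerate = FALSE), class = "null_fit")
#' auto_threshold(fit, 0.05)  # 1.6449
#' @export
auto_threshold <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "null_fit"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  if (fit$degenerate)
    warning("threshold from a degenerate fit equals mu", call. = FALSE)
  fit$mu + fit$sigma * qnorm(1 - alpha)
}

#' Call transcripts positive or negative for a mark
#'
#' Scores each transcript against the automatic threshold: positive if and
#' only if its normalized signal strictly exceeds the threshold (ties at
#' the threshold are negative). The fitted null and rate used are recorded
#' with every call for provenance.
#'
#' @param quants data.frame from [quantify_tss_signal()].
#' @param fit A `null_fit` for the same signal vector.
#' @param alpha Expected-by-chance rate (default 0.05).
#' @param mark Optional mark label stored with the calls.
#' @return data.frame with columns `transcript_id`, `mark`, `signal`,
#'   `positive`, `threshold`, `alpha`.
#' @export
call_marks <- function(quants, fit, alpha = 0.05, mark = NA_character_) {
  thr <- auto_threshold(fit, alpha)
  data.frame(transcript_id = quants$transcript_id,
             mark = mark,
             signal = quants$normalized,
             positive = quants$normalized > thr,
             threshold = thr,
             alpha = alpha,
             stringsAsFactors = FALSE)
}
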