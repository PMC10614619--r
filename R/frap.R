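# FRAP trace normalization and recovery metrics.
#
# Traces are background corrected and single-normalized so that the
# prebleach plateau averages exactly 1; the post-bleach recovery is fitted
# with a single-exponential I(t) = I0 + A (1 - exp(-t/tau)), whose plateau
# relative to the bleached depth is the mobile fraction.  A fluid lipid
# gives mobile fractions near 1, a stably bound protein scaffold near 0.

#' FRAP intensity trace
#'
#' @param time_s strictly increasing acquisition times (s).
#' @param intensity raw ROI intensities.
#' @param bleach_index index of the first post-bleach sample (the bleach
#'   event lies between `bleach_index - 1` and `bleach_index`); at least 3
#'   prebleach samples are required.
#' @param background scalar background, or a vector along the trace.
#' @return a `frap_trace`.
#' @export
frap_trace <- function(time_s, intensity, bleach_index = 4L,
                       background = 0) {
  if (length(time_s) != length(intensity))
    stop("time_s and intensity must have the same length")
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 4L || bleach_index > length(time_s))
    stop("bleach_index out of range (need >= 3 prebleach samples)")
  if (!length(background) %in% c(1L, length(time_s)))
    stop("background must be a scalar or match the trace length")
  structure(list(time_s = as.numeric(time_s),
                 intensity = as.numeric(intensity),
                 bleach_index = bleach_index,
                 background = background,
                 normalized = FALSE),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d samples, bleach at index %d%s\n",
              length(x$time_s), x$bleach_index,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Background-correct and normalize a FRAP trace
#'
#' out(t) = (I(t) - bg) / (mean prebleach I - bg), so the prebleach samples
#' average to exactly 1.  Applying it to an already-normalized trace with
#' zero background is the identity.
#'
#' @param trace a [frap_trace()].
#' @return a normalized `frap_trace` (background reset to 0).
#' @export
normalize_trace <- function(trace) {
  if (!inherits(trace, "frap_trace")) stop("expected a frap_trace")
  pre <- seq_len(trace$bleach_index - 1L)
  corr <- trace$intensity - trace$background
  pre_mean <- mean(corr[pre])
  if (pre_mean <= 0)
    stop("prebleach intensity does not exceed background")
  out <- trace
  out$intensity <- corr / pre_mean
  out$background <- 0
  out$normalized <- TRUE
  out
}

#' Recovery metrics from a normalized FRAP trace
#'
#' Least-squares fit of I(t) = I0 + A (1 - exp(-(t - t_post)/tau)) to the
#' post-bleach samples (t_post = time of the first post-bleach frame).
#' The mobile fraction is A / (1 - I0): the recovered amplitude relative to
#' the bleached depth.  Estimates are invariant to uniform shifts of the
#' time axis.
#'
#' @param trace a normalized [frap_trace()] (see [normalize_trace()]).
#' @return a `frap_result`: list with `mobile_fraction` (clipped to
#'   \[0, 1\] with `clipped` flag), `tau_s`, `half_time_s` (= tau ln 2),
#'   `I0`, `amplitude`, `rss`, `n_post`.
#' @export
recovery_metrics <- function(trace) {
  if (!inherits(trace, "frap_trace")) stop("expected a frap_trace")
  if (!trace$normalized)
    stop("trace must be normalized first (see normalize_trace())")
  post <- trace$bleach_index:length(trace$time_s)
  if (length(post) < 10L) stop("need at least 10 post-bleach samples")
  t <- trace$time_s[post] - trace$time_s[trace$bleach_index]
  y <- trace$intensity[post]
  I0 <- y[1]
  depth <- 1 - I0
  if (depth < 0.05)
    stop("no bleach detected: first post-bleach sample is at ",
         sprintf("%.3f", I0), " of the prebleach level")
  # profile the nonlinear tau on a grid, then polish with optimize();
  # I0 and A are linear given tau
  sse_for <- function(tau) {
    x <- 1 - exp(-t / tau)
    fit <- stats::lm.fit(cbind(1, x), y)
    sum(fit$residuals^2)
  }
  t_max <- max(t[t > 0])
  taus <- exp(seq(log(t_max / 500), log(t_max * 4), length.out = 60))
  sse <- vapply(taus, sse_for, 0)
  i_best <- which.min(sse)
  lo <- taus[max(1L, i_best - 1L)]; hi <- taus[min(length(taus), i_best + 1L)]
  opt <- stats::optimize(sse_for, c(lo, hi))
  tau <- opt$minimum
  x <- 1 - exp(-t / tau)
  fit <- stats::lm.fit(cbind(1, x), y)
  I0_hat <- fit$coefficients[1]
  A <- fit$coefficients[2]
  if (!all(is.finite(c(I0_hat, A, tau))))
    stop("recovery fit did not converge (tau grid ",
         sprintf("%.3g..%.3g s", min(taus), max(taus)), ")")
  mf <- A / (1 - I0_hat)
  clipped <- mf < 0 || mf > 1
  structure(list(mobile_fraction = unname(min(max(mf, 0), 1)),
                 mobile_fraction_raw = unname(mf), clipped = clipped,
                 tau_s = tau, half_time_s = tau * log(2),
                 I0 = unname(I0_hat), amplitude = unname(A),
                 rss = sum(fit$residuals^2), n_post = length(post)),
            class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf(
    "<frap_result> mobile fraction %.3f%s, tau %.3g s (t1/2 %.3g s)\n",
    x$mobile_fraction, if (x$clipped) " [clipped]" else "", x$tau_s,
    x$half_time_s))
  invisible(x)
}

#' Read / write FRAP traces as CSV
#'
#' The CSV carries columns `time_s`, `intensity` and optionally
#' `background`.
#'
#' @param path CSV file path.
#' @param bleach_index first post-bleach sample index.
#' @return [read_frap_csv()]: a `frap_trace`.
#' @export
read_frap_csv <- function(path, bleach_index = 4L) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "intensity") %in% names(df)))
    stop("FRAP CSV needs columns time_s, intensity")
  frap_trace(df$time_s, df$intensity, bleach_index = bleach_index,
             background = if ("background" %in% names(df)) df$background else 0)
}

#' @rdname read_frap_csv
#' @param trace a [frap_trace()].
#' @export
write_frap_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, intensity = trace$intensity)
  if (any(trace$background != 0)) df$background <- trace$background
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
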