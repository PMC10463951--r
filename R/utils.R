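.stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

#' Derive a reproducible child seed from a master seed
#'
#' Stages and replicate runs draw their own seeds from one master seed by a
#' fixed integer derivation, so each stage is independently reproducible.
#'
#' @param seed master seed (integer).
#' @param offset stage/replicate offset (integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 10007) %%
               (2^31 - 1)) + 1L
}

#' Match detected event times against ground truth
#'
#' Greedy chronological matching: each true event is matched to the nearest
#' unmatched detection within `tol` seconds. Used to score spike detection
#' against generator ground truth.
#'
#' @param detected detected event times (seconds).
#' @param truth ground-truth event times (seconds).
#' @param tol matching tolerance in seconds.
#' @return list with `tp`, `fp`, `fn` counts plus `recall` and `precision`
#'   (NA when undefined).
#' @export
matchEventTimes <- function(detected, truth, tol = 0.002) {
  detected <- sort(detected)
  truth <- sort(truth)
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    if (!length(detected)) break
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used)
  fn <- length(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       precision = if (length(detected)) tp / length(detected) else NA_real_)
}

# trapezoidal rule on an irregular grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# the opposite-side corner in the 4-corner cage (diagonal mapping 1<->3, 2<->4)
#' Opposite-side corner of an IntelliCage corner
#'
#' Corners are numbered 1-4 around the cage; the place-preference reversal
#' task rewards the corner on the opposite side of the previously rewarded
#' one, here the diagonal partner (1<->3, 2<->4).
#'
#' @param corner corner number(s) in 1..4.
#' @return opposite corner number(s).
#' @export
oppositeCorner <- function(corner) {
  .stopIf(!all(corner %in% 1:4), "corner must be in 1..4")
  ((corner + 1L) %% 4L) + 1L
}
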