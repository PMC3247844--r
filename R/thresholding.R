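#' Intensity histogram of one channel
#'
#' @param channel Integer matrix of intensities in \[0, 255\].
#' @return A `channel_histogram`: list with `counts` (256 integers, index
#'   `i + 1` holds the count of intensity `i`) and `total`.
#' @export
channel_histogram <- function(channel) {
  if (length(channel) == 0) abort("cannot histogram an empty image.")
  v <- as.vector(channel)
  if (anyNA(v) || min(v) < 0 || max(v) > 255) {
    abort("intensities must lie in [0, 255].")
  }
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)),
            class = "channel_histogram")
}

as_channel_histogram <- function(h) {
  if (inherits(h, "channel_histogram")) return(h)
  if (is.numeric(h) && length(h) == 256) {
    if (anyNA(h) || any(h < 0)) abort("histogram counts must be non-negative.")
    return(structure(list(counts = as.numeric(h), total = sum(h)),
                     class = "channel_histogram"))
  }
  abort("`h` must be a channel_histogram or a 256-bin count vector.")
}

#' Kapur maximum-entropy threshold
#'
#' Selects the intensity level `t` in \[0, 254\] that maximises the sum of the
#' Shannon entropies of the background class (intensities `<= t`) and the
#' foreground class (intensities `> t`), the "MaxEntropy" auto-threshold of
#' ImageJ. With bin probabilities `p_i` and cumulative mass `P_t`, the score
#' is
#' \deqn{H_b(t) + H_f(t) = \left[\ln P_t - \frac{S_t}{P_t}\right] +
#'       \left[\ln(1-P_t) - \frac{S - S_t}{1-P_t}\right]}
#' where `S_t = sum_{i<=t} p_i ln p_i` (empty bins contribute 0, the
#' `x ln x -> 0` limit). Only splits with non-empty background *and*
#' foreground are candidates; ties are broken towards the smallest `t`.
#' Pixels with intensity `> t` are foreground.
#'
#' @param h A `channel_histogram` (or 256-bin count vector).
#' @return Integer threshold in \[0, 254\].
#' @seealso [max_entropy_threshold_oracle()] for the brute-force reference,
#'   [binarize()] to apply the threshold.
#' @export
max_entropy_threshold <- function(h) {
  h <- as_channel_histogram(h)
  if (sum(h$counts > 0) < 2) {
    abort("degenerate histogram: need at least 2 occupied bins to threshold.",
          class = "cyanovia_degenerate_histogram")
  }
  p <- h$counts / h$total
  P <- cumsum(p)                       # P[t+1] = mass of intensities <= t
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  Stot <- S[256]
  t_all <- 0:254
  Pt <- P[t_all + 1]
  St <- S[t_all + 1]
  valid <- Pt > 0 & Pt < 1
  score <- rep(-Inf, 255)
  score[valid] <- (log(Pt[valid]) - St[valid] / Pt[valid]) +
    (log1p(-Pt[valid]) - (Stot - St[valid]) / (1 - Pt[valid]))
  t_all[which.max(score)]              # which.max: first max = smallest t
}

#' Brute-force reference for the maximum-entropy threshold
#'
#' Literal evaluation of the Kapur criterion: for every candidate `t` both
#' class entropies are recomputed from scratch by summation. Serves as the
#' independent oracle in the test suite and must agree with
#' [max_entropy_threshold()] on every valid histogram.
#'
#' @inheritParams max_entropy_threshold
#' @return Integer threshold in \[0, 254\].
#' @export
max_entropy_threshold_oracle <- function(h) {
  h <- as_channel_histogram(h)
  if (sum(h$counts > 0) < 2) {
    abort("degenerate histogram: need at least 2 occupied bins to threshold.",
          class = "cyanovia_degenerate_histogram")
  }
  p <- h$counts / h$total
  best_t <- NA_integer_
  best_score <- -Inf
  for (t in 0:254) {
    pb <- p[1:(t + 1)]
    pf <- p[(t + 2):256]
    Pb <- sum(pb)
    Pf <- sum(pf)
    if (Pb <= 0 || Pf <= 0) next
    qb <- pb[pb > 0] / Pb
    qf <- pf[pf > 0] / Pf
    score <- -sum(qb * log(qb)) - sum(qf * log(qf))
    if (score > best_score) {          # strict: keeps smallest t on ties
      best_score <- score
      best_t <- t
    }
  }
  best_t
}

#' Apply an intensity threshold
#'
#' @param channel Integer matrix of intensities.
#' @param t Threshold level in \[0, 254\]; pixels with intensity `> t` become
#'   foreground.
#' @return Logical mask with the channel's dimensions.
#' @export
binarize <- function(channel, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0 || t > 254) {
    abort("`t` must be a single level in [0, 254].")
  }
  channel > t
}
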