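#' Read-length N50
#'
#' The largest length \code{L} in the input such that reads of length
#' \code{>= L} comprise at least half the total sequenced bases — the
#' standard long-read length summary.
#'
#' @param lengths Vector of positive read lengths.
#' @return A single length, always a member of \code{lengths}.
#' @examples
#' computeN50(c(10, 10, 10, 10, 10, 50))  # 50
#' @export
computeN50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be positive and finite")
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  s[which(cumsum(s) >= half)[1L]]
}
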