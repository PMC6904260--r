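#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic child seed for a named random channel, kept within the
## 32-bit integer range R requires of set.seed().
channel_seed <- function(master, channel) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(channel) * seq_along(utf8ToInt(channel)))
  as.integer((abs(as.integer(master)) %% 1000003L) * 1009L + h %% 100003L)
}

## Clamp a numeric vector at zero, reporting how many values were raised.
clamp_nonneg <- function(x, what = "values", quiet = FALSE) {
  n <- sum(x < 0, na.rm = TRUE)
  if (n > 0L && !quiet) {
    message(sprintf("clamped %d negative %s to 0", n, what))
  }
  pmax(x, 0)
}

stop_mc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Rescale rows of a share matrix (or one share vector) to sum to 1,
## logging when an actual renormalization was needed.
normalize_shares <- function(x, quiet = FALSE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  tot <- rowSums(x)
  if (any(tot <= 0)) stop_mc("allocation shares must have a positive sum")
  if (!quiet && any(abs(tot - 1) > 1e-9)) {
    message(sprintf("renormalized %d allocation share vector(s) to sum to 1",
                    sum(abs(tot - 1) > 1e-9)))
  }
  out <- x / tot
  if (vec) stats::setNames(as.numeric(out), colnames(out)) else out
}

warn_mc <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Moving average with one lead and one lag; endpoints fall back to the
## available two-term mean. Used to iron out reimbursement-lag artifacts in
## per-capita revenue series.

#' Smooth a per-capita revenue series with a one-lead/one-lag moving average
#'
#' Each interior value is replaced by the mean of itself, the previous year,
#' and the next year; the two endpoints use the mean of the two available
#' years. This absorbs single-year reimbursement-lag artifacts common in
#' administrative revenue data while preserving level and trend.
#'
#' @param x Numeric vector ordered by year, length at least 3, no gaps.
#' @return Numeric vector of the same length.
#' @examples
#' smooth_per_capita_revenue(c(1, 2, 3, 4))
#' @export
smooth_per_capita_revenue <- function(x) {
  if (anyNA(x)) stop_mc("series contains NA values")
  n <- length(x)
  if (n < 3L) stop_mc("series must have length >= 3 to smooth (got %d)", n)
  out <- x
  out[1L] <- mean(x[1:2])
  out[n] <- mean(x[(n - 1L):n])
  if (n > 2L) {
    i <- 2:(n - 1L)
    out[i] <- (x[i - 1L] + x[i] + x[i + 1L]) / 3
  }
  out
}
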