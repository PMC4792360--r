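#' Mean and normal-approximation confidence interval
#'
#' Summarises replicate outcomes as mean +/- z * sd / sqrt(n), the interval
#' the replication harness reports for every outcome.
#'
#' @param x numeric vector of replicate values (length >= 1).
#' @param level confidence level, default 0.95.
#' @return named numeric vector with elements `mean`, `lo`, `hi`, `sd`, `n`.
#' @examples
#' mean_ci(rbinom(500, 1, 0.5))
#' @export
mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) {
    return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_, sd = NA_real_, n = 0))
  }
  m <- mean(x)
  s <- if (n > 1L) stats::sd(x) else 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * s / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, sd = s, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_acosim <- function(...) stop(..., call. = FALSE)

# key-join lookup used by the conditional probability tables: every column of
# `tbl` except `p` is a key matched against the same-named column of `df`.
lookup_prob <- function(tbl, df, table_name = "probability table") {
  keys <- setdiff(names(tbl), "p")
  missing <- setdiff(keys, names(df))
  if (length(missing)) {
    stop_acosim(sprintf("%s keys not present in data: %s", table_name,
                        paste(missing, collapse = ", ")))
  }
  key_of <- function(d) do.call(paste, c(lapply(d[keys], as.character), sep = "\r"))
  i <- match(key_of(df), key_of(tbl))
  if (anyNA(i)) {
    stop_acosim(sprintf("%s has no entry for %d sampled combination(s)",
                        table_name, sum(is.na(i))))
  }
  tbl$p[i]
}
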