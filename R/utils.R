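logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) 1 / (1 + exp(-x))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# dB helpers: levels combine on the intensity (power) scale
db_to_power <- function(db) 10^(db / 10)
power_to_db <- function(p) 10 * log10(p)

power_sum_db <- function(...) {
  power_to_db(Reduce(`+`, lapply(list(...), db_to_power)))
}

#' Split-chain potential scale reduction factor
#'
#' Computes the split-R-hat convergence diagnostic from a draws matrix with
#' one column per chain: each chain is split in half and the classical
#' between/within variance ratio is computed on the resulting half-chains.
#'
#' @param x numeric matrix, iterations x chains.
#' @return scalar R-hat (1 at perfect convergence).
#' @keywords internal
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(halves)
  nh <- nrow(halves)
  mu_j <- colMeans(halves)
  s2_j <- apply(halves, 2, stats::var)
  W <- mean(s2_j)
  B <- nh * stats::var(mu_j)
  if (W == 0) return(1)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}
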