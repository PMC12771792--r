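# MCMC convergence diagnostics: split rank-normalised R-hat and bulk/tail
# effective sample size (Vehtari, Gelman, Simpson, Carpenter & Burkner 2021).

# rank-normalise pooled draws, preserving the chains-in-columns layout
rank_normalise <- function(m) {
  z <- qnorm((rank(m, ties.method = "average") - 3 / 8) /
               (length(m) + 1 / 4))
  matrix(z, nrow = nrow(m))
}

split_chains <- function(m) {
  n <- nrow(m)
  half <- n %/% 2L
  cbind(m[seq_len(half), , drop = FALSE],
        m[seq.int(n - half + 1L, n), , drop = FALSE])
}

# classic potential scale reduction on a draws-by-chains matrix
rhat_basic <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s2 <- apply(m, 2, var)
  w <- mean(s2)
  b <- n * var(mu)
  if (w < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# per-sequence autocovariance via FFT
autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- 2L^ceiling(log2(2L * n))
  f <- fft(c(x, rep(0, nfft - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
  ac / n  # biased (divide-by-n) estimator
}

# effective sample size of a draws-by-chains matrix (Geyer initial monotone
# positive sequence, combined across chains as in Stan)
ess_basic <- function(m) {
  n <- nrow(m)
  nc <- ncol(m)
  if (n < 4L) return(NA_real_)
  acov <- vapply(seq_len(nc), function(j) autocov(m[, j]), numeric(n))
  chain_var <- acov[1L, ] * n / (n - 1)
  w <- mean(chain_var)
  var_plus <- w * (n - 1) / n
  if (nc > 1L) var_plus <- var_plus + var(colMeans(m))
  if (var_plus < .Machine$double.eps) return(n * nc)
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  # Geyer pairs P_t = rho_{2t} + rho_{2t+1}: keep while positive, force
  # monotone non-increasing; tau = -1 + 2 * sum of the first pair onwards
  # with rho_0 = 1 included in the first pair
  pair <- numeric(0)
  t <- 0L
  prev <- Inf
  repeat {
    i1 <- 2L * t + 1L  # rho index (1-based: rho[1] = lag 0)
    i2 <- 2L * t + 2L
    if (i2 > n) break
    p <- rho[i1] + rho[i2]
    if (p < 0) break
    p <- min(p, prev)
    prev <- p
    pair <- c(pair, p)
    t <- t + 1L
  }
  tau <- max(-1 + 2 * sum(pair), 1 / log10(n * nc + 10))
  min(n * nc / tau, n * nc)
}

ess_tail_one <- function(m) {
  q <- quantile(m, c(0.05, 0.95), names = FALSE)
  lo <- matrix(as.numeric(m <= q[1L]), nrow = nrow(m))
  hi <- matrix(as.numeric(m >= q[2L]), nrow = nrow(m))
  min(ess_basic(lo), ess_basic(hi))
}

#' Convergence diagnostics for a set of chains
#'
#' Computes, per parameter, the split rank-normalised R-hat (the larger of
#' the bulk and folded versions), the bulk effective sample size (ESS of the
#' rank-normalised draws) and the tail ESS (smaller of the ESS of the 5% and
#' 95% quantile-exceedance indicators).
#'
#' @param per_chain List of per-chain draw matrices with identical column
#'   names (one column per parameter).
#' @return Data frame with columns `parameter`, `rhat`, `ess_bulk`,
#'   `ess_tail`.
#' @export
mcmc_diagnostics <- function(per_chain) {
  stopifnot(length(per_chain) >= 2L)
  params <- colnames(per_chain[[1L]])
  rows <- lapply(params, function(p) {
    m <- vapply(per_chain, function(ch) ch[, p], numeric(nrow(per_chain[[1L]])))
    s <- split_chains(m)
    z <- rank_normalise(s)
    folded <- rank_normalise(abs(s - median(s)))
    data.frame(parameter = p,
               rhat = max(rhat_basic(z), rhat_basic(folded)),
               ess_bulk = ess_basic(z),
               ess_tail = ess_tail_one(s))
  })
  do.call(rbind, rows)
}
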