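# Independent empirical-variogram oracle: axis-aligned lag differences.
# gamma(h) = 0.5 * E[(Z(s) - Z(s + h))^2], estimated from all row-wise and
# column-wise pairs at integer cell lags.
empirical_variogram <- function(field, resolution, lags_cells) {
  vapply(lags_cells, function(d) {
    nr <- nrow(field); nc <- ncol(field)
    dx <- field[, seq_len(nc - d)] - field[, seq_len(nc - d) + d]
    dy <- field[seq_len(nr - d), ] - field[seq_len(nr - d) + d, ]
    0.5 * mean(c(dx^2, dy^2))
  }, 1)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
sample_excess_kurtosis <- function(x) mean((x - mean(x))^4) / stats::sd(x)^4 - 3
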