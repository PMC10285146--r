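# Shared fixtures and independent oracles for the test suite.

# Independent brute-force quantile with midpoint (type-5) interpolation on
# the sorted draws: h = n*p + 0.5, linear interpolation between the
# floor(h)-th and ceiling(h)-th order statistics.
oracle_quantile5 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- n * p + 0.5
  lo <- pmin(pmax(floor(h), 1), n)
  hi <- pmin(pmax(ceiling(h), 1), n)
  g <- h - floor(h)
  s[lo] * (1 - g) + s[hi] * g
}

# small incomplete dataset with a hole pattern used across tests
toy_incomplete <- function() {
  incomplete_data(data.frame(
    x = c(1, 2, 3, 4, 5, 6),
    y = c(2.1, NA, 6.2, 8.0, NA, 12.1)
  ))
}

# bare replicate_matrix built from explicit pieces
make_rep <- function(obs, draws, kind = "continuous") {
  structure(list(obs = obs, draws = draws, kind = kind, target = "y"),
            class = "replicate_matrix")
}
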