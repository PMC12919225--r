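# Small named fixture networks used throughout the suite.

net2s <- function() {
  rate_network(data.frame(from = c("1", "2"), to = c("2", "1"),
                          rate = c(1, 1)))
}

net2a <- function() {
  rate_network(data.frame(from = c("1", "2"), to = c("2", "1"),
                          rate = c(2, 1)))
}

# 3-state ring, all forward (1->2->3->1) rates 2, backward rates 1
net3c <- function() {
  rate_network(data.frame(
    from = c("1", "2", "2", "3", "3", "1"),
    to   = c("2", "1", "3", "2", "1", "3"),
    rate = c(2, 1, 2, 1, 2, 1)
  ))
}

# uniform N-ring, forward rate fwd, backward rate rev
ring_network <- function(N, fwd = 1, rev = 1e-6) {
  st <- as.character(seq_len(N))
  nxt <- c(st[-1], st[1])
  rate_network(data.frame(
    from = c(st, nxt), to = c(nxt, st),
    rate = c(rep(fwd, N), rep(rev, N))
  ), states = st)
}

expect_close <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(actual - expected)), tol)
}

# rates of `net` aligned with the frame's directed-edge order
frame_rates_for_test <- function(net, frame) {
  vapply(seq_len(nrow(frame$directed)), function(d) {
    edge_rate(net, frame$directed$from[d], frame$directed$to[d])
  }, numeric(1))
}

# full response matrix by central finite differences of the mean vector
fd_response_matrix <- function(net, frame, h = 1e-6) {
  dirs <- frame$directed
  nd <- nrow(dirs)
  R <- matrix(0, nd, nd)
  for (d in seq_len(nd)) {
    mean_at <- function(fac) {
      n2 <- net
      hit <- n2$from == dirs$from[d] & n2$to == dirs$to[d]
      n2$rate[hit] <- n2$rate[hit] * fac
      steady_observables(n2, frame)$mean_x
    }
    R[, d] <- (mean_at(1 + h) - mean_at(1 - h)) / (2 * h)
  }
  R
}
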