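# Programmatic image fixtures with exactly known geometry (independent of the
# synthetic generator).

px_grid <- function(n) {
  list(cols = matrix(seq_len(n), n, n, byrow = TRUE),
       rows = matrix(seq_len(n), n, n))
}

disc_mat <- function(n, cx, cy, r, value = 1) {
  g <- px_grid(n)
  value * ((g$cols - cx)^2 + (g$rows - cy)^2 <= r^2)
}

annulus_mat <- function(n, cx, cy, r_in, r_out, value = 1) {
  g <- px_grid(n)
  d2 <- (g$cols - cx)^2 + (g$rows - cy)^2
  value * (d2 > r_in^2 & d2 <= r_out^2)
}

ellipse_mat <- function(n, cx, cy, a, b, value = 1) {
  g <- px_grid(n)
  value * (((g$cols - cx) / a)^2 + ((g$rows - cy) / b)^2 <= 1)
}

# rotate a matrix by 90 degrees counter-clockwise
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
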