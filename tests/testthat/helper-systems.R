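# shared helpers: numerical-derivative oracle, fixture loaders, index utilities

# independent 5-point central-difference gradient of a primitive's value;
# used as the oracle for the analytic B rows
numeric_b_row <- function(coord, coords, h = 1e-5) {
  x <- as.numeric(t(coords))
  vapply(seq_along(x), function(k) {
    f <- function(d) {
      x2 <- x
      x2[k] <- x2[k] + d
      evaluate_primitive(coord, matrix(x2, ncol = 3, byrow = TRUE))
    }
    (f(-2 * h) - 8 * f(-h) + 8 * f(h) - f(2 * h)) / (12 * h)
  }, numeric(1))
}

all_offdiag_pairs <- function(n) {
  p <- which(upper.tri(diag(n)), arr.ind = TRUE)
  cbind(i = p[, 1], j = p[, 2])
}

all_pairs_with_diag <- function(n) {
  rbind(cbind(1:n, 1:n), all_offdiag_pairs(n))
}

toy_kinds <- c("bent_triatomic", "linear_triatomic", "planar_ring", "chain")

# quiet wrapper: level-triple generation may message() about alpha damping
quiet_triple <- function(...) suppressMessages(make_level_triple(...))
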