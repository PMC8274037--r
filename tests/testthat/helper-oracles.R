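# Dense grid oracle for 1-feature problems. For each candidate slope w the
# intercept is profiled out exactly: the 1-D convex loss attains its minimum
# at a breakpoint of the residuals, so scanning r +/- epsilon is exact. The
# slope is gridded in two stages (coarse, then fine around the optimum).
grid_oracle_1d <- function(x, y, lambda, epsilon) {
  profile_w <- function(w) {
    r <- y - x * w
    bs <- unique(c(r - epsilon, r + epsilon))
    min(vapply(bs, function(b) sum(pmax(abs(r - b) - epsilon, 0)),
               numeric(1))) + lambda * abs(w)
  }
  sweep_w <- function(ws) {
    vals <- vapply(ws, profile_w, numeric(1))
    list(w = ws[which.min(vals)], value = min(vals))
  }
  coarse <- sweep_w(seq(-3, 3, by = 1e-3))
  fine <- sweep_w(seq(coarse$w - 2e-3, coarse$w + 2e-3, by = 1e-6))
  unname(fine$value)
}

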