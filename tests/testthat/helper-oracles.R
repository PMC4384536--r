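# Independent oracles: plain bisection on the untransformed mass-balance
# equations, never sharing code with the package's closed forms.

bisect <- function(f, lower, upper, iters = 200L) {
  fl <- f(lower)
  for (i in seq_len(iters)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (sign(fm) == sign(fl)) {
      lower <- mid
      fl <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

# 1:1 heterodimer: bound b satisfies (R - b)(L - b) = Kd * b
oracle_hetero_bound <- function(R, L, kd) {
  if (R == 0 || L == 0) return(0)
  bisect(function(b) (R - b) * (L - b) - kd * b, 0, min(R, L))
}

# self-association: unbound x satisfies x^2 = Kd * (C - x)
oracle_self_unbound <- function(C, kd) {
  if (C == 0) return(0)
  bisect(function(x) x^2 - kd * (C - x), 0, C)
}

# replicate summary for scale parameters fitted on the log scale
geomean <- function(x) exp(mean(log(x)))

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)
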