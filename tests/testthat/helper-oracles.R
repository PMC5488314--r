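# Independent oracles used across the suite.

# Exhaustive signed-rank null: enumerate all 2^n sign assignments of the
# nonzero differences and double the attained tail, capped at 1. Valid for
# tie-free differences (the batteries draw continuous values).
wilcox_enum_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p1 <- if (w > mu) mean(W >= w) else mean(W <= w)
  min(1, 2 * p1)
}

# Mean of a normal truncated below at `lower` (closed form).
truncnorm_mean <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  mu + sd * dnorm(a) / (1 - pnorm(a))
}

# Frozen high-precision evaluations of the closed-form curves (computed
# once with exact rational arithmetic, independent of the package code).
ORACLE <- list(
  logistic_115p5_m1_80 = 0.81095845190260504,   # exp(116.5/80)/(1+...)
  martel_96p25         = 0.91070413015376782,   # 1/(1+(72/96.25)^8)
  ohri_bed100_L2p5     = 0.91829134963450251,   # logistic(75/31)
  gucken_bed0          = 0.50312495931053161,   # logistic(1/80)
  eqd2_5x10            = 83.333333333333333     # 50 * 20 / 12
)
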