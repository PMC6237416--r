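# Independent scalar re-implementation of the reduced potential, term by
# term, in plain R.  Kept deliberately separate from the package kernel so
# energy/gradient tests compare two implementations.
oracleTwist <- function(d, k, mup, mum, ts = 0.2) {
  f <- c(mum + 0.5 * k * (d + 1)^2, 0.5 * k * d^2, mup + 0.5 * k * (d - 1)^2)
  fmin <- min(f)
  fmin - ts * log(sum(exp(-(f - fmin) / ts)))
}

oracleEnergy <- function(s, ps) {
  x <- s[1:14]; y1 <- s[15]; y2 <- s[16]
  E <- 0
  if (ps@terms["octamer"]) {
    E <- E + sum(ps@depth * (1 - cos(2 * pi * x)) / 2) + sum(ps@tilt * x)
    sg <- if (ps@terms["remodeler"] && ps@defectStab > 0) {
      1 / (1 + exp(-((y1 - y2) - 0.5) / 0.1))
    } else 0
    for (i in 1:13) {
      mup <- ps@muPlus[i]; mum <- ps@muMinus[i]
      if (i == 8) mup <- max(0, mup - ps@defectStab * sg)   # SHL +1
      if (i == 9) mum <- max(0, mum - ps@defectStab * sg)   # SHL +2
      E <- E + oracleTwist(x[i + 1] - x[i], ps@k[i], mup, mum, ps@smooth)
    }
  }
  if (ps@terms["remodeler"]) {
    sw <- 0.1
    d1 <- max(0, ps@grip1 * ps@gripScale[1] -
                 ps@strain / (1 + exp((y1 - 0.5) / sw)))
    d2 <- max(0, ps@grip2 * ps@gripScale[2] -
                 ps@release / (1 + exp((y2 - 0.5) / sw)))
    E <- E + d1 * (1 - cos(2 * pi * y1)) / 2 + d2 * (1 - cos(2 * pi * y2)) / 2
    u <- y1 - y2
    E <- E + 16 * ps@couplingBarrier * u^2 * (1 - u)^2 + ps@couplingOffset * u
  }
  xbar <- (x[9] + x[10]) / 2
  if (ps@terms["wall"]) {
    ex <- abs(xbar - (y1 + y2) / 2) - ps@wallHalfwidth
    if (ex > 0) E <- E + ps@wallHeight * ex^2
  }
  if (ps@terms["elec"]) {
    r1 <- xbar - y1
    E <- E - ps@epsElec * exp(-r1^2 / (2 * ps@elecWidth^2))
  }
  unname(E)
}

polyApGProfile <- function(...) {
  profileFromSequence(buildSequence("polyApG"), defaultMappingRules(...))
}

randomState <- function() {
  systemState(x = rnorm(14, 0, 0.7), y1 = rnorm(1, 0, 0.7),
              y2 = rnorm(1, 0, 0.7))
}
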