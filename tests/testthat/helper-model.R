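## Shared objects for the test suite.  Everything is built in code; no
## stored fixtures.

defP <- defaultCircuitParams()

dsaC <- topology("DSA", "non_targeting")
dsaT <- topology("DSA", "targeting")
cbsC <- topology("CBS", "non_targeting")
cbsT <- topology("CBS", "targeting")

## Independent mass-action oracle for the dCas9 partition: integrate the
## explicit binding/unbinding ODE for the two complexes (free guides
## clamped) to equilibrium.  kon/koff chosen so binding is `fold` times
## faster than the dilution timescale.
bindingEquilibrium <- function(g1, g2, dTotal, Kd, delta = 0.7,
                               fold = 100) {
  koff <- fold * delta
  kon <- koff / Kd
  rhs <- function(t, y, p) {
    dFree <- dTotal - y[1] - y[2]
    list(c(kon * dFree * g1 - koff * y[1],
           kon * dFree * g2 - koff * y[2]))
  }
  out <- deSolve::lsoda(c(c1 = 0, c2 = 0), seq(0, 50 / koff, length.out = 5),
                        rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  as.numeric(out[nrow(out), c("c1", "c2")])
}

## Deterministic per-event fluorescence for noise-free population checks.
noiseFree <- noiseModel(cvExtrinsic = 0, sigmaMeas = 0, doubletFrac = 0,
                        autofluorGfp = 0, autofluorRfp = 0)

statev <- function(x1 = 0, x2 = 0, g1 = 0, g2 = 0)
  c(x1 = x1, x2 = x2, g1 = g1, g2 = g2)
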