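#' @include AllClasses.R params.R utils.R
NULL

#' Total dCas9 as a function of aTc
#'
#' dCas9 is chromosomally integrated under the aTc-inducible pTet promoter
#' and equilibrates fast relative to the circuit dynamics, so its total
#' level is an algebraic Hill function of the aTc dose rather than a state
#' variable: \code{d_basal + d_max * atc^h / (theta_atc^h + atc^h)}.
#'
#' @param atc anhydrotetracycline dose (ng/mL), non-negative.
#' @param params a \linkS4class{CircuitParams}.
#' @return total dCas9 (au), strictly increasing in \code{atc} and bounded
#'   by \code{d_basal + d_max}.
#' @examples
#' p <- defaultCircuitParams()
#' atcToDcas9(0, p)                    # leak only
#' atcToDcas9(p[["theta_atc"]], p)     # half induction
#' @export
atcToDcas9 <- function(atc, params) {
  if (any(!is.finite(atc)) || any(atc < 0))
    stop("atc must be finite and non-negative", call. = FALSE)
  params[["d_basal"]] +
    params[["d_max"]] * .hill(atc, params[["theta_atc"]], params[["h_atc"]])
}

#' Competitive partition of the dCas9 pool between the two sgRNAs
#'
#' Quasi-steady-state allocation of a shared, limited dCas9 pool between
#' sg-pBAD (g1) and sg-pLux9 (g2): each complex is
#' \code{c_i = d_total * (g_i/Kd) / (1 + g1/Kd + g2/Kd)} and the free pool
#' is the remainder.  This competitive form is the heart of the NCR
#' controller: raising one sgRNA sequesters dCas9 into its own complex and
#' strictly lowers the complex formed by the other.
#'
#' @param g1,g2 sgRNA levels (au), non-negative; may be vectors.
#' @param dTotal total dCas9 (au), non-negative.
#' @param params a \linkS4class{CircuitParams} (uses \code{Kd}).
#' @return a list with elements \code{c1}, \code{c2}, \code{dFree};
#'   conservation \code{c1 + c2 + dFree == dTotal} holds exactly.
#' @examples
#' p <- defaultCircuitParams()
#' dcas9Partition(p[["Kd"]], p[["Kd"]], 9, p)   # symmetric thirds
#' @export
dcas9Partition <- function(g1, g2, dTotal, params) {
  if (any(!is.finite(c(g1, g2, dTotal))) || any(c(g1, g2, dTotal) < 0))
    stop("g1, g2 and dTotal must be finite and non-negative", call. = FALSE)
  Kd <- params[["Kd"]]
  den <- 1 + g1 / Kd + g2 / Kd
  c1 <- dTotal * (g1 / Kd) / den
  c2 <- dTotal * (g2 / Kd) / den
  list(c1 = c1, c2 = c2, dFree = dTotal - c1 - c2)
}

#' Effective activator level under inducer control
#'
#' A transcription factor at level \code{x} is competent to activate its
#' promoter only when bound by its inducer; the effective activator is
#' \code{x * inducer^n / (theta^n + inducer^n)}.
#'
#' @param x transcription-factor level (au).
#' @param inducer inducer concentration (units of \code{theta}).
#' @param theta half-activation concentration.
#' @param n Hill coefficient.
#' @return effective activator (au); 0 at zero inducer, \code{x} at
#'   saturating inducer.
#' @export
inducerActivity <- function(x, inducer, theta, n) {
  if (any(x < 0) || any(inducer < 0))
    stop("x and inducer must be non-negative", call. = FALSE)
  x * .hill(inducer, theta, n)
}

#' Intrinsic promoter activity under self-activation
#'
#' Leaky Hill activation \code{basal + (alpha - basal) * a^n / (K^n + a^n)},
#' bounded in \code{[basal, alpha]} and monotone in the effective activator.
#'
#' @param a effective activator (au).
#' @param basal leaky activity (au/h).
#' @param alpha maximal activity (au/h).
#' @param K half-activation threshold (au).
#' @param n Hill coefficient.
#' @return intrinsic promoter activity (au/h).
#' @export
promoterDemand <- function(a, basal, alpha, K, n) {
  basal + (alpha - basal) * .hill(a, K, n)
}

#' CRISPRi repression multiplier
#'
#' Multiplicative repression of a promoter by its sgRNA-dCas9 complex:
#' without overlap, \code{1 / (1 + (c/Kc)^m)}.  When the sgRNA target site
#' overlaps the activator operator (the pLux9 Lux box), the activator
#' competes with the complex for promoter binding and repression is
#' relieved at high activator:
#' \code{1 / (1 + (c/Kc)^m / (1 + a/Ka))}.
#'
#' @param cc sgRNA-dCas9 complex level (au).
#' @param Kc repression threshold (au).
#' @param m repression Hill coefficient.
#' @param a effective activator (au), used only when \code{luxOverlap}.
#' @param luxOverlap logical; enable activator/CRISPRi competition.
#' @param KaOverlap activator-competition scale (au).
#' @return multiplier in (0, 1]; 1 when \code{cc = 0}.
#' @export
repressionFactor <- function(cc, Kc, m, a = 0, luxOverlap = FALSE,
                             KaOverlap = Inf) {
  if (any(cc < 0) || any(a < 0))
    stop("complex and activator levels must be non-negative", call. = FALSE)
  occ <- (cc / Kc)^m
  if (luxOverlap) occ <- occ / (1 + a / KaOverlap)
  1 / (1 + occ)
}

#' Shared-resource allocation between two promoter demands
#'
#' Both modules draw on the same transcription/translation machinery; the
#' realized production saturates jointly:
#' \code{rho_i = P_i / (1 + P1/J1 + P2/J2)}.  Each module's realized rate
#' strictly decreases in the other's demand --- the unintended mutual
#' inhibition that drives winner-takes-all behaviour.
#'
#' @param P1,P2 intrinsic promoter demands (au/h).
#' @param params a \linkS4class{CircuitParams} (uses \code{J1}, \code{J2}).
#' @return list with realized production rates \code{rho1}, \code{rho2}.
#' @export
resourceAllocation <- function(P1, P2, params) {
  if (any(P1 < 0) || any(P2 < 0))
    stop("demands must be non-negative", call. = FALSE)
  den <- 1 + P1 / params[["J1"]] + P2 / params[["J2"]]
  list(rho1 = P1 / den, rho2 = P2 / den)
}

## Vectorised model core: all arguments are equal-length vectors (one entry
## per cell) except inducers/topology, which are shared.  pm is a list of
## parameter vectors (length 1 or n).  Single source of truth for both the
## scalar RHS and the population simulator.
.rhsCore <- function(x1, x2, g1, g2, pm, kind, targeting, lAra, c6, atc) {
  fAra <- .hill(lAra, pm$theta_ara[1], pm$n_ara[1])
  if (kind == "CBS") {
    a1 <- (x1 + pm$w_cross * x2) * fAra
    c6eff <- c6 + pm$k_syn * x1
    a2 <- x2 * .hill(c6eff, pm$theta_c6[1], pm$n_c6[1])
  } else {
    a1 <- x1 * fAra
    a2 <- x2 * .hill(c6, pm$theta_c6[1], pm$n_c6[1])
  }
  if (targeting) {
    dTotal <- pm$d_basal + pm$d_max * .hill(atc, pm$theta_atc[1], pm$h_atc[1])
    den <- 1 + (g1 + g2) / pm$Kd
    c1 <- dTotal * (g1 / pm$Kd) / den
    c2 <- dTotal * (g2 / pm$Kd) / den
    r1 <- 1 / (1 + (c1 / pm$Kc1)^pm$m)
    occ2 <- (c2 / pm$Kc2)^pm$m
    if (pm$lux_overlap[1]) occ2 <- occ2 / (1 + a2 / pm$Ka_overlap)
    r2 <- 1 / (1 + occ2)
  } else {
    r1 <- r2 <- 1
  }
  P1 <- (pm$basal1 + (pm$alpha1 - pm$basal1) * .hill(a1, pm$K1, pm$n1)) * r1
  P2 <- (pm$basal2 + (pm$alpha2 - pm$basal2) * .hill(a2, pm$K2, pm$n2)) * r2
  den <- 1 + P1 / pm$J1 + P2 / pm$J2
  rho1 <- P1 / den
  rho2 <- P2 / den
  list(dx1 = rho1 - pm$delta * x1,
       dx2 = rho2 - pm$delta * x2,
       ## sgRNAs are transcribed from the same promoter but bypass the
       ## translational resource bottleneck (no ribosome demand)
       dg1 = pm$kappa_g * P1 - pm$gamma_g * g1,
       dg2 = pm$kappa_g * P2 - pm$gamma_g * g2)
}

.paramsAsVectors <- function(params) {
  pm <- params@.Data
  names(pm) <- names(params)
  pm$lux_overlap <- as.logical(pm$lux_overlap)
  pm
}

#' Right-hand side of the circuit ODE model
#'
#' Assembles the full model: inducer-gated self-activation of each module,
#' CBS cross-activation (LuxI-synthesized C6 from M1, AraC from M2),
#' CRISPRi self-repression through the competitive dCas9 partition (in
#' targeting mode), shared-resource allocation of realized production, and
#' first-order dilution.  In non-targeting mode the repression pathway is
#' exactly inert: both complexes are identically zero and the derivatives
#' equal those of a model without dCas9.
#'
#' @param state named numeric of length 4: x1, x2 (module proteins, au) and
#'   g1, g2 (sgRNAs, au), all non-negative.
#' @param topo a \linkS4class{Topology}.
#' @param ind an \linkS4class{Inducers}.
#' @param params a \linkS4class{CircuitParams}.
#' @return named numeric of length 4, the time derivatives (au/h).
#' @examples
#' p <- defaultCircuitParams()
#' s <- c(x1 = 1, x2 = 1, g1 = 0, g2 = 0)
#' circuitRHS(s, topology("DSA", "targeting"), inducers(atc = 15), p)
#' @export
circuitRHS <- function(state, topo, ind, params) {
  stopifnot(is(topo, "Topology"), is(ind, "Inducers"),
            is(params, "CircuitParams"))
  if (length(state) != 4L) stop("state must have length 4", call. = FALSE)
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and non-negative", call. = FALSE)
  pm <- .paramsAsVectors(params)
  d <- .rhsCore(state[[1]], state[[2]], state[[3]], state[[4]], pm,
                topo@kind, topo@controller == "targeting",
                ind@lAra, ind@c6, ind@atc)
  c(x1 = d$dx1, x2 = d$dx2, g1 = d$dg1, g2 = d$dg2)
}
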