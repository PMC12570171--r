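## Courtemanche-Ramirez-Nattel (CRN) human atrial myocyte model: parameter
## set, state layout, and the right-hand side of the 21-variable ODE system.
## Voltages in mV, time in ms, concentrations in mM, current densities in
## pA/pF (Cm = 100 pF).

#' CRN ionic parameters with remodeling multipliers
#'
#' Maximal conductances of the CRN model plus the electrical-remodeling
#' multipliers (transient-outward, L-type Ca and inward-rectifier
#' conductances at 40%, 35% and 200% of normal) and the sodium-conductance
#' factor applied in regions of heterogeneous loss of function.
#'
#' @param f_gto,f_gCaL,f_gK1 remodeling multipliers on g_to, g_CaL, g_K1.
#' @param gna_factor multiplier on g_Na (0.30 emulates a 70% reduction).
#' @param remodeled logical; FALSE resets all three remodeling multipliers
#'   to 1 (baseline CRN).
#' @return list of class `ionic_params`.
#' @export
ionic_params <- function(f_gto = 0.40, f_gCaL = 0.35, f_gK1 = 2.00,
                         gna_factor = 1.0, remodeled = TRUE) {
  if (!remodeled) {
    f_gto <- 1; f_gCaL <- 1; f_gK1 <- 1
  }
  .assert(all(c(f_gto, f_gCaL, f_gK1, gna_factor) > 0),
          "all multipliers must be positive")
  p <- list(
    R = 8.3143, Temp = 310, Fc = 96.4867, Cm = 100,
    Vi = 13668, Vup = 1109.52, Vrel = 96.48,
    Ko = 5.4, Nao = 140, Cao = 1.8,
    gNa = 7.8, gK1 = 0.09, gto = 0.1652, gKr = 0.029411765,
    gKs = 0.12941176, gCaL = 0.12375, gbCa = 0.001131, gbNa = 0.0006744375,
    INaK_max = 0.59933874, KmNai = 10, KmKo = 1.5,
    IpCa_max = 0.275,
    INaCa_max = 1600, KmNa = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35,
    krel = 30, Iup_max = 0.005, Kup = 0.00092, Caup_max = 15, tau_tr = 180,
    Cmdn_max = 0.05, Trpn_max = 0.07, Csqn_max = 10,
    KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8,
    KQ10 = 3,
    f_gto = f_gto, f_gCaL = f_gCaL, f_gK1 = f_gK1, gna_factor = gna_factor)
  class(p) <- "ionic_params"
  p
}

#' CRN state variable names (21 variables)
#' @export
crn_state_names <- function() {
  c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f",
    "fCa", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel")
}

#' CRN resting initial conditions
#'
#' The published resting state of the baseline model.
#'
#' @return named numeric vector of the 21 state variables.
#' @export
crn_initial_state <- function() {
  s <- c(V = -81.18, m = 2.908e-3, h = 9.649e-1, j = 9.775e-1,
         oa = 3.043e-2, oi = 9.992e-1, ua = 4.966e-3, ui = 9.986e-1,
         xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 9.996e-1,
         fCa = 7.755e-1, u = 0, v = 1, w = 9.992e-1,
         Nai = 1.117e1, Ki = 1.39e2, Cai = 1.013e-4,
         Caup = 1.488, Carel = 1.488)
  s
}

## safe x/(1-exp(-x/k))-style evaluations at removable singularities
.sing <- function(num, den, limit) if (abs(den) < 1e-10) limit else num / den

#' CRN right-hand side
#'
#' Time derivatives of the 21 CRN state variables, with conductances scaled
#' by the remodeling multipliers and `gna_factor` in `params`.
#'
#' @param state named numeric vector in [crn_state_names()] order.
#' @param params an [ionic_params()].
#' @param istim stimulus current density, pA/pF (positive depolarizes).
#' @return named vector of derivatives (per ms).
#' @export
crn_rhs <- function(state, params = ionic_params(), istim = 0) {
  if (anyNA(state)) {
    bad <- crn_state_names()[which(is.na(state))]
    stop("NaN in state variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- params
  s <- as.list(stats::setNames(as.numeric(state), crn_state_names()))
  V <- s$V
  RTF <- p$R * p$Temp / p$Fc

  ENa <- RTF * log(p$Nao / s$Nai)
  EK <- RTF * log(p$Ko / s$Ki)
  ECa <- RTF / 2 * log(p$Cao / s$Cai)

  gNa <- p$gNa * p$gna_factor
  INa <- gNa * s$m^3 * s$h * s$j * (V - ENa)
  IK1 <- p$gK1 * p$f_gK1 * (V - EK) / (1 + exp(0.07 * (V + 80)))
  Ito <- p$gto * p$f_gto * s$oa^3 * s$oi * (V - EK)
  gKur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
  IKur <- gKur * s$ua^3 * s$ui * (V - EK)
  IKr <- p$gKr * s$xr * (V - EK) / (1 + exp((V + 15) / 22.4))
  IKs <- p$gKs * s$xs^2 * (V - EK)
  ICaL <- p$gCaL * p$f_gCaL * s$d * s$f * s$fCa * (V - 65)
  sig <- (exp(p$Nao / 67.3) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) +
                 0.0365 * sig * exp(-V / RTF))
  INaK <- p$INaK_max * fNaK * (1 / (1 + (p$KmNai / s$Nai)^1.5)) *
    p$Ko / (p$Ko + p$KmKo)
  INaCa <- p$INaCa_max *
    (exp(p$gam * V / RTF) * s$Nai^3 * p$Cao -
       exp((p$gam - 1) * V / RTF) * p$Nao^3 * s$Cai) /
    ((p$KmNa^3 + p$Nao^3) * (p$KmCa + p$Cao) *
       (1 + p$ksat * exp((p$gam - 1) * V / RTF)))
  IbNa <- p$gbNa * (V - ENa)
  IbCa <- p$gbCa * (V - ECa)
  IpCa <- p$IpCa_max * s$Cai / (0.0005 + s$Cai)

  ## SR fluxes (mM/ms)
  Irel <- p$krel * s$u^2 * s$v * s$w * (s$Carel - s$Cai)
  Iup <- p$Iup_max / (1 + p$Kup / s$Cai)
  Iup_leak <- p$Iup_max * s$Caup / p$Caup_max
  Itr <- (s$Caup - s$Carel) / p$tau_tr

  ## gate kinetics
  am <- .sing(0.32 * (V + 47.13), 1 - exp(-0.1 * (V + 47.13)), 3.2)
  bm <- 0.08 * exp(-V / 11)
  if (V >= -40) {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.135 * exp(-(V + 80) / 6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  a_oa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
  b_oa <- 0.65 / (2.5 + exp((V + 82) / 17))
  tau_oa <- 1 / ((a_oa + b_oa) * p$KQ10)
  oa_inf <- 1 / (1 + exp(-(V + 20.47) / 17.54))
  a_oi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
  b_oi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
  tau_oi <- 1 / ((a_oi + b_oi) * p$KQ10)
  oi_inf <- 1 / (1 + exp((V + 43.1) / 5.3))
  a_ua <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
  b_ua <- 0.65 / (2.5 + exp((V + 82) / 17))
  tau_ua <- 1 / ((a_ua + b_ua) * p$KQ10)
  ua_inf <- 1 / (1 + exp(-(V + 30.3) / 9.6))
  a_ui <- 1 / (21 + exp(-(V - 185) / 28))
  b_ui <- exp((V - 158) / 16)
  tau_ui <- 1 / ((a_ui + b_ui) * p$KQ10)
  ui_inf <- 1 / (1 + exp((V - 99.45) / 27.48))
  a_xr <- .sing(0.0003 * (V + 14.1), 1 - exp(-(V + 14.1) / 5), 0.0015)
  b_xr <- .sing(7.3898e-5 * (V - 3.3328),
                exp((V - 3.3328) / 5.1237) - 1, 3.7862e-4)
  tau_xr <- 1 / (a_xr + b_xr)
  xr_inf <- 1 / (1 + exp(-(V + 14.1) / 6.5))
  a_xs <- .sing(4e-5 * (V - 19.9), 1 - exp(-(V - 19.9) / 17), 6.8e-4)
  b_xs <- .sing(3.5e-5 * (V - 19.9), exp((V - 19.9) / 9) - 1, 3.15e-4)
  tau_xs <- 0.5 / (a_xs + b_xs)
  xs_inf <- 1 / sqrt(1 + exp(-(V - 19.9) / 12.7))
  tau_d <- .sing((1 - exp(-(V + 10) / 6.24)),
                 0.035 * (V + 10) * (1 + exp(-(V + 10) / 6.24)),
                 1 / (0.035 * 6.24 * 2))
  d_inf <- 1 / (1 + exp(-(V + 10) / 8))
  tau_f <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
  f_inf <- 1 / (1 + exp((V + 28) / 6.9))
  fCa_inf <- 1 / (1 + s$Cai / 0.00035)
  tau_fCa <- 2
  tau_w <- .sing(6 * (1 - exp(-(V - 7.9) / 5)),
                 (1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9),
                 (6 / 5) / 1.3)
  w_inf <- 1 - 1 / (1 + exp(-(V - 40) / 17))

  ## Ca-release activation driver (currents in pA)
  Fn <- 1e-12 * p$Vrel * Irel -
    (5e-13 / p$Fc) * (0.5 * ICaL * p$Cm - 0.2 * INaCa * p$Cm)
  u_inf <- 1 / (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))
  tau_u <- 8
  tau_v <- 1.91 + 2.09 / (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))
  v_inf <- 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / 13.67e-16))

  FVi <- p$Fc * p$Vi
  Cm <- p$Cm
  dNai <- (-3 * INaK - 3 * INaCa - IbNa - INa) * Cm / FVi
  dKi <- (2 * INaK - IK1 - Ito - IKur - IKr - IKs) * Cm / FVi
  B1 <- (2 * INaCa - IpCa - ICaL - IbCa) * Cm / (2 * FVi) +
    (p$Vup * (Iup_leak - Iup) + Irel * p$Vrel) / p$Vi
  B2 <- 1 + p$Trpn_max * p$KmTrpn / (s$Cai + p$KmTrpn)^2 +
    p$Cmdn_max * p$KmCmdn / (s$Cai + p$KmCmdn)^2
  dCai <- B1 / B2
  dCaup <- Iup - Iup_leak - Itr * p$Vrel / p$Vup
  dCarel <- (Itr - Irel) / (1 + p$Csqn_max * p$KmCsqn /
                              (s$Carel + p$KmCsqn)^2)

  iion <- INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
    INaCa + IbNa + IbCa
  dV <- -iion + istim

  c(V = dV,
    m = am * (1 - s$m) - bm * s$m,
    h = ah * (1 - s$h) - bh * s$h,
    j = aj * (1 - s$j) - bj * s$j,
    oa = (oa_inf - s$oa) / tau_oa,
    oi = (oi_inf - s$oi) / tau_oi,
    ua = (ua_inf - s$ua) / tau_ua,
    ui = (ui_inf - s$ui) / tau_ui,
    xr = (xr_inf - s$xr) / tau_xr,
    xs = (xs_inf - s$xs) / tau_xs,
    d = (d_inf - s$d) / tau_d,
    f = (f_inf - s$f) / tau_f,
    fCa = (fCa_inf - s$fCa) / tau_fCa,
    u = (u_inf - s$u) / tau_u,
    v = (v_inf - s$v) / tau_v,
    w = (w_inf - s$w) / tau_w,
    Nai = dNai, Ki = dKi, Cai = dCai, Caup = dCaup, Carel = dCarel)
}
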