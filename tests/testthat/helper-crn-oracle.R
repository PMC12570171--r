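# Independent transcription of the Courtemanche-Ramirez-Nattel human atrial
# myocyte equations, used only as a cross-check oracle for the package's
# implementation.  Written separately from the package code, organized by
# current rather than by gate, and integrated with deSolve.

oracle_crn_derivs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    RTF <- 8.3143 * 310 / 96.4867
    E_Na <- RTF * log(140 / Nai)
    E_K <- RTF * log(5.4 / Ki)
    E_Ca <- RTF / 2 * log(1.8 / Cai)

    # fast sodium
    i_Na <- 7.8 * gna_mult * m^3 * h * jj * (V - E_Na)
    a_m <- if (abs(V + 47.13) < 1e-8) 3.2 else
      0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
    b_m <- 0.08 * exp(-V / 11)
    if (V < -40) {
      a_h <- 0.135 * exp((V + 80) / -6.8)
      b_h <- 3.56 * exp(0.079 * V) + 310000 * exp(0.35 * V)
      a_j <- (-127140 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
        (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
      b_j <- 0.1212 * exp(-0.01052 * V) /
        (1 + exp(-0.1378 * (V + 40.14)))
    } else {
      a_h <- 0
      b_h <- 1 / (0.13 * (1 + exp((V + 10.66) / -11.1)))
      a_j <- 0
      b_j <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
    }

    # inward rectifier / transient outward / ultrarapid
    i_K1 <- f_K1 * 0.09 * (V - E_K) / (1 + exp(0.07 * (V + 80)))
    i_to <- f_to * 0.1652 * oa^3 * oi * (V - E_K)
    g_Kur <- 0.005 + 0.05 / (1 + exp((V - 15) / -13))
    i_Kur <- g_Kur * ua^3 * ui * (V - E_K)
    a_oa <- 0.65 / (exp((V + 10) / -8.5) + exp((V - 30) / -59))
    b_oa <- 0.65 / (2.5 + exp((V + 82) / 17))
    oa_bar <- (1 + exp((V + 20.47) / -17.54))^-1
    a_oi <- (18.53 + exp((V + 113.7) / 10.95))^-1
    b_oi <- (35.56 + exp((V + 1.26) / -7.44))^-1
    oi_bar <- (1 + exp((V + 43.1) / 5.3))^-1
    a_ua <- 0.65 / (exp((V + 10) / -8.5) + exp((V - 30) / -59))
    b_ua <- 0.65 / (2.5 + exp((V + 82) / 17))
    ua_bar <- (1 + exp((V + 30.3) / -9.6))^-1
    a_ui <- (21 + exp((V - 185) / -28))^-1
    b_ui <- exp((V - 158) / 16)
    ui_bar <- (1 + exp((V - 99.45) / 27.48))^-1

    # delayed rectifiers
    i_Kr <- 0.029411765 * xr * (V - E_K) / (1 + exp((V + 15) / 22.4))
    a_xr <- if (abs(V + 14.1) < 1e-8) 0.0015 else
      0.0003 * (V + 14.1) / (1 - exp((V + 14.1) / -5))
    b_xr <- if (abs(V - 3.3328) < 1e-8) 3.7836118e-4 else
      7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1)
    xr_bar <- (1 + exp((V + 14.1) / -6.5))^-1
    i_Ks <- 0.12941176 * xs^2 * (V - E_K)
    a_xs <- if (abs(V - 19.9) < 1e-8) 0.00068 else
      4e-5 * (V - 19.9) / (1 - exp((V - 19.9) / -17))
    b_xs <- if (abs(V - 19.9) < 1e-8) 0.000315 else
      3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1)
    xs_bar <- (1 + exp((V - 19.9) / -12.7))^-0.5

    # L-type calcium
    i_CaL <- f_CaL * 0.12375 * d * f * fCa * (V - 65)
    d_bar <- (1 + exp((V + 10) / -8))^-1
    tau_d <- if (abs(V + 10) < 1e-8) 4.579 / (1 + exp((V + 10) / -6.24)) else
      (1 - exp((V + 10) / -6.24)) /
        (0.035 * (V + 10) * (1 + exp((V + 10) / -6.24)))
    f_bar <- exp(-(V + 28) / 6.9) / (1 + exp(-(V + 28) / 6.9))
    tau_f <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
    fCa_bar <- (1 + Cai / 0.00035)^-1

    # pumps and exchangers
    sigma <- (exp(140 / 67.3) - 1) / 7
    f_NaK <- (1 + 0.1245 * exp(-0.1 * 96.4867 * V / (8.3143 * 310)) +
                0.0365 * sigma * exp(-96.4867 * V / (8.3143 * 310)))^-1
    i_NaK <- 0.59933874 * f_NaK / (1 + (10 / Nai)^1.5) * 5.4 / (5.4 + 1.5)
    i_NaCa <- 1600 * (exp(0.35 * V / RTF) * Nai^3 * 1.8 -
                        exp(-0.65 * V / RTF) * 140^3 * Cai) /
      ((87.5^3 + 140^3) * (1.38 + 1.8) * (1 + 0.1 * exp(-0.65 * V / RTF)))
    i_B_Na <- 0.0006744375 * (V - E_Na)
    i_B_Ca <- 0.001131 * (V - E_Ca)
    i_PCa <- 0.275 * Cai / (0.0005 + Cai)

    # SR calcium handling
    i_rel <- 30 * u^2 * v * w * (Carel - Cai)
    i_up <- 0.005 / (1 + 0.00092 / Cai)
    i_up_leak <- 0.005 * Caup / 15
    i_tr <- (Caup - Carel) / 180
    w_bar <- 1 - (1 + exp(-(V - 40) / 17))^-1
    tau_w <- if (abs(V - 7.9) < 1e-8) 6 * 0.2 / 1.3 else
      6 * (1 - exp(-(V - 7.9) / 5)) /
        ((1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9))
    Fn <- 96.48e-12 * i_rel - 5e-13 / 96.4867 *
      (0.5 * i_CaL * 100 - 0.2 * i_NaCa * 100)
    u_bar <- (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))^-1
    v_bar <- 1 - (1 + exp(-(Fn - 6.835e-14) / 13.67e-16))^-1
    tau_v <- 1.91 + 2.09 * (1 + exp(-(Fn - 3.4175e-13) / 13.67e-16))^-1

    istim <- if (!is.null(parms[["stim_fun"]])) stim_fun(t) else 0

    cmf <- 100 / (96.4867 * 13668)
    d_Nai <- cmf * (-3 * i_NaK - 3 * i_NaCa - i_B_Na - i_Na)
    d_Ki <- cmf * (2 * i_NaK - i_K1 - i_to - i_Kur - i_Kr - i_Ks)
    buf <- 1 + 0.07 * 0.0005 / (Cai + 0.0005)^2 +
      0.05 * 0.00238 / (Cai + 0.00238)^2
    d_Cai <- (cmf / 2 * (2 * i_NaCa - i_PCa - i_CaL - i_B_Ca) +
                (1109.52 * (i_up_leak - i_up) + i_rel * 96.48) / 13668) / buf
    d_Caup <- i_up - i_up_leak - i_tr * 96.48 / 1109.52
    d_Carel <- (i_tr - i_rel) * (1 + 10 * 0.8 / (Carel + 0.8)^2)^-1

    d_V <- -(i_Na + i_K1 + i_to + i_Kur + i_Kr + i_Ks + i_CaL + i_PCa +
               i_NaK + i_NaCa + i_B_Na + i_B_Ca) + istim

    list(c(V = d_V,
           m = a_m * (1 - m) - b_m * m,
           h = a_h * (1 - h) - b_h * h,
           jj = a_j * (1 - jj) - b_j * jj,
           oa = 3 * (a_oa + b_oa) * (oa_bar - oa),
           oi = 3 * (a_oi + b_oi) * (oi_bar - oi),
           ua = 3 * (a_ua + b_ua) * (ua_bar - ua),
           ui = 3 * (a_ui + b_ui) * (ui_bar - ui),
           xr = (a_xr + b_xr) * (xr_bar - xr),
           xs = 2 * (a_xs + b_xs) * (xs_bar - xs),
           d = (d_bar - d) / tau_d,
           f = (f_bar - f) / tau_f,
           fCa = (fCa_bar - fCa) / 2,
           u = (u_bar - u) / 8,
           v = (v_bar - v) / tau_v,
           w = (w_bar - w) / tau_w,
           Nai = d_Nai, Ki = d_Ki, Cai = d_Cai,
           Caup = d_Caup, Carel = d_Carel))
  })
}

oracle_crn_state <- function() {
  s <- crn_initial_state()
  names(s)[names(s) == "j"] <- "jj"
  s
}

# APD90 via deSolve integration of the oracle equations
oracle_apd90 <- function(remodeled, stim_times = c(50, 1050),
                         duration = 2000) {
  stim_fun <- function(t) {
    on <- any(t >= stim_times & t < stim_times + 2)
    if (on) 20 else 0
  }
  parms <- list(gna_mult = 1,
                f_to = if (remodeled) 0.40 else 1,
                f_CaL = if (remodeled) 0.35 else 1,
                f_K1 = if (remodeled) 2.00 else 1,
                stim_fun = stim_fun)
  out <- deSolve::lsoda(oracle_crn_state(), seq(0, duration, by = 1),
                        oracle_crn_derivs, parms, rtol = 1e-6, atol = 1e-8,
                        hmax = 1)
  apd90(out[, "time"], out[, "V"])
}
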