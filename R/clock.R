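#' The 16-variable mammalian circadian clock model
#'
#' Builds the process-decomposed kinetic model of the mammalian circadian
#' oscillator: mRNAs of *Per*, *Cry* and *Bmal1*, the corresponding proteins
#' in cytosolic, nuclear, free, complexed and phosphorylated forms, and the
#' inactive PER-CRY:CLOCK-BMAL1 complex.  The network couples one positive
#' and two negative feedback loops; CLOCK-BMAL1 activates *Per*/*Cry*
#' transcription (Hill cooperativity `n`) and represses its own gene *Bmal1*
#' (cooperativity `m`).  Light input raises the *Per* transcription rate
#' `v_sP` from 1.5 to 1.8 nM/h during the first 12 h of every 24 h cycle
#' (lights-on at t = 0).
#'
#' The model has 76 process terms distributed over the 16 equations as
#' (3,3,3,6,6,4,4,7,7,4,4,6,4,7,4,4).  Aggregate quantities (`k_stot`,
#' `v_stot`, `V_phos`) and the Hill coefficients are kept in `meta`; the
#' kinetic parameters derived from them (`k_sB = 0.12 k_stot`, ...) are
#' materialised at their numeric values so that each can be varied
#' independently in sensitivity analyses.  `n` and `m` are carried in the
#' parameter vector but marked fixed via `meta$fixed_parameters`.
#'
#' @return A [process_model()] named `"clock"` with six standard outputs
#'   (`M_P`, `M_C`, `M_B`, `P_Tot`, `C_Tot`, `B_Tot`).
#' @examples
#' m <- clock_model()
#' n_processes(m)       # per-equation term counts
#' length(process_labels(m))  # 76
#' @export
clock_model <- function() {
  params <- c(
    k1 = 0.4, k2 = 0.2, k3 = 0.4, k4 = 0.2, k5 = 0.4, k6 = 0.2,
    k7 = 0.5, k8 = 0.1,
    K_AP = 0.7, K_AC = 0.6, K_IB = 2.2,
    k_dmb = 0.01, k_dmc = 0.01, k_dmp = 0.01, k_dnc = 0.12, k_dn = 0.01,
    K_d = 0.3, K_dp = 0.1, K_p = 0.1,
    K_mB = 0.4, K_mC = 0.4, K_mP = 0.31,
    k_sB = 0.12, k_sC = 1.6, k_sP = 0.6,
    n = 4, m = 2,
    V_1B = 0.5, V_1C = 0.6, V_1P = 0.4, V_1PC = 0.4,
    V_2B = 0.1, V_2C = 0.1, V_2P = 0.3, V_2PC = 0.1,
    V_3B = 0.5, V_3PC = 0.4, V_4B = 0.2, V_4PC = 0.1,
    v_dBC = 0.5, v_dBN = 0.6, v_dCC = 0.7, v_dIN = 0.8,
    v_dPC = 0.7, v_dPCC = 0.7, v_dPCN = 0.7,
    v_mB = 0.8, v_mC = 1.0, v_mP = 1.1,
    v_sB = 1.0, v_sC = 1.1, v_sP = 1.5)

  x0 <- c(M_P = 2.188, M_C = 1.633, M_B = 9.498, P_C = 2.008, C_C = 1.884,
          P_CP = 0.129, C_CP = 0.473, PC_C = 1.228, PC_N = 0.177,
          PC_CP = 0.203, PC_NP = 0.101, B_C = 2.523, B_CP = 0.929,
          B_N = 1.787, B_NP = 0.318, I_N = 0.051)

  tm <- function(e, s, l) process_term(e, s, l)
  terms <- list(
    M_P = list(
      tm(quote(v_sP * B_N^n / (K_AP^n + B_N^n)), +1, "Per transcription (light-driven)"),
      tm(quote(-v_mP * M_P / (K_mP + M_P)), -1, "Per mRNA enzymatic degradation"),
      tm(quote(-k_dmp * M_P), -1, "Per mRNA basal degradation")),
    M_C = list(
      tm(quote(v_sC * B_N^n / (K_AC^n + B_N^n)), +1, "Cry transcription"),
      tm(quote(-v_mC * M_C / (K_mC + M_C)), -1, "Cry mRNA enzymatic degradation"),
      tm(quote(-k_dmc * M_C), -1, "Cry mRNA basal degradation")),
    M_B = list(
      tm(quote(v_sB * K_IB^m / (K_IB^m + B_N^m)), +1, "Bmal1 transcription (auto-repressed)"),
      tm(quote(-v_mB * M_B / (K_mB + M_B)), -1, "Bmal1 mRNA enzymatic degradation"),
      tm(quote(-k_dmb * M_B), -1, "Bmal1 mRNA basal degradation")),
    P_C = list(
      tm(quote(k_sP * M_P), +1, "PER translation"),
      tm(quote(-V_1P * P_C / (K_p + P_C)), -1, "PER phosphorylation (cytosol)"),
      tm(quote(V_2P * P_CP / (K_dp + P_CP)), +1, "PER dephosphorylation (cytosol)"),
      tm(quote(k4 * PC_C), +1, "PER-CRY dissociation (cytosol)"),
      tm(quote(-k3 * P_C * C_C), -1, "PER-CRY association (cytosol)"),
      tm(quote(-k_dn * P_C), -1, "PER basal degradation")),
    C_C = list(
      tm(quote(k_sC * M_C), +1, "CRY translation"),
      tm(quote(-V_1C * C_C / (K_p + C_C)), -1, "CRY phosphorylation (cytosol)"),
      tm(quote(V_2C * C_CP / (K_dp + C_CP)), +1, "CRY dephosphorylation (cytosol)"),
      tm(quote(k4 * PC_C), +1, "PER-CRY dissociation (cytosol)"),
      tm(quote(-k3 * P_C * C_C), -1, "PER-CRY association (cytosol)"),
      tm(quote(-k_dnc * C_C), -1, "CRY basal degradation")),
    P_CP = list(
      tm(quote(V_1P * P_C / (K_p + P_C)), +1, "PER phosphorylation (cytosol)"),
      tm(quote(-V_2P * P_CP / (K_dp + P_CP)), -1, "PER dephosphorylation (cytosol)"),
      tm(quote(-v_dPC * P_CP / (K_d + P_CP)), -1, "phospho-PER degradation"),
      tm(quote(-k_dn * P_CP), -1, "phospho-PER basal degradation")),
    C_CP = list(
      tm(quote(V_1C * C_C / (K_p + C_C)), +1, "CRY phosphorylation (cytosol)"),
      tm(quote(-V_2C * C_CP / (K_dp + C_CP)), -1, "CRY dephosphorylation (cytosol)"),
      tm(quote(-v_dCC * C_CP / (K_d + C_CP)), -1, "phospho-CRY degradation"),
      tm(quote(-k_dn * C_CP), -1, "phospho-CRY basal degradation")),
    PC_C = list(
      tm(quote(-V_1PC * PC_C / (K_p + PC_C)), -1, "PER-CRY phosphorylation (cytosol)"),
      tm(quote(V_2PC * PC_CP / (K_dp + PC_CP)), +1, "PER-CRY dephosphorylation (cytosol)"),
      tm(quote(-k4 * PC_C), -1, "PER-CRY dissociation (cytosol)"),
      tm(quote(k3 * P_C * C_C), +1, "PER-CRY association (cytosol)"),
      tm(quote(k2 * PC_N), +1, "PER-CRY nuclear export"),
      tm(quote(-k1 * PC_C), -1, "PER-CRY nuclear import"),
      tm(quote(-k_dn * PC_C), -1, "PER-CRY basal degradation")),
    PC_N = list(
      tm(quote(-V_3PC * PC_N / (K_p + PC_N)), -1, "PER-CRY phosphorylation (nucleus)"),
      tm(quote(V_4PC * PC_NP / (K_dp + PC_NP)), +1, "PER-CRY dephosphorylation (nucleus)"),
      tm(quote(-k2 * PC_N), -1, "PER-CRY nuclear export"),
      tm(quote(k1 * PC_C), +1, "PER-CRY nuclear import"),
      tm(quote(-k7 * B_N * PC_N), -1, "PER-CRY:CLOCK-BMAL1 formation"),
      tm(quote(k8 * I_N), +1, "PER-CRY:CLOCK-BMAL1 dissociation"),
      tm(quote(-k_dn * PC_N), -1, "nuclear PER-CRY basal degradation")),
    PC_CP = list(
      tm(quote(V_1PC * PC_C / (K_p + PC_C)), +1, "PER-CRY phosphorylation (cytosol)"),
      tm(quote(-V_2PC * PC_CP / (K_dp + PC_CP)), -1, "PER-CRY dephosphorylation (cytosol)"),
      tm(quote(-v_dPCC * PC_CP / (K_d + PC_CP)), -1, "phospho-PER-CRY degradation (cytosol)"),
      tm(quote(-k_dn * PC_CP), -1, "phospho-PER-CRY basal degradation")),
    PC_NP = list(
      tm(quote(V_3PC * PC_N / (K_p + PC_N)), +1, "PER-CRY phosphorylation (nucleus)"),
      tm(quote(-V_4PC * PC_NP / (K_dp + PC_NP)), -1, "PER-CRY dephosphorylation (nucleus)"),
      tm(quote(-v_dPCN * PC_NP / (K_d + PC_NP)), -1, "phospho-PER-CRY degradation (nucleus)"),
      tm(quote(-k_dn * PC_NP), -1, "phospho-PER-CRY basal degradation")),
    B_C = list(
      tm(quote(k_sB * M_B), +1, "BMAL1 translation"),
      tm(quote(-V_1B * B_C / (K_p + B_C)), -1, "BMAL1 phosphorylation (cytosol)"),
      tm(quote(V_2B * B_CP / (K_dp + B_CP)), +1, "BMAL1 dephosphorylation (cytosol)"),
      tm(quote(-k5 * B_C), -1, "BMAL1 nuclear import"),
      tm(quote(k6 * B_N), +1, "BMAL1 nuclear export"),
      tm(quote(-k_dn * B_C), -1, "BMAL1 basal degradation")),
    B_CP = list(
      tm(quote(V_1B * B_C / (K_p + B_C)), +1, "BMAL1 phosphorylation (cytosol)"),
      tm(quote(-V_2B * B_CP / (K_dp + B_CP)), -1, "BMAL1 dephosphorylation (cytosol)"),
      tm(quote(-v_dBC * B_CP / (K_d + B_CP)), -1, "phospho-BMAL1 degradation (cytosol)"),
      tm(quote(-k_dn * B_CP), -1, "phospho-BMAL1 basal degradation")),
    B_N = list(
      tm(quote(-V_3B * B_N / (K_p + B_N)), -1, "BMAL1 phosphorylation (nucleus)"),
      tm(quote(V_4B * B_NP / (K_dp + B_NP)), +1, "BMAL1 dephosphorylation (nucleus)"),
      tm(quote(k5 * B_C), +1, "BMAL1 nuclear import"),
      tm(quote(-k6 * B_N), -1, "BMAL1 nuclear export"),
      tm(quote(-k7 * B_N * PC_N), -1, "PER-CRY:CLOCK-BMAL1 formation"),
      tm(quote(k8 * I_N), +1, "PER-CRY:CLOCK-BMAL1 dissociation"),
      tm(quote(-k_dn * B_N), -1, "nuclear BMAL1 basal degradation")),
    B_NP = list(
      tm(quote(V_3B * B_N / (K_p + B_N)), +1, "BMAL1 phosphorylation (nucleus)"),
      tm(quote(-V_4B * B_NP / (K_dp + B_NP)), -1, "BMAL1 dephosphorylation (nucleus)"),
      tm(quote(-v_dBN * B_NP / (K_d + B_NP)), -1, "phospho-BMAL1 degradation (nucleus)"),
      tm(quote(-k_dn * B_NP), -1, "phospho-BMAL1 basal degradation")),
    I_N = list(
      tm(quote(-k8 * I_N), -1, "PER-CRY:CLOCK-BMAL1 dissociation"),
      tm(quote(k7 * B_N * PC_N), +1, "PER-CRY:CLOCK-BMAL1 formation"),
      tm(quote(-v_dIN * I_N / (K_d + I_N)), -1, "complex degradation"),
      tm(quote(-k_dn * I_N), -1, "complex basal degradation")))

  links <- list(
    c("f_4,5", "f_5,5", "f_8,4"),     # PER-CRY association k3 P_C C_C
    c("f_4,4", "f_5,4", "f_8,3"),     # PER-CRY dissociation k4 PC_C
    c("f_4,2", "f_6,1"),              # PER phosphorylation V_1P
    c("f_4,3", "f_6,2"),              # PER dephosphorylation V_2P
    c("f_5,2", "f_7,1"),              # CRY phosphorylation V_1C
    c("f_5,3", "f_7,2"),              # CRY dephosphorylation V_2C
    c("f_8,1", "f_10,1"),             # PER-CRY phosphorylation (cyt) V_1PC
    c("f_8,2", "f_10,2"),             # PER-CRY dephosphorylation (cyt) V_2PC
    c("f_9,1", "f_11,1"),             # PER-CRY phosphorylation (nuc) V_3PC
    c("f_9,2", "f_11,2"),             # PER-CRY dephosphorylation (nuc) V_4PC
    c("f_8,6", "f_9,4"),              # PER-CRY nuclear import k1
    c("f_8,5", "f_9,3"),              # PER-CRY nuclear export k2
    c("f_9,5", "f_14,5", "f_16,2"),   # large complex formation k7 B_N PC_N
    c("f_9,6", "f_14,6", "f_16,1"),   # large complex dissociation k8 I_N
    c("f_12,2", "f_13,1"),            # BMAL1 phosphorylation (cyt) V_1B
    c("f_12,3", "f_13,2"),            # BMAL1 dephosphorylation (cyt) V_2B
    c("f_12,4", "f_14,3"),            # BMAL1 nuclear import k5
    c("f_12,5", "f_14,4"),            # BMAL1 nuclear export k6
    c("f_14,1", "f_15,1"),            # BMAL1 phosphorylation (nuc) V_3B
    c("f_14,2", "f_15,2"))            # BMAL1 dephosphorylation (nuc) V_4B

  pc_forms <- c(PC_C = 1, PC_N = 1, PC_CP = 1, PC_NP = 1, I_N = 1)
  outputs <- list(
    M_P = c(M_P = 1), M_C = c(M_C = 1), M_B = c(M_B = 1),
    P_Tot = c(P_C = 1, P_CP = 1, pc_forms),
    C_Tot = c(C_C = 1, C_CP = 1, pc_forms),
    B_Tot = c(B_C = 1, B_CP = 1, B_N = 1, B_NP = 1, I_N = 1))

  process_model(
    variables = names(terms), terms = unname(terms),
    parameters = params, initial_state = x0,
    horizon = c(0, 24),
    forcing = list(param = "v_sP", multiplier = 1.2, period = 24, on = 12),
    links = links, outputs = outputs,
    descriptions = c(
      "Per mRNA", "Cry mRNA", "Bmal1 mRNA",
      "PER protein (cytosol)", "CRY protein (cytosol)",
      "phospho-PER (cytosol)", "phospho-CRY (cytosol)",
      "PER-CRY complex (cytosol)", "PER-CRY complex (nucleus)",
      "phospho-PER-CRY (cytosol)", "phospho-PER-CRY (nucleus)",
      "BMAL1 protein (cytosol)", "phospho-BMAL1 (cytosol)",
      "BMAL1 protein (nucleus)", "phospho-BMAL1 (nucleus)",
      "PER-CRY:CLOCK-BMAL1 complex (nucleus)"),
    meta = list(
      units = list(concentration = "nM", time = "h"),
      aggregates = c(k_stot = 1.0, v_stot = 1.0, V_phos = 0.4),
      fixed_parameters = c("n", "m"),
      light = c(v_sP_light = 1.8, v_sP_dark = 1.5)),
    name = "clock")
}

## fixed order of the 52 kinetic parameters in the compiled parameter vector;
## must match the #defines in src/clock.c
clock_param_order <- c(
  "k1","k2","k3","k4","k5","k6","k7","k8",
  "K_AP","K_AC","K_IB",
  "k_dmb","k_dmc","k_dmp","k_dnc","k_dn",
  "K_d","K_dp","K_p",
  "K_mB","K_mC","K_mP",
  "k_sB","k_sC","k_sP",
  "n","m",
  "V_1B","V_1C","V_1P","V_1PC",
  "V_2B","V_2C","V_2P","V_2PC",
  "V_3B","V_3PC","V_4B","V_4PC",
  "v_dBC","v_dBN","v_dCC","v_dIN",
  "v_dPC","v_dPCC","v_dPCN",
  "v_mB","v_mC","v_mP",
  "v_sB","v_sC","v_sP")

clock_parms_vector <- function(params, mask, forcing) {
  light <- if (is.null(forcing)) c(1, -1, 0)
           else c(forcing$multiplier, forcing$period, forcing$on)
  c(unname(params[clock_param_order]), light, as.numeric(mask))
}
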