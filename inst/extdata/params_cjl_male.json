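{
  "condition": "cjl_male",
  "clock.v_per": 2.70074181553431,
  "clock.v_cry": 0.35373577451882,
  "clock.v_rev": 14.9993089730619,
  "clock.v_ror": 5.2560408910585,
  "clock.v_bmal1": 2.85937523802462,
  "clock.beta_per": 0.02,
  "clock.beta_cry": 0.05,
  "clock.beta_rev": 0.01,
  "clock.beta_ror": 0.02,
  "clock.beta_bmal1": 0.349479177411346,
  "clock.K_cb_per": 0.288637319564955,
  "clock.K_cb_cry": 0.310361941575497,
  "clock.K_cb_rev": 0.836442925811736,
  "clock.K_cb_ror": 0.156341559448289,
  "clock.h_cb_per": 6.4603780972332,
  "clock.h_cb_cry": 2.36247694561982,
  "clock.h_cb_rev": 6.65543958715258,
  "clock.h_cb_ror": 1,
  "clock.K_pc_per": 3.14068619022554,
  "clock.K_pc_cry": 1.33203805157875,
  "clock.K_pc_rev": 1.64528958159508,
  "clock.K_pc_ror": 0.923103685120347,
  "clock.h_pc_per": 8,
  "clock.h_pc_cry": 5.88904008048656,
  "clock.h_pc_rev": 4.63898775691677,
  "clock.h_pc_ror": 5.35897225178549,
  "clock.K_revcry": 14.5071946754009,
  "clock.h_revcry": 2.55617898429036,
  "clock.K_ror": 1.17947524426607,
  "clock.h_ror": 6.26091011637245,
  "clock.K_rev": 0.91068451340098,
  "clock.h_rev": 7.11656557355494,
  "clock.dm_per": 0.208366433108604,
  "clock.dm_cry": 0.0882492230222522,
  "clock.dm_rev": 0.411384167128446,
  "clock.dm_ror": 2.53631333332397,
  "clock.dm_bmal1": 0.697524150620012,
  "clock.kp_per": 0.113191404416182,
  "clock.kp_cry": 0.365933854854794,
  "clock.kp_rev": 0.369581074909855,
  "clock.kp_ror": 2.2972451012704,
  "clock.kp_bmal1": 0.563904439736464,
  "clock.dp_per": 0.194704716242077,
  "clock.dp_cry": 0.037256608954961,
  "clock.dp_rev": 0.452419231875827,
  "clock.dp_ror": 1.08489268397143,
  "clock.dp_bmal1": 0.214833481037271,
  "clock.kf_pc": 1.87067190035642,
  "clock.kb_pc": 0.118323229181732,
  "clock.d_pc": 0.574540206818521,
  "clock.kf_cb": 1.62055895261388,
  "clock.kb_cb": 0.0591616145908659,
  "clock.d_cb": 0.189582650910934,
  "clock.clock0": 1,
  "clock.k_lps": 8,
  "immune.d_P": 3,
  "immune.k_NP": 5.33780182765358,
  "immune.k_NT": 0.528980679345688,
  "immune.k_N6": 0.0630052732023379,
  "immune.k_ND": 0.00352550172895168,
  "immune.theta_N10": 0.23892367770376,
  "immune.theta_NCA": 1.89532396420053,
  "immune.k_N": 1.28593771805677,
  "immune.x_N": 1.18686983692324,
  "immune.d_N": 0.738457631552251,
  "immune.k_D": 0.477613971195714,
  "immune.x_D": 0.439445897226199,
  "immune.h_D": 3,
  "immune.k_DP": 0.00905194906454652,
  "immune.d_D": 0.127289200138305,
  "immune.k_T": 27.3219478807702,
  "immune.x_T": 0.540397946989809,
  "immune.h_T": 1.5,
  "immune.theta_T10": 0.154004629774876,
  "immune.theta_TCA": 0.77280366319052,
  "immune.d_T": 1.36843606020027,
  "immune.k_6": 6.95907191399266,
  "immune.x_6": 0.907602133462733,
  "immune.h_6": 1.5,
  "immune.theta_610": 0.190964384995592,
  "immune.theta_6CA": 0.629397423091714,
  "immune.a_6T": 3.62351078986982,
  "immune.x_6T": 2.39956002117296,
  "immune.h_6T": 2,
  "immune.d_6": 1.26839557861681,
  "immune.s_IL10": 0.025,
  "immune.k_10": 0.758355235256326,
  "immune.x_10": 0.299224669676704,
  "immune.h_10": 1.5,
  "immune.a_106": 2.73295639686008,
  "immune.x_106": 1.15851862626905,
  "immune.h_106": 2,
  "immune.k_Y10": 0.890638506225219,
  "immune.d_10": 0.786753194277478,
  "immune.k_Y": 0.229133188368418,
  "immune.x_Y": 17.8440627462522,
  "immune.h_Y": 2,
  "immune.d_Y": 0.515175527834836,
  "immune.s_CA": 0.03,
  "immune.k_CA": 0.0979360365137667,
  "immune.x_CA": 0.873158891331018,
  "immune.h_CA": 2,
  "immune.d_CA": 0.140274636298926,
  "coupling.K_cry_tnf": 0.0835090331304139,
  "coupling.h_cry_tnf": 2.87613310781324,
  "coupling.K_ror_tnf": 8.21407613184283,
  "coupling.h_ror_tnf": 2.13243554896754,
  "coupling.K_rev_il6": 63.964528934662,
  "coupling.h_rev_il6": 4.53409919386793,
  "coupling.K_rev_il10": 6.76322870730293,
  "coupling.h_rev_il10": 1.57059771353038
}
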