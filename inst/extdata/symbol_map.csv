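"name","equation","term"
"D_c","tumor","diffusion"
"c_max","tumor","logistic crowding"
"lambda_c","tumor","proliferation"
"d_n","tumor","necrosis"
"d_c","tumor","apoptosis"
"eta","tumor","CD8 kill"
"w_nec","tumor","oxygen switch"
"w_hyp","tumor","oxygen switch"
"w_normal","tumor","oxygen switch"
"D_q","mcsf","diffusion"
"s_q","mcsf","tumor source"
"d_q","mcsf","decay"
"s_M","mdsc","constant source"
"lambda_Mrho","mdsc","IL-35 source"
"K_rho","mdsc","IL-35 source"
"D_M","mdsc","diffusion"
"chi_M","mdsc","chemotaxis"
"lambda_MQ","mdsc","polarization"
"M_0","mdsc","polarization"
"K_q","mdsc","polarization"
"d_M","mdsc","death"
"D_rho","il35","diffusion"
"lambda_rho_c","il35","tumor source"
"lambda_rho_R","il35","Treg source"
"lambda_rho_M","il35","MDSC source"
"d_rho","il35","decay"
"D_R","treg","diffusion"
"lambda_RM","treg","MDSC activation"
"K_M","treg","MDSC activation"
"lambda_Rbeta","treg","TGF-beta activation"
"K_beta","treg","TGF-beta activation"
"d_R","treg","death"
"D_beta","tgfb","diffusion"
"lambda_beta_c","tgfb","tumor source"
"lambda_beta_R","tgfb","Treg source"
"d_beta","tgfb","decay"
"D_T","cd8","diffusion"
"chi_T","cd8","chemotaxis"
"lambda_T12","cd8","IL-12 activation"
"k_10M","cd8","IL-10 suppression"
"k_MCP","cd8","chemotaxis attractant"
"k_12M","cd8","IL-12 activation"
"K_T1","cd8","IL-10 suppression"
"K_T2","cd8","IL-12 activation"
"d_T","cd8","death"
"D_h","vegf","diffusion"
"lambda_hc","vegf","tumor source"
"K_rho_h","vegf","tumor source"
"eps_c","vegf","tumor source"
"lambda_hM","vegf","MDSC source"
"K_q_h","vegf","MDSC source"
"eps_M","vegf","MDSC source"
"d_h","vegf","decay"
"w_star","vegf","hypoxia factor"
"D_e","ec","diffusion"
"chi_e","ec","chemotaxis"
"lambda_e","ec","proliferation"
"e_max","ec","proliferation"
"K_h","ec","proliferation"
"h_star","ec","proliferation"
"lambda_w","oxygen","EC delivery"
"D_w","oxygen","diffusion"
"k_wT","oxygen","consumption"
"k_wM","oxygen","consumption"
"k_wR","oxygen","consumption"
"k_wc","oxygen","consumption"
"gamma_e","boundary","Robin exchange"
"gamma_w","boundary","Robin exchange"
"e_normal","boundary","exterior value"
"w_0","boundary","exterior value"
"R_domain","domain","geometry"
"t_final","domain","horizon"
"c_init","init","initial profile"
"r_init","init","initial profile"
"e_init_frac","init","initial profile"
"w_init_frac","init","initial profile"
"mu_A","drug","IL-35 sink"
"drug_alpha","drug","spatial profile"
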