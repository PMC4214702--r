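"name","group","value","unit","nd_scale","description","nd_value"
"D_c","tumor",8.64e-07,"cm^2/day","tau/L^2","diffusion coefficient of tumor cells",3.456e-06
"c_max","tumor",0.4,"g/cm^3","1/cref","carrying capacity of tumor cells",1
"lambda_c","tumor",0.6,"1/day","tau","maximal proliferation rate of tumor cells",0.6
"d_n","tumor",0.3,"1/day","tau","maximal necrosis rate of tumor cells",0.3
"d_c","tumor",0.1,"1/day","tau","apoptosis rate of tumor cells",0.1
"eta","tumor",30,"cm^3/g/day","tau*Tref","killing rate of tumor cells by activated CD8+ T cells",0.3
"w_nec","tumor",7.5e-07,"g/cm^3","1/wref","upper oxygen bound of the necrotic state",0.15
"w_hyp","tumor",2e-06,"g/cm^3","1/wref","upper oxygen bound of the extremely hypoxic state",0.4
"w_normal","tumor",5e-06,"g/cm^3","1/wref","normal oxygen level",1
"D_q","mcsf",0.0864,"cm^2/day","tau/L^2","diffusion coefficient of M-CSF",0.3456
"s_q","mcsf",2e-08,"1/day","tau*cref/qref","production rate of M-CSF by tumor cells",8
"d_q","mcsf",8,"1/day","tau","decay rate of M-CSF",8
"s_M","mdsc",1e-04,"g/cm^3/day","tau/Mref","constant source of MDSC",0.01
"lambda_Mrho","mdsc",0.003,"g/cm^3/day","tau/Mref","maximal IL-35-enhanced production rate of MDSC",0.3
"K_rho","mdsc",1e-10,"g/cm^3","1/rhoref","half-saturation of IL-35 in MDSC production",1
"D_M","mdsc",8.64e-07,"cm^2/day","tau/L^2","diffusion coefficient of MDSC",3.456e-06
"chi_M","mdsc",864,"cm^5/g/day","tau*qref/L^2","chemotaxis rate of MDSC toward M-CSF",3.456e-06
"lambda_MQ","mdsc",0.15,"1/day","tau","polarization rate of myeloid precursors by M-CSF",0.15
"M_0","mdsc",0.002,"g/cm^3","1/Mref","density of myeloid precursor cells",0.2
"K_q","mdsc",1e-09,"g/cm^3","1/qref","half-saturation of M-CSF in MDSC polarization",1
"d_M","mdsc",0.1,"1/day","tau","death rate of MDSC",0.1
"D_rho","il35",0.0864,"cm^2/day","tau/L^2","diffusion coefficient of IL-35",0.3456
"lambda_rho_c","il35",3.45e-10,"1/day","tau*cref/rhoref","production rate of IL-35 by tumor cells (scenario-dependent)",1.38
"lambda_rho_R","il35",2e-08,"1/day","tau*Rref/rhoref","production rate of IL-35 by Treg",0.2
"lambda_rho_M","il35",2e-10,"1/day","tau*Mref/rhoref","production rate of IL-35 by MDSC",0.02
"d_rho","il35",1.38,"1/day","tau","decay rate of IL-35",1.38
"D_R","treg",8.64e-07,"cm^2/day","tau/L^2","diffusion coefficient of Treg",3.456e-06
"lambda_RM","treg",1e-04,"g/cm^3/day","tau/Rref","maximal MDSC/IL-10-mediated activation rate of Treg",0.1
"K_M","treg",0.005,"g/cm^3","1/Mref","half-saturation of MDSC in Treg activation",0.5
"lambda_Rbeta","treg",3e-04,"g/cm^3/day","tau/Rref","maximal TGF-beta-mediated activation rate of Treg",0.3
"K_beta","treg",1e-10,"g/cm^3","1/betaref","half-saturation of TGF-beta in Treg activation",1
"d_R","treg",0.2,"1/day","tau","death rate of Treg",0.2
"D_beta","tgfb",0.0864,"cm^2/day","tau/L^2","diffusion coefficient of TGF-beta",0.3456
"lambda_beta_c","tgfb",1.25e-07,"1/day","tau*cref/betaref","production rate of TGF-beta by tumor cells",500
"lambda_beta_R","tgfb",5e-06,"1/day","tau*Rref/betaref","production rate of TGF-beta by Treg",50
"d_beta","tgfb",499,"1/day","tau","decay rate of TGF-beta",499
"D_T","cd8",8.64e-07,"cm^2/day","tau/L^2","diffusion coefficient of CD8+ T cells",3.456e-06
"chi_T","cd8",500,"cm^5/g/day","tau*mcpref/L^2","chemotaxis rate of CD8+ T cells toward MCP-1",2e-06
"lambda_T12","cd8",0.004,"g/cm^3/day","tau/Tref","maximal IL-12-mediated activation rate of CD8+ T cells",0.4
"k_10M","cd8",1e-07,"-","Mref/il10ref","IL-10 concentration produced per unit MDSC density",10
"k_MCP","cd8",1e-07,"-","Mref/mcpref","MCP-1 concentration produced per unit MDSC density",1
"k_12M","cd8",1e-08,"-","Mref/il12ref","IL-12 concentration produced per unit MDSC density",10
"K_T1","cd8",2e-11,"g/cm^3","1/il10ref","half-saturation of IL-10 in CD8+ T-cell suppression",0.2
"K_T2","cd8",2e-12,"g/cm^3","1/il12ref","half-saturation of IL-12 in CD8+ T-cell activation",0.2
"d_T","cd8",0.17,"1/day","tau","death rate of CD8+ T cells",0.17
"D_h","vegf",0.0864,"cm^2/day","tau/L^2","diffusion coefficient of VEGF",0.3456
"lambda_hc","vegf",1e-07,"1/day","tau*cref/href","maximal VEGF production rate by tumor cells",40
"K_rho_h","vegf",1e-10,"g/cm^3","1/rhoref","critical IL-35 value in tumor VEGF production",1
"eps_c","vegf",0.1,"-","1","baseline ratio of IL-35-independent tumor VEGF production",0.1
"lambda_hM","vegf",2e-07,"1/day","tau*Mref/href","maximal VEGF production rate by MDSC",2
"K_q_h","vegf",1e-09,"g/cm^3","1/qref","critical M-CSF value in MDSC VEGF production",1
"eps_M","vegf",0.1,"-","1","baseline ratio of M-CSF-independent MDSC VEGF production",0.1
"d_h","vegf",12.6,"1/day","tau","decay rate of VEGF",12.6
"w_star","vegf",2.5e-06,"g/cm^3","1/wref","oxygen level of maximal hypoxic VEGF enhancement",0.5
"D_e","ec",8.64e-07,"cm^2/day","tau/L^2","diffusion coefficient of endothelial cells",3.456e-06
"chi_e","ec",864,"cm^5/g/day","tau*href/L^2","chemotaxis rate of EC toward VEGF",3.456e-06
"lambda_e","ec",0.5,"1/day","tau","VEGF-driven proliferation rate of EC",0.5
"e_max","ec",0.01,"g/cm^3","1/eref","maximal EC density inside the tumor",2
"K_h","ec",1e-09,"g/cm^3","1/href","VEGF scaling constant in EC proliferation",1
"h_star","ec",5e-10,"g/cm^3","1/href","VEGF threshold for EC proliferation",0.5
"lambda_w","oxygen",8e+05,"cm^3/g/day","tau*eref","delivery rate of oxygen by EC",4000
"D_w","oxygen",1.73,"cm^2/day","tau/L^2","diffusion coefficient of oxygen",6.92
"k_wT","oxygen",2000,"cm^3/g/day","tau*Tref","oxygen consumption rate by CD8+ T cells",20
"k_wM","oxygen",2000,"cm^3/g/day","tau*Mref","oxygen consumption rate by MDSC",20
"k_wR","oxygen",2000,"cm^3/g/day","tau*Rref","oxygen consumption rate by Treg",2
"k_wc","oxygen",5000,"cm^3/g/day","tau*cref","oxygen consumption rate by tumor cells",2000
"gamma_e","boundary",2e-05,"cm/day","tau/L","flux rate of EC from healthy tissue at r = R",4e-05
"gamma_w","boundary",5,"cm/day","tau/L","flux rate of oxygen exchange with healthy tissue at r = R",10
"e_normal","boundary",0.0025,"g/cm^3","1/eref","EC density in normal healthy tissue",0.5
"w_0","boundary",5e-06,"g/cm^3","1/wref","oxygen concentration in normal healthy tissue",1
"R_domain","domain",0.5,"cm","1/L","radius of the tumor sphere",1
"t_final","domain",56,"day","1/tau","default simulation horizon",56
"c_init","init",0.2,"g/cm^3","1/cref","initial tumor density at r = 0",0.5
"r_init","init",0.1,"cm","1/L","spatial decay length of the initial tumor profile",0.2
"e_init_frac","init",0.5,"-","1","initial EC density at r = 0 as fraction of e_normal",0.5
"w_init_frac","init",0.5,"-","1","initial oxygen at r = 0 as fraction of w_0",0.5
"mu_A","drug",5,"1/day","tau","anti-IL-35 neutralization rate per unit drug",5
"drug_alpha","drug",4,"1/cm","L","spatial decay rate of drug from the tumor boundary",2
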