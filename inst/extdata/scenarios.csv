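"scenario","parameter","value","note"
"J558-IL-35","lambda_rho_c",3.45e-10,"high tumor IL-35 secretion (transfected line)"
"J558-Ctrl","lambda_rho_c",1.725e-11,"low tumor IL-35 secretion (control line)"
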