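# Compiled literature optical constants used by the chromophore solver.
# eps_*: molar extinction coefficients of oxy-/deoxy-hemoglobin,
#        1/(cm * mol/L), base-10 convention (multiply by ln(10) for mua).
# mua_water / mua_lipid: absorption coefficients of pure water and lipid,
#        mm^-1, at the tabulated wavelength.
wavelength_nm,eps_hbo2,eps_hb,mua_water,mua_lipid
730,420,1080,0.0019,0.0007
830,974,693,0.0029,0.0008
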