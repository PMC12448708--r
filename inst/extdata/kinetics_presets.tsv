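name	constant	value	units	source
tobacco	kc25	404.9	umol mol-1	standard tobacco in-vivo Rubisco constants (Bernacchi-form temperature functions)
tobacco	ko25	278400	umol mol-1	standard tobacco in-vivo Rubisco constants (Bernacchi-form temperature functions)
tobacco	gammastar25	42.75	umol mol-1	standard tobacco in-vivo Rubisco constants (Bernacchi-form temperature functions)
tobacco	rl25	1.0	umol CO2 m-2 s-1	package default basal day respiration; normally re-estimated per curve
tobacco	ea_kc	79430	J mol-1	standard tobacco in-vivo Rubisco constants (Bernacchi-form temperature functions)
tobacco	ea_ko	36380	J mol-1	standard tobacco in-vivo Rubisco constants (Bernacchi-form temperature functions)
tobacco	ea_gammastar	37830	J mol-1	standard tobacco in-vivo Rubisco constants (Bernacchi-form temperature functions)
tobacco	ea_rl	46390	J mol-1	standard tobacco in-vivo Rubisco constants (Bernacchi-form temperature functions)
rice	kc25	330.0	umol mol-1	synthetic stand-in: representative Oryza sativa deviation from tobacco, for sensitivity analysis only
rice	ko25	247000	umol mol-1	synthetic stand-in: representative Oryza sativa deviation from tobacco, for sensitivity analysis only
rice	gammastar25	39.0	umol mol-1	synthetic stand-in: representative Oryza sativa deviation from tobacco, for sensitivity analysis only
rice	rl25	1.0	umol CO2 m-2 s-1	package default basal day respiration; normally re-estimated per curve
rice	ea_kc	71000	J mol-1	synthetic stand-in: representative Oryza sativa deviation from tobacco, for sensitivity analysis only
rice	ea_ko	32000	J mol-1	synthetic stand-in: representative Oryza sativa deviation from tobacco, for sensitivity analysis only
rice	ea_gammastar	36000	J mol-1	synthetic stand-in: representative Oryza sativa deviation from tobacco, for sensitivity analysis only
rice	ea_rl	46390	J mol-1	synthetic stand-in: representative Oryza sativa deviation from tobacco, for sensitivity analysis only
potato	kc25	460.0	umol mol-1	synthetic stand-in: representative Solanum tuberosum deviation from tobacco, for sensitivity analysis only
potato	ko25	310000	umol mol-1	synthetic stand-in: representative Solanum tuberosum deviation from tobacco, for sensitivity analysis only
potato	gammastar25	44.5	umol mol-1	synthetic stand-in: representative Solanum tuberosum deviation from tobacco, for sensitivity analysis only
potato	rl25	1.0	umol CO2 m-2 s-1	package default basal day respiration; normally re-estimated per curve
potato	ea_kc	82000	J mol-1	synthetic stand-in: representative Solanum tuberosum deviation from tobacco, for sensitivity analysis only
potato	ea_ko	38000	J mol-1	synthetic stand-in: representative Solanum tuberosum deviation from tobacco, for sensitivity analysis only
potato	ea_gammastar	39000	J mol-1	synthetic stand-in: representative Solanum tuberosum deviation from tobacco, for sensitivity analysis only
potato	ea_rl	46390	J mol-1	synthetic stand-in: representative Solanum tuberosum deviation from tobacco, for sensitivity analysis only
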