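c_source	uptake_rate	uptake_sd	yield_mass	yield_sd	growth_rate	growth_sd	degree_respiration	degree_sd	mw
glucose	-16.3	1.1	0.11	0.01	0.33	0.01	0.00	0.00	0.18016
mannose	-12.8	1.1	0.14	0.03	0.32	0.01	0.06	0.00	0.18016
galactose	-4.5	0.3	0.25	0.02	0.20	0.01	6.90	1.30	0.18016
pyruvate	-2.5	0.4	0.45	0.04	0.10	0.01	13.30	2.66	0.08806
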