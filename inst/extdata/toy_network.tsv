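tf	target	evidence
TF1	E01	literature
TF1	E02	literature
TF1	E03	literature
TF2	E01	literature
TF2	E04	literature
TF2	E05	other
TF3	E06	literature
TF3	E07	literature
TF3	E08	literature
TF3	E09	literature
TF4	E10	literature
TF4	E11	literature
TF5	E02	literature
TF5	E02	other
TF5	E05	literature
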