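# Internal calibrant definitions: name, theoretical MH+ (Da), kind.
# kind is one of: matrix_standard (spiked into the MALDI matrix) or
# autolysis (trypsin self-digestion products present in every digest).
# The RfffR value (f = pentafluoro-phenylalanine) is a configured
# constant, not computed from residue masses. Autolysis masses are the
# standard porcine trypsin values; edit to match your enzyme lot.
name	theoretical_mh	kind
ACTH_18_39	2465.199	matrix_standard
RfffR	1042.276	matrix_standard
trypsin_842	842.5100	autolysis
trypsin_1045	1045.5642	autolysis
trypsin_2211	2211.1046	autolysis
trypsin_2283	2283.1807	autolysis
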