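# Predictor calls for the 10-peptide reference panel versus IR microscopy.
# Columns follow the printed order; consensus_ir_pct is the printed per-peptide
# consensus-with-IR percentage.
id	ir_microscopy	amylogram	foldamyloid	pasta2	path_lr	path_rf	consensus_ir_pct
FNPQGG	No	No	No	No	No	No	100
FTFIQF	Yes	Yes	Yes	No	Yes	Yes	80
ISFLIF	Yes	Yes	Yes	Yes	Yes	Yes	100
KPAESD	No	No	No	No	No	No	100
LVFYQQ	Yes	Yes	Yes	No	Yes	Yes	80
NPQGGY	No	No	No	No	No	No	100
SFLIFL	Yes*	Yes	Yes	Yes	Yes	Yes	100
TKPAES	No	No	No	No	No	No	100
YLLYYT	Yes	Yes	Yes	No	Yes	Yes	80
YTVIIE	Yes	Yes	Yes	Yes	No	Yes	80
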