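# Predictor calls for the 24-peptide test panel versus IR microscopy and the
# original database annotation. Column order and call case (YES/NO/no) are
# verbatim from print; the loader normalizes case. The printed WSFYLL consensus
# cell (80) is inconsistent with its own row: the five calls against IR (No)
# give 20 under the stated definition. The cell is stored as printed and the
# discrepancy is surfaced by the audit functions.
id	database	ir_microscopy	amylogram	path_lr	path_rf	foldamyloid	pasta2	consensus_ir_pct
ALEEYT	Yes	No	No	No	No	No	No	100
ASSSNY	Yes	No	No	No	No	No	No	100
DETVIV	No	Yes*	Yes	No	Yes	No	Yes	60
ELNIYQ	No	No	Yes	No	No	Yes	No	60
FGELFE	No	No	Yes	No	No	No	No	80
FQKQQK	No	No	Yes	No	No	No	No	80
FTPTEK	No	No	Yes	No	No	No	No	80
HGFNQQ	Yes	No	No	No	No	No	No	100
HLFNLT	Yes	No	No	No	Yes	Yes	No	60
HSSNNF	Yes	No	No	No	No	No	No	100
MIENIQ	Yes	No	No	No	No	No	No	100
MIHFGN	Yes	No	No	No	No	No	No	100
MMHFGN	Yes	No	No	No	No	No	No	100
NIFNIT	Yes	No	No	No	Yes	Yes	No	60
NNSGPN	Yes	No	No	No	No	No	No	100
NTIFVQ	No	Yes	YES	Yes	Yes	Yes	No	80
QANKHI	Yes	No	No	No	No	No	No	100
QEMRHF	Yes	No	No	No	No	No	No	100
SHVIIE	No	Yes	Yes	No	No	Yes	Yes	60
STTIIE	No	No	Yes	No	No	No	No	80
STVVIE	No	Yes	Yes	No	Yes	Yes	Yes	80
SWVIIE	No	Yes	Yes	No	Yes	Yes	Yes	80
WSFYLL	No	No	Yes	Yes	Yes	Yes	No	80
YYTEFT	No	no	Yes	No	No	No	No	80
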