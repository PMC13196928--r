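# Default brand -> generic synonym table for the pulmonary-hypertension drug panel.
# Deliberately minimal: only pairs needed to reconcile the mixed brand/generic naming of
# the panel. Treprostinil formulations (Tyvaso, Remodulin, Orenitram) are kept as
# distinct products and are not pooled by active ingredient.
OPSUMIT	MACITENTAN
ADEMPAS	RIOCIGUAT
ADCIRCA	TADALAFIL
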