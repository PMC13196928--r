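# Narrative per-drug event subsets for the three pulmonary-hypertension panel drugs the
# source text singles out as NOT related to all four symptoms. The remaining nine panel
# drugs are stated to relate to all four. Note the documented internal conflict: the
# printed CI table for Adempas (riociguat) has all four lower bounds > 1, which would
# make it a fourth all-positive exception; this table records the text's drug-level
# statement. Canonical (generic) drug names.
drug	events
ILOPROST	DYSPNOEA;COUGH;CHEST PAIN
RIOCIGUAT	COUGH;PALPITATIONS;CHEST PAIN
SILDENAFIL	DYSPNOEA;PALPITATIONS
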