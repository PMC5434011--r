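predictor	token	normalized
provean	deleterious	Deleterious
provean	possibly deleterious	Deleterious
provean	neutral	Neutral
provean	possibly neutral	Neutral
provean	missing	missing
provean	na	missing
sift	damaging	Damaging
sift	tolerated	Tolerated
sift	missing	missing
sift	na	missing
polyphen	probably damaging	probably_damaging
polyphen	probably_damaging	probably_damaging
polyphen	possibly damaging	possibly_damaging
polyphen	possibly_damaging	possibly_damaging
polyphen	possibly deleterious	possibly_damaging
polyphen	benign	benign
polyphen	possibly neutral	benign
polyphen	missing	missing
polyphen	na	missing
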