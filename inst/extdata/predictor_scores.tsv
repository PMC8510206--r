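peptide	anticp_svm	iacp_prob	mlacp_rf	mlacp_svm	toxic	cpp
TTMICLTCAR	1.05	0.997	0.515	0.766	1	1
TTGICLTCCR	1.58	0.997	0.538	0.674	1	1
VTFVLIAAK	1.28	0.875	0.558	0.787	0	0
FTFVLLAAK	1.62	0.943	0.506	0.541	0	1
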