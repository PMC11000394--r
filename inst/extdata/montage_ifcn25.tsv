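name	alt_name	x	y	region
Fp1	NA	-0.206011329583	0.63403767753	frontal
Fp2	NA	0.206011329583	0.63403767753	frontal
F9	NA	-0.809016994375	0.587785252292	inferior
F7	NA	-0.539344662917	0.391856834862	frontal
F3	NA	-0.268043870262	0.331006613213	frontal
Fz	NA	0	0.333333333333	frontal
F4	NA	0.268043870262	0.331006613213	frontal
F8	NA	0.539344662917	0.391856834862	frontal
F10	NA	0.809016994375	0.587785252292	inferior
T9	NA	-1	0	inferior
T3	T7	-0.666666666667	0	temporal
C3	NA	-0.333333333333	0	central
Cz	NA	0	0	central
C4	NA	0.333333333333	0	central
T4	T8	0.666666666667	0	temporal
T10	NA	1	0	inferior
T5	P7	-0.539344662917	-0.391856834862	temporal
P3	NA	-0.268043870262	-0.331006613213	parietal
Pz	NA	0	-0.333333333333	parietal
P4	NA	0.268043870262	-0.331006613213	parietal
T6	P8	0.539344662917	-0.391856834862	temporal
P9	NA	-0.809016994375	-0.587785252292	inferior
P10	NA	0.809016994375	-0.587785252292	inferior
O1	NA	-0.206011329583	-0.63403767753	occipital
O2	NA	0.206011329583	-0.63403767753	occipital
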