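# Published confusion matrix of the five-PC SVM classifier on the
# 31-sample prediction set (rows = true class, columns = predicted).
# The printed header's final column label repeats "PSu"; the row labels
# (and the table note defining PSe) identify it as PSe, and the parser
# trusts row labels.
	PQ	Su10:Q90	Su20:Q80	Su30:Q70	Su40:Q60	Su50:Q50	PSu	Se10:Q90	Se20:Q80	Se30:Q70	Se40:Q60	Se50:Q50	PSu
PQ	3	0	0	0	0	0	0	0	0	0	0	0	0
Su10:Q90	0	2	0	0	0	0	0	0	0	0	0	0	0
Su20:Q80	0	0	2	0	0	0	0	0	0	0	0	0	0
Su30:Q70	0	0	0	2	0	0	0	0	0	0	0	0	0
Su40:Q60	0	0	0	0	3	0	0	0	0	0	0	0	0
Su50:Q50	0	0	0	0	0	2	0	0	0	0	0	0	0
PSu	0	0	0	0	0	0	2	0	0	0	0	0	0
Se10:Q90	0	0	0	0	0	0	0	2	1	0	0	0	0
Se20:Q80	0	0	0	0	0	0	0	0	3	0	0	0	0
Se30:Q70	0	0	0	0	0	0	0	0	0	2	0	0	0
Se40:Q60	0	0	0	0	0	0	0	0	0	0	3	0	0
Se50:Q50	0	0	0	0	0	0	0	0	0	0	0	2	0
PSe	0	0	0	0	0	0	0	0	0	0	0	0	2
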