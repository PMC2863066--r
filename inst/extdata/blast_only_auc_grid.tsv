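dataset	network	adaboost_j48	naive_bayes	svm	logistic	ensemble
mouse-human	ppi	87.79	90.15	77.31	90.29	90.30
mouse-human	coexpression	89.80	70.4	90.40	90.40	90.40
mouse-fly	ppi	87.58	88.47	70.17	92.01	88.89
mouse-yeast	ppi	89.85	91.89	90.78	95.46	91.45
human-fly	ppi	81.35	87.70	65.90	88.90	84.42
human-yeast	ppi	82.97	81.26	63.68	85.50	84.19
yeast-fly	ppi	73.02	72.49	56.80	74.86	74.48
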