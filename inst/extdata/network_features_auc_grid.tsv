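dataset	network	adaboost_j48	naive_bayes	svm	logistic	ensemble
mouse-human	ppi	95.19	88.72	90.78	89.57	96.18
mouse-human	coexpression	89.80	94.1	97.50	97.30	96.10
mouse-fly	ppi	90.31	85.81	81.28	80.67	88.94
mouse-yeast	ppi	92.04	85.50	79.63	95.60	95.50
human-fly	ppi	88.18	83.10	75.03	87.04	87.20
human-yeast	ppi	82.83	81.26	78.22	81.57	84.84
yeast-fly	ppi	74.52	69.36	64.57	74.33	72.78
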