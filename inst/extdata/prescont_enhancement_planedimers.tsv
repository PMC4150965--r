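# surfcrf reference table
# Published confusion counts and metrics for enhancing the PresCont predictor
# above score thresholds theta on the PlaneDimers set, paired with the
# PresCont threshold predictor at approximately equal specificity.
# Surface totals: tp+fn = 3595 interface, tn+fp = 27327 non-interface.
method	theta	tp	tn	fp	fn	specificity	sensitivity	mcc
enhance	0.500	2181	23182	4145	1414	0.848	0.607	0.362
prescont	0.500	2100	23197	4130	1495	0.849	0.584	0.346
enhance	0.525	2303	22917	4410	1292	0.839	0.641	0.373
prescont	0.525	2206	22912	4415	1389	0.838	0.614	0.353
enhance	0.550	2507	22103	5224	1088	0.809	0.697	0.375
prescont	0.550	2419	22102	5225	1176	0.809	0.673	0.358
enhance	0.575	2560	21992	5335	1035	0.805	0.712	0.380
prescont	0.575	2463	21915	5412	1132	0.802	0.685	0.358
enhance	0.600	2379	22685	4642	1216	0.830	0.662	0.376
prescont	0.600	2253	22780	4547	1342	0.834	0.627	0.356
enhance	0.625	2287	23044	4283	1308	0.843	0.636	0.376
prescont	0.625	2136	23049	4278	1459	0.843	0.594	0.346
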