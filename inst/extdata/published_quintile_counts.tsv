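variant	quintile	controls	cases	total
unweighted	1	342	438	780
unweighted	2	250	344	594
unweighted	3	226	327	553
unweighted	4	180	293	473
unweighted	5	209	367	576
unweighted_scaled	1	478	522	1000
unweighted_scaled	2	356	449	805
unweighted_scaled	3	338	448	786
unweighted_scaled	4	252	440	692
unweighted_scaled	5	317	548	865
weighted	1	244	293	537
weighted	2	248	315	563
weighted	3	234	363	597
weighted	4	241	387	628
weighted	5	240	411	651
weighted_scaled	1	356	361	717
weighted_scaled	2	342	386	728
weighted_scaled	3	348	493	841
weighted_scaled	4	348	546	894
weighted_scaled	5	347	621	968
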