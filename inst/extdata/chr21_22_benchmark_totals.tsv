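# Published benchmark summary of CpG-island predictions on human chromosomes 21 and 22
# (assembly NCBI build 36), as printed in the CpG-island prediction literature.
# Columns: printed totals/counts plus the printed mean island length and coverage cells.
# mean_stable / coverage_stable flag cells whose printed value is reproducible from the
# printed total, count and chromosome length by half-up rounding at the printed precision
# (the remaining cells were evidently computed from unrounded counts not printed).
chromosome	chrom_length	method	total_length	n_islands	printed_mean	mean_stable	printed_coverage	coverage_digits	coverage_stable
chr21	46944329	CpGPlot	347334	973	357	1	0.73	2	0
chr21	46944329	CpGcluster	639161	2703	237	0	1.36	2	1
chr21	46944329	CpGProD	1072192	1091	983	1	2.28	2	1
chr21	46944329	CpGIS	1280505	3704	346	1	2.73	2	1
chr21	46944329	PSO	1564596	2648	591	1	3.3	1	1
chr21	46944329	CPSO	1607472	2813	571	1	3.4	1	1
chr21	46944329	GA	1262449	2513	502	1	2.68	2	0
chr21	46944329	CGA	1589629	3304	482	0	3.39	2	1
chr22	49691432	CpGPlot	679803	1642	414	1	1.36	2	0
chr22	49691432	CpGcluster	522748	2186	239	1	1.05	2	1
chr22	49691432	CpGProD	2067653	1903	1087	1	4.16	2	1
chr22	49691432	CpGIS	2842255	6875	413	1	5.71	2	0
chr22	49691432	PSO	2802675	4571	613	1	5.64	2	1
chr22	49691432	CPSO	2907983	4882	596	1	5.85	2	1
chr22	49691432	GA	2251454	3902	577	1	4.53	2	1
chr22	49691432	CGA	3085715	4985	619	1	6.20	2	0
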