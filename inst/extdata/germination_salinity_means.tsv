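line	treatment	percent	t50	sd_plate
M82	SDF	95.13	2.66	1.00
M82	SDS	90.75	3.42	1.82
IL1-1-3	SDF	79.24	5.00	1.49
IL1-1-3	SDS	93.94	3.08	0.94
IL2-1-1	SDF	97.91	3.00	1.41
IL2-1-1	SDS	100.00	2.50	0.93
IL2-5	SDF	98.67	3.00	1.14
IL2-5	SDS	91.87	3.00	1.07
IL3-4	SDF	85.71	4.00	0.85
IL3-4	SDS	99.00	4.00	1.18
IL4-1	SDF	92.58	3.00	2.21
IL4-1	SDS	95.98	3.00	1.28
IL6-1	SDF	80.00	3.33	1.94
IL6-1	SDS	57.92	5.00	2.62
IL7-4	SDF	75.10	4.83	1.89
IL7-4	SDS	99.00	2.50	1.10
IL8-3-1	SDF	97.22	2.33	0.58
IL8-3-1	SDS	100.00	2.33	1.01
IL11-4	SDF	100.00	3.50	0.68
IL11-4	SDS	96.67	3.00	1.19
IL12-1	SDF	98.00	4.00	1.55
IL12-1	SDS	99.00	3.00	0.75
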