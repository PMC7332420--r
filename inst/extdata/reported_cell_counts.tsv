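category	item	count
cluster	1	2794
cluster	2	2704
cluster	3	2073
cluster	4	1679
cluster	5	1511
cluster	6	1374
cluster	7	1248
cluster	8	1069
cluster	9	986
cluster	10	923
cluster	11	797
cluster	12	649
cluster	13	575
cluster	14	321
cluster	15	246
cluster	16	185
atlas	total	19134
endosymbiotic	total	382
state	1	36
state	2	109
state	3	155
state	4	45
state	5	37
ordering_subcluster	1	247
ordering_subcluster	2	53
ordering_subcluster	3	82
cnidocyte_subcluster	1	423
cnidocyte_subcluster	2	374
cnidocyte	total	797
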