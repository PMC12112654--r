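degree	description	n_pairs
1	parent-offspring	378
1	siblings	354
2	grandparent-grandchild	65
2	avuncular	450
2	half-siblings	37
2	double 1st cousins	4
3	1st cousins and 2nd cousins	12
3	grand avuncular	69
3	half avuncular	63
3	1st cousins	500
3	double 1st cousins, 1 removed	19
4	1st cousins, 1 removed and 2nd cousins, 1 removed	16
4	1st cousins, 1 removed	522
4	half 1st cousins	32
4	double 2nd cousins	22
4	double 1st cousins, 2 removed	9
5	other	637
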