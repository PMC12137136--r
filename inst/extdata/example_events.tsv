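onset	duration	category	identity	orientation	relevance	block	run	trial_id
0	0.5	false_font	16	right	irrelevant	1	1	1
2.99000973621383	1.5	false_font	6	right	irrelevant	1	1	2
5.2516053274637	0.5	face	10	front	target	1	1	3
7.52219460773568	1	object	9	front	relevant_nontarget	1	1	4
9.87310591303653	0.5	false_font	20	left	irrelevant	1	1	5
12.467734413729	1.5	face	3	right	relevant_nontarget	1	1	6
14.7099161368024	0.5	face	11	front	relevant_nontarget	1	1	7
17.1183580230422	1.5	letter	6	left	irrelevant	1	1	8
19.8863211812121	1.5	object	17	left	relevant_nontarget	1	1	9
22.3692649706144	0.5	object	5	right	relevant_nontarget	1	1	10
24.5996751956702	0.5	face	14	left	relevant_nontarget	1	1	11
27.1823750166416	0.5	letter	13	right	irrelevant	1	1	12
29.6102790306973	1	false_font	10	front	irrelevant	1	1	13
31.9543777986068	0.5	object	13	front	relevant_nontarget	1	1	14
34.2167618830912	0.5	object	2	right	relevant_nontarget	1	1	15
36.6556481962165	1	object	3	front	relevant_nontarget	1	1	16
39.1793380172177	1.5	letter	16	front	irrelevant	1	1	17
41.4560786632551	0.5	object	15	front	relevant_nontarget	1	1	18
44.1030021144909	0.5	face	17	front	relevant_nontarget	1	1	19
46.3587260667753	1.5	letter	12	right	irrelevant	1	1	20
48.5700138530701	1.5	false_font	3	front	irrelevant	1	1	21
50.9643865209266	1.5	object	18	right	target	1	1	22
53.339114539583	1	face	12	right	relevant_nontarget	1	1	23
55.8001809386387	1.5	face	13	front	relevant_nontarget	1	1	24
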