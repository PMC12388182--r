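mol_id	atom	nucleus	shift	class
ferrocene	1	13C	69.7488055869351	ring_metal
ferrocene	1	1H	4.18242226602321	ring_metal
ferrocene	2	13C	69.935639500995	ring_metal
ferrocene	2	1H	4.16002218868545	ring_metal
ferrocene	3	13C	69.266029970034	ring_metal
ferrocene	3	1H	4.21708818367125	ring_metal
ferrocene	4	13C	68.5330847156758	ring_metal
ferrocene	4	1H	4.1739294497002	ring_metal
ferrocene	5	13C	69.2614891950551	ring_metal
ferrocene	5	1H	4.18333377269588	ring_metal
ferrocene	6	13C	69.3939593896445	ring_metal
ferrocene	6	1H	4.19548853327592	ring_metal
ferrocene	7	13C	69.2115619732468	ring_metal
ferrocene	7	1H	4.23969662555799	ring_metal
ferrocene	8	13C	68.9435948289964	ring_metal
ferrocene	8	1H	4.1868771639343	ring_metal
ferrocene	9	13C	69.691173273863	ring_metal
ferrocene	9	1H	4.20084667933274	ring_metal
ferrocene	10	13C	69.3742653434042	ring_metal
ferrocene	10	1H	4.21167643214955	ring_metal
methyl-ferrocene	1	13C	69.4710062103139	ring_metal
methyl-ferrocene	1	1H	4.19566679319918	ring_metal
methyl-ferrocene	2	13C	69.6166689102419	ring_metal
methyl-ferrocene	2	1H	4.21109720572231	ring_metal
methyl-ferrocene	3	13C	69.3273801056555	ring_metal
methyl-ferrocene	3	1H	4.15583810044738	ring_metal
methyl-ferrocene	4	13C	69.2211521362703	ring_metal
methyl-ferrocene	4	1H	4.16559899606344	ring_metal
methyl-ferrocene	5	13C	68.6576090700823	ring_metal
methyl-ferrocene	5	1H	4.18159474264769	ring_metal
methyl-ferrocene	6	13C	69.3351065457886	ring_metal
methyl-ferrocene	7	13C	69.877043730546	ring_metal
methyl-ferrocene	7	1H	4.24668429826956	ring_metal
methyl-ferrocene	8	13C	69.7325352680451	ring_metal
methyl-ferrocene	8	1H	4.16707974465346	ring_metal
methyl-ferrocene	9	13C	68.8418182850867	ring_metal
methyl-ferrocene	9	1H	4.17259263456068	ring_metal
methyl-ferrocene	10	13C	69.7736706735961	ring_metal
methyl-ferrocene	10	1H	4.20263564155082	ring_metal
methyl-ferrocene	12	13C	27.4270445685151	methyl
methyl-ferrocene	12	1H	0.87544550950294	methyl
acetyl-ferrocene	1	13C	68.9372296488779	ring_metal
acetyl-ferrocene	1	1H	4.21667646437195	ring_metal
acetyl-ferrocene	2	13C	69.289291308848	ring_metal
acetyl-ferrocene	2	1H	4.16857985159892	ring_metal
acetyl-ferrocene	3	13C	69.4054539748743	ring_metal
acetyl-ferrocene	3	1H	4.22645632517268	ring_metal
acetyl-ferrocene	4	13C	69.6645584485729	ring_metal
acetyl-ferrocene	4	1H	4.23078729555385	ring_metal
acetyl-ferrocene	5	13C	69.2856072461962	ring_metal
acetyl-ferrocene	5	1H	4.23298305711425	ring_metal
acetyl-ferrocene	6	13C	69.3907248606455	ring_metal
acetyl-ferrocene	7	13C	69.4571018259854	ring_metal
acetyl-ferrocene	7	1H	4.24005619604994	ring_metal
acetyl-ferrocene	8	13C	69.6191657003636	ring_metal
acetyl-ferrocene	8	1H	4.20168605691492	ring_metal
acetyl-ferrocene	9	13C	69.7987916889056	ring_metal
acetyl-ferrocene	9	1H	4.18775640172164	ring_metal
acetyl-ferrocene	10	13C	69.1545228679902	ring_metal
acetyl-ferrocene	10	1H	4.21076837009773	ring_metal
acetyl-ferrocene	12	13C	200.017614818014	carbonyl
acetyl-ferrocene	14	13C	27.2791690235267	methyl
acetyl-ferrocene	14	1H	0.888455511967885	methyl
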