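# name	pattern	budget
DM	TTATCCCNNTTATCCC	1
RBS	AGGAGG	1
minus35	TTGACA	2
minus10	TATAAT	2
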