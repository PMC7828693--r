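enzyme_id	component	status_vickermania
cytb	complex III	absent
cyc1	complex III	absent
risp	complex III	absent
qcr1	complex III	absent
cox1	complex IV	absent
cox2	complex IV	absent
cox3	complex IV	absent
cox4	complex IV	absent
cox6	complex IV	absent
cytc	cytochrome c	absent
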