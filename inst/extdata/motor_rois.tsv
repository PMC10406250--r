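task	location	x	y	z
hand_right	thumb	-46.6	-22.8	56.2
hand_right	index_finger	-43.3	-26.8	59.9
hand_right	middle_finger	-40.8	-28.6	62
hand_right	ring_finger	-37.5	-29.7	64.8
hand_right	little_finger	-35.2	-30.9	66.3
hand_left	thumb	46.6	-22.8	56.2
hand_left	index_finger	43.3	-26.8	59.9
hand_left	middle_finger	40.8	-28.6	62
hand_left	ring_finger	37.5	-29.7	64.8
hand_left	little_finger	35.2	-30.9	66.3
tongue	base	-61.4	-11.1	23.3
tongue	base	61.4	-11.1	23.3
tongue	middle	-60.7	-11.4	30
tongue	middle	60.7	-11.4	30
tongue	tip	-59.2	-11	36
tongue	tip	59.2	-11	36
foot_right	foot	-4	-41	64
foot_left	foot	4	-41	64
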