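rank	month	scope	n_used	n_available
family	April	all	18	80
family	May	all	29	85
family	combined	all	31	96
family	April	A	15	80
family	May	A	14	85
family	combined	A	20	96
family	April	B	11	80
family	May	B	25	85
family	combined	B	26	96
family	April	C	10	80
family	May	C	20	85
family	combined	C	21	96
genus	April	all	31	291
genus	May	all	45	360
genus	combined	all	47	437
genus	April	A	26	291
genus	May	A	19	360
genus	combined	A	31	437
genus	April	B	19	291
genus	May	B	39	360
genus	combined	B	40	437
genus	April	C	16	291
genus	May	C	34	360
genus	combined	C	35	437
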