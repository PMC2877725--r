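G01	O01
G02	O01
G03	O02
G04	O02
G05	O03
G06	O04
G07	O04
G08	O04
G09	O05
G17	O08
G18	O08
G19	O09
G20	O10
G21	O10
G22	O11
G23	O11
G26	O13
G27	O14
G28	O14
G29	O15
G31	O17
G32	O18
G33	O18
G34	O18
G35	O18
G36	O18
G37	O19
G38	O20
G39	O21
G41	O23
G42	O23
G43	O23
G44	O24
G45	O25
G46	O26
G49	O28
G50	O28
G53	O30
G54	O31
G55	O31
G56	O32
G57	O32
G58	O32
G62	O34
G66	O36
G67	O36
G68	O37
G69	O37
G70	O38
G72	O40
G73	O40
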