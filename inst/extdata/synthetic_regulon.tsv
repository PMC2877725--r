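R01	G39
R02	G29
R02	G41
R02	G42
R02	G43
R02	G45
R03	G01
R03	G02
R04	G44
R05	G19
R05	G27
R05	G28
R05	G62
R06	G38
R07	G32
R07	G33
R07	G34
R07	G35
R07	G36
R08	G68
R08	G69
R09	G01
R09	G02
R09	G03
R09	G04
R09	G05
R09	G09
R09	G17
R09	G18
R09	G19
R09	G20
R09	G21
R09	G26
R09	G31
R09	G32
R09	G33
R09	G34
R09	G35
R09	G36
R09	G37
R09	G44
R09	G45
R09	G53
R09	G62
R09	G66
R09	G67
R09	G68
R09	G69
R09	G70
R09	G72
R09	G73
R10	G20
R10	G21
R11	G01
R11	G02
R11	G03
R11	G04
R11	G05
R11	G06
R11	G07
R11	G08
R11	G09
R11	G22
R11	G23
R11	G26
R11	G39
R11	G46
R11	G49
R11	G50
R11	G53
R11	G54
R11	G55
R11	G56
R11	G57
R11	G58
R11	G70
R12	G31
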