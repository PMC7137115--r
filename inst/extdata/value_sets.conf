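# English tariff anchors per instrument.
# feasible set = {ceiling} U [floor, gap_lower]; the open interval
# (gap_lower, ceiling) is the unobservable "gap".
eq5d3l.floor = -0.594
eq5d3l.gap_lower = 0.883
eq5d3l.ceiling = 1

eq5d5l.floor = -0.285
eq5d5l.gap_lower = 0.951
eq5d5l.ceiling = 1

icecapo.floor = 0
icecapo.gap_lower = 1
icecapo.ceiling = 1
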