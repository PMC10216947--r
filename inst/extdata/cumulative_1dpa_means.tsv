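# Mean labeling indices (percent) of regenerating Alitta virens under
# cumulative EdU exposure starting at 1 day post-amputation; one row per
# exposure time, values are per-time-point means across specimens.
time_h	li_percent
0.25	1.8
5	17
10	30.1
24	64.9
48	85.7
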