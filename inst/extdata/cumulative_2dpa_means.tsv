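# Mean labeling indices (percent) of regenerating Alitta virens under
# cumulative EdU exposure starting at 2 days post-amputation; one row per
# exposure time, values are per-time-point means across specimens.
time_h	li_percent
0.25	22.3
10	51
24	61.4
48	90.6
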