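metabolite	ratio_70_over_80	knockout_sp0_over_wt_80
Glc	0.97	1
DGat	1.27	1
KDG	4.16	2.79
GA	NA	2.79
Gly	1.91	1.44
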