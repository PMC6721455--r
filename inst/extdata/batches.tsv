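# generated-by: mirep 0.1.0
# seed: 11
# alpha: 0.05
# min_expr: 0.004
# command: simulate --seed 11 --n-targets 6 --out-dir inst/extdata
construct_id	batch	positive_control_id	is_positive_control	true_r0
g0001	1	posctrl_b01	FALSE	1
g0002	1	posctrl_b01	FALSE	0.50262757760986
g0003	1	posctrl_b01	FALSE	0.597542550513529
g0004	1	posctrl_b01	FALSE	0.5
g0005	1	posctrl_b01	FALSE	0.548731344581738
g0006	1	posctrl_b01	FALSE	0.614591617171596
posctrl_b01	1	posctrl_b01	TRUE	0.184889113181271
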