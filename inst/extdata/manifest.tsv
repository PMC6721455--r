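# generated-by: mirep 0.1.0
# seed: 11
# alpha: 0.05
# min_expr: 0.004
# command: simulate --seed 11 --n-targets 6 --out-dir inst/extdata
gene_id	utr_id	start	end	n_sites	pass_restriction
g0001	g0001	593	1093	1	FALSE
g0002	g0002	30	530	1	TRUE
g0003	g0003	1500	2000	1	TRUE
g0004	g0004	680	1180	1	TRUE
g0005	g0005	0	500	1	TRUE
g0006	g0006	931	1431	1	TRUE
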