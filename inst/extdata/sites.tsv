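# generated-by: mirep 0.1.0
# seed: 11
# alpha: 0.05
# min_expr: 0.004
# command: simulate --seed 11 --n-targets 6 --out-dir inst/extdata
utr_id	start	end	seed_type	matched_seq
g0001	246	254	8mer	AUUAUAGA
g0002	246	254	8mer	AUUAUAGA
g0003	470	477	7mer-m8	AUUAUAG
g0004	246	254	8mer	AUUAUAGA
g0005	174	182	8mer	AUUAUAGA
g0006	246	253	7mer-m8	AUUAUAG
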